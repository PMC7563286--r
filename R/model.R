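#' Construct a reaction
#'
#' A reaction is a stoichiometric conversion with flux bounds, an optional
#' gene-protein-reaction (GPR) Boolean rule, an objective weight and
#' pathway annotations. Negative stoichiometric coefficients denote
#' substrates, positive coefficients products.
#'
#' @param id Non-empty reaction identifier, unique within a model.
#' @param stoichiometry Named numeric vector: metabolite id -> signed
#'   coefficient. May be empty only for exchange/demand reactions.
#' @param reversible Logical; a reversible reaction may carry negative flux.
#' @param lower_bound,upper_bound Default flux bounds (arbitrary flux units,
#'   mmol/gDW/h implied). Irreversible reactions must have
#'   `lower_bound >= 0`.
#' @param gpr GPR rule: a string such as `"g1 and (g2 or g3)"`, a parsed
#'   [gpr_expression][parse_gpr] tree, or `NULL` for none.
#' @param objective_coefficient Weight of this reaction's flux in the FBA
#'   objective; 0 for non-objective reactions.
#' @param subsystem Pathway name, or `NA` if unannotated.
#' @param categories Character vector of category tags, a subset of
#'   `c("carbon", "nitrogen", "anabolic", "catabolic", "exchange")`.
#' @return An object of class `"mm_reaction"`.
#' @export
#' @examples
#' reaction("PGI", c(g6p = -1, f6p = 1), reversible = TRUE, gpr = "pgi")
reaction <- function(id, stoichiometry = numeric(), reversible = FALSE,
                     lower_bound = if (reversible) -1000 else 0,
                     upper_bound = 1000, gpr = NULL,
                     objective_coefficient = 0, subsystem = NA_character_,
                     categories = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) > 0 && is.null(names(stoichiometry)))
    stop("stoichiometry must be a named numeric vector (metabolite id -> coefficient)")
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (!is.null(gpr) && !inherits(gpr, "gpr_expression"))
    stop("gpr must be NULL, a string, or a gpr_expression")
  structure(
    list(id = id,
         stoichiometry = stoichiometry[stoichiometry != 0],
         reversible = isTRUE(reversible),
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound),
         gpr = gpr,
         objective_coefficient = as.numeric(objective_coefficient),
         subsystem = as.character(subsystem),
         categories = as.character(categories)),
    class = "mm_reaction")
}

#' Construct a metabolic model
#'
#' Bundles metabolites and reactions into a constraint-based metabolic model
#' whose steady-state flux space is \eqn{\{v : Sv = 0,\ L \le v \le U\}},
#' where the stoichiometric matrix \eqn{S} (metabolites x reactions) is
#' assembled from the per-reaction stoichiometries.
#'
#' The model's gene set is the union of all gene identifiers appearing as
#' leaves of the reactions' GPR rules.
#'
#' @param metabolites A data.frame with columns `id` (unique, non-empty),
#'   `name` and `compartment` (free-text tags; compartments are carried as
#'   annotations only and play no role in the mass balance).
#' @param reactions A list of [reaction()] objects.
#' @param biomass_reaction_id Identifier of the biomass reaction; it should
#'   carry a nonzero `objective_coefficient`.
#' @return An object of class `"metabolic_model"`.
#' @seealso [validate_model()], [stoichiometric_matrix()], [load_model()]
#' @export
metabolic_model <- function(metabolites, reactions, biomass_reaction_id) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  for (col in c("name", "compartment")) {
    if (is.null(metabolites[[col]])) metabolites[[col]] <- NA_character_
    metabolites[[col]] <- as.character(metabolites[[col]])
  }
  metabolites$id <- as.character(metabolites$id)
  stopifnot(is.list(reactions))
  genes <- sort(unique(unlist(lapply(reactions, function(r)
    if (is.null(r$gpr)) character() else gpr_genes(r$gpr)))))
  structure(
    list(metabolites = metabolites[, c("id", "name", "compartment")],
         reactions = reactions,
         biomass_reaction_id = as.character(biomass_reaction_id),
         genes = genes),
    class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites, %d reactions, %d genes\n",
              nrow(x$metabolites), length(x$reactions), length(x$genes)))
  cat(sprintf("  biomass reaction: %s\n", x$biomass_reaction_id))
  invisible(x)
}

reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

reaction_by_id <- function(model, id) {
  idx <- match(id, reaction_ids(model))
  if (is.na(idx)) stop("unknown reaction id: ", id)
  model$reactions[[idx]]
}

#' Assemble the stoichiometric matrix
#'
#' @param model A [metabolic_model()].
#' @return A sparse `Matrix` with one row per metabolite and one column per
#'   reaction, in model order, preserving coefficient signs.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rids <- reaction_ids(model)
  triples <- lapply(seq_along(model$reactions), function(j) {
    st <- model$reactions[[j]]$stoichiometry
    if (length(st) == 0) return(NULL)
    cbind(i = match(names(st), mets), j = j, x = unname(st))
  })
  tr <- do.call(rbind, triples)
  if (is.null(tr)) tr <- cbind(i = integer(), j = integer(), x = numeric())
  Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                       dims = c(length(mets), length(rids)),
                       dimnames = list(mets, rids))
}

#' Objective coefficient vector
#'
#' @param model A [metabolic_model()].
#' @return Named numeric vector of objective coefficients, one per reaction.
#' @export
objective_coefficients <- function(model) {
  v <- vapply(model$reactions, `[[`, 0, "objective_coefficient")
  names(v) <- reaction_ids(model)
  v
}

is_exchange_reaction <- function(r) {
  "exchange" %in% r$categories || length(r$stoichiometry) <= 1L ||
    grepl("^(EX_|DM_|SK_)", r$id)
}

#' Validate a metabolic model
#'
#' Checks all structural invariants (unique non-empty identifiers, resolvable
#' stoichiometry references, bound ordering, reversibility consistency,
#' presence of the biomass/objective reaction) and reports problems instead
#' of raising conditions. A model with an empty error list is safe to use
#' with the solver functions.
#'
#' @param model A [metabolic_model()].
#' @return An object of class `"validation_report"`: a list with data.frames
#'   `errors` and `warnings`, each with columns `code` and `message`.
#' @export
validate_model <- function(model) {
  errs <- list(); warns <- list()
  err <- function(code, msg) errs[[length(errs) + 1L]] <<- c(code, msg)
  wrn <- function(code, msg) warns[[length(warns) + 1L]] <<- c(code, msg)

  mets <- model$metabolites$id
  if (length(mets) == 0) err("no_metabolites", "model has no metabolites")
  if (anyNA(mets) || any(!nzchar(mets)))
    err("empty_metabolite_id", "metabolite with empty id")
  if (anyDuplicated(mets))
    err("duplicate_metabolite_id", paste("duplicate metabolite id:",
        paste(unique(mets[duplicated(mets)]), collapse = ", ")))

  if (length(model$reactions) == 0) err("no_reactions", "model has no reactions")
  rids <- reaction_ids(model)
  if (anyDuplicated(rids))
    err("duplicate_reaction_id", paste("duplicate reaction id:",
        paste(unique(rids[duplicated(rids)]), collapse = ", ")))

  for (r in model$reactions) {
    if (!nzchar(r$id)) err("empty_reaction_id", "reaction with empty id")
    if (r$lower_bound > r$upper_bound)
      err("bound_order", sprintf("reaction %s: lower_bound %g > upper_bound %g",
                                 r$id, r$lower_bound, r$upper_bound))
    if (!r$reversible && r$lower_bound < 0)
      err("irreversible_negative_lb",
          sprintf("irreversible reaction %s has lower_bound %g < 0",
                  r$id, r$lower_bound))
    unknown <- setdiff(names(r$stoichiometry), mets)
    if (length(unknown) > 0)
      err("unknown_metabolite",
          sprintf("reaction %s references unknown metabolite(s): %s",
                  r$id, paste(unknown, collapse = ", ")))
    if (length(r$stoichiometry) == 0 && !is_exchange_reaction(r))
      err("empty_stoichiometry",
          sprintf("non-exchange reaction %s has empty stoichiometry", r$id))
    if (is.na(r$subsystem) || !nzchar(r$subsystem))
      wrn("unannotated_subsystem", sprintf("reaction %s has no subsystem", r$id))
  }

  if (!model$biomass_reaction_id %in% rids) {
    err("missing_biomass", sprintf("biomass reaction '%s' not in model",
                                   model$biomass_reaction_id))
  } else if (reaction_by_id(model, model$biomass_reaction_id)$objective_coefficient == 0) {
    wrn("biomass_zero_objective",
        sprintf("biomass reaction '%s' has objective coefficient 0",
                model$biomass_reaction_id))
  }
  if (length(model$reactions) > 0 && all(objective_coefficients(model) == 0))
    err("no_objective", "no reaction has a nonzero objective coefficient")

  as_df <- function(x) {
    if (length(x) == 0) return(data.frame(code = character(), message = character()))
    m <- do.call(rbind, x)
    data.frame(code = m[, 1], message = m[, 2], row.names = NULL)
  }
  structure(list(errors = as_df(errs), warnings = as_df(warns)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors) > 0)
    cat(paste0("  E[", x$errors$code, "] ", x$errors$message, collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname validate_model
#' @export
is_valid_model <- function(model) nrow(validate_model(model)$errors) == 0

assert_valid_model <- function(model) {
  rep <- validate_model(model)
  if (nrow(rep$errors) > 0)
    stop("invalid model: ", paste(rep$errors$message, collapse = "; "))
  invisible(model)
}
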