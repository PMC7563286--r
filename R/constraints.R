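#' Bound sets
#'
#' A bound set is the per-reaction flux bounds actually handed to the
#' solver, together with the provenance of each pair: `"default"` (the
#' model's own bounds), `"expression"` (set from a GPR evaluation by
#' [apply_eflux()]), `"knockout"` or `"overexpression"`.
#'
#' @param reaction_id,lower_bound,upper_bound,provenance Parallel vectors.
#' @return A data.frame classed `"bound_set"`.
#' @export
bound_set <- function(reaction_id, lower_bound, upper_bound,
                      provenance = "default") {
  b <- data.frame(reaction_id = as.character(reaction_id),
                  lower_bound = as.numeric(lower_bound),
                  upper_bound = as.numeric(upper_bound),
                  provenance = provenance,
                  row.names = NULL)
  if (any(b$lower_bound > b$upper_bound))
    stop("bound set has lower_bound > upper_bound for: ",
         paste(b$reaction_id[b$lower_bound > b$upper_bound], collapse = ", "))
  class(b) <- c("bound_set", "data.frame")
  b
}

#' @rdname bound_set
#' @param model A [metabolic_model()].
#' @export
default_bounds <- function(model) {
  bound_set(reaction_ids(model),
            vapply(model$reactions, `[[`, 0, "lower_bound"),
            vapply(model$reactions, `[[`, 0, "upper_bound"),
            "default")
}

bounds_index <- function(bounds, ids) {
  idx <- match(ids, bounds$reaction_id)
  if (anyNA(idx))
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Derive expression (E-flux) bounds from a proteome
#'
#' For every reaction whose GPR rule evaluates to a measured level `p`
#' under the min/max semantics of [evaluate_gpr()], the allowable flux is
#' set to `[-scale*p, +scale*p]` if the reaction is reversible and
#' `[0, +scale*p]` if irreversible, so that more abundant enzymes permit
#' proportionally more flux. Reactions with no GPR, or whose rule is
#' unmeasured under `missing_policy`, keep their default model bounds
#' (provenance `"default"`).
#'
#' By default the expression bound replaces the default bound outright;
#' with `cap_at_default = TRUE` it is intersected with the default
#' interval instead, which prevents an expression level larger than the
#' model's physical maximum from widening the bound.
#'
#' @param model A validated [metabolic_model()].
#' @param levels Expression map (named non-negative numeric), see
#'   [to_expression_map()].
#' @param scale Positive proteome-to-flux proportionality constant
#'   (default 1: normalized levels are used as bounds directly).
#' @param missing_policy Passed to [evaluate_gpr()].
#' @param cap_at_default Intersect expression bounds with default bounds?
#' @return A [bound_set()] covering every reaction of the model.
#' @export
apply_eflux <- function(model, levels, scale = 1.0,
                        missing_policy = c("unbounded", "zero", "ignore"),
                        cap_at_default = FALSE) {
  missing_policy <- match.arg(missing_policy)
  if (!is.numeric(scale) || length(scale) != 1 || is.na(scale) || scale <= 0)
    stop("scale must be a positive number")
  assert_valid_model(model)
  b <- default_bounds(model)
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    if (is.null(r$gpr)) next
    p <- evaluate_gpr(r$gpr, levels, missing_policy)
    if (is.na(p)) next
    lb <- if (r$reversible) -scale * p else 0
    ub <- scale * p
    if (cap_at_default) {
      lb <- max(lb, r$lower_bound)
      ub <- min(ub, r$upper_bound)
      if (lb > ub) lb <- ub  # disjoint intervals collapse to the default edge
    }
    b$lower_bound[i] <- lb
    b$upper_bound[i] <- ub
    b$provenance[i] <- "expression"
  }
  b
}

#' In silico reaction knockout
#'
#' Removes flux capacity through the named reactions by setting both
#' bounds to zero.
#'
#' @param bounds A [bound_set()].
#' @param reaction_ids Reactions to knock out.
#' @return The modified bound set (provenance `"knockout"`).
#' @export
knockout <- function(bounds, reaction_ids) {
  if (length(reaction_ids) == 0) return(bounds)
  idx <- bounds_index(bounds, reaction_ids)
  bounds$lower_bound[idx] <- 0
  bounds$upper_bound[idx] <- 0
  bounds$provenance[idx] <- "knockout"
  bounds
}

#' In silico reaction overexpression
#'
#' Scales both bounds of the named reactions by `factor` (default 2,
#' i.e. a doubling of the enzyme's capacity in both directions).
#'
#' @param bounds A [bound_set()].
#' @param reaction_ids Reactions to overexpress.
#' @param factor Multiplier >= 1.
#' @return The modified bound set (provenance `"overexpression"`).
#' @export
overexpress <- function(bounds, reaction_ids, factor = 2.0) {
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) || factor < 1)
    stop("overexpression factor must be >= 1")
  if (length(reaction_ids) == 0) return(bounds)
  idx <- bounds_index(bounds, reaction_ids)
  bounds$lower_bound[idx] <- bounds$lower_bound[idx] * factor
  bounds$upper_bound[idx] <- bounds$upper_bound[idx] * factor
  bounds$provenance[idx] <- "overexpression"
  bounds
}

#' Gene-level knockout, as an expression-map edit
#'
#' Convenience wrapper for gene (rather than reaction) deletions: forces
#' the named genes to level 0 in the expression map, so that on the next
#' [apply_eflux()] with `missing_policy = "zero"` every reaction whose
#' rule depends on them is bounded accordingly (a complex loses all
#' capacity; an isoenzyme falls back to its measured siblings).
#'
#' @param levels Expression map.
#' @param genes Genes to delete.
#' @return The modified expression map.
#' @export
knockout_genes <- function(levels, genes) {
  levels[genes] <- 0
  levels
}

#' Export a bound set to TSV
#'
#' @param bounds A [bound_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bounds <- function(bounds, path) {
  out <- bounds
  out$lower_bound <- num17(out$lower_bound)
  out$upper_bound <- num17(out$upper_bound)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
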