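#' Read a metabolic model from disk
#'
#' Three formats are supported:
#' * `"json"` — the canonical lossless dialect (documented in
#'   [save_model()]).
#' * `"sbml"` — SBML Level 3 with fbc-style flux bounds, objectives and
#'   nested gene-product associations.
#' * `"tsv"` — a triple of tab-separated files sharing a path prefix:
#'   `<prefix>.metabolites.tsv`, `<prefix>.reactions.tsv`,
#'   `<prefix>.stoichiometry.tsv`.
#'
#' @param path File path (for `tsv`, the common prefix of the three files).
#' @param format One of `"json"`, `"sbml"`, `"tsv"`; by default inferred
#'   from the file extension (`.json`; `.xml`/`.sbml`; anything else is
#'   treated as a TSV prefix).
#' @param validate If `TRUE` (default) the loaded model must pass
#'   [validate_model()] with zero errors, otherwise an error is raised.
#' @return A [metabolic_model()] with GPR strings parsed into trees.
#' @export
load_model <- function(path, format = NULL, validate = TRUE) {
  format <- model_format(path, format)
  if (format != "tsv" && !file.exists(path))
    stop("model file not found: ", path)
  model <- switch(format,
                  json = read_model_json(path),
                  sbml = read_model_sbml(path),
                  tsv  = read_model_tsv(path))
  if (validate) {
    rep <- validate_model(model)
    if (nrow(rep$errors) > 0)
      stop("model in '", path, "' failed validation: ",
           paste(rep$errors$message, collapse = "; "))
  }
  model
}

#' Write a metabolic model to disk
#'
#' The JSON dialect is an object with keys `format`
#' (`"proflux-model-1"`), `biomass_reaction_id`, `metabolites` (array of
#' `{id, name, compartment}`) and `reactions` (array of `{id,
#' stoichiometry: {metabolite: coefficient}, reversible, lower_bound,
#' upper_bound, gpr (rule string or null), objective_coefficient,
#' subsystem, categories}`). It round-trips every field losslessly.
#'
#' SBML output uses Level 3 core with the fbc conventions (bound
#' parameters, a maximize objective, `geneProductAssociation` trees);
#' subsystem and category annotations are carried in the reaction notes.
#' Identifiers are prefixed (`M_`, `R_`, `G_`) on write and stripped on
#' read; identifiers containing characters outside `[A-Za-z0-9_]` are not
#' representable in this dialect.
#'
#' TSV output is three files: metabolites (`id`, `name`, `compartment`),
#' reactions (`id`, `reversible`, `lower_bound`, `upper_bound`, `gpr`,
#' `objective_coefficient`, `subsystem`, `categories` semicolon-joined,
#' plus a `biomass` flag column) and stoichiometry (`reaction_id`,
#' `metabolite_id`, `coefficient`). Bounds and coefficients are printed
#' with 17 significant digits so doubles survive the round trip exactly.
#'
#' @param model A validated [metabolic_model()].
#' @param path Destination path (for `tsv`, the common prefix).
#' @inheritParams load_model
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = NULL) {
  assert_valid_model(model)
  format <- model_format(path, format)
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path),
         tsv  = write_model_tsv(model, path))
  invisible(path)
}

model_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("json", "sbml", "tsv")))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") "json" else if (ext %in% c("xml", "sbml")) "sbml" else "tsv"
}

## ---- JSON ----

write_model_json <- function(model, path) {
  rx <- lapply(model$reactions, function(r) {
    list(id = r$id,
         stoichiometry = as.list(r$stoichiometry),
         reversible = r$reversible,
         lower_bound = r$lower_bound,
         upper_bound = r$upper_bound,
         gpr = if (is.null(r$gpr)) NULL else unparse_gpr(r$gpr),
         objective_coefficient = r$objective_coefficient,
         subsystem = if (is.na(r$subsystem)) NULL else r$subsystem,
         categories = as.list(r$categories))
  })
  obj <- list(format = "proflux-model-1",
              biomass_reaction_id = model$biomass_reaction_id,
              metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
                as.list(model$metabolites[i, , drop = FALSE])),
              reactions = rx)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
}

read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$reactions) || is.null(obj$metabolites))
    stop("JSON model '", path, "': missing 'metabolites' or 'reactions' key")
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id %||% NA_character_,
               name = m$name %||% NA_character_,
               compartment = m$compartment %||% NA_character_)))
  if (is.null(mets)) mets <- data.frame(id = character(), name = character(),
                                        compartment = character())
  reactions <- lapply(obj$reactions, function(r) {
    st <- unlist(r$stoichiometry %||% list())
    if (is.null(st)) st <- numeric()
    reaction(id = r$id,
             stoichiometry = st,
             reversible = isTRUE(r$reversible),
             lower_bound = r$lower_bound,
             upper_bound = r$upper_bound,
             gpr = if (is.null(r$gpr)) NULL else r$gpr,
             objective_coefficient = r$objective_coefficient %||% 0,
             subsystem = r$subsystem %||% NA_character_,
             categories = unlist(r$categories %||% list()) %||% character())
  })
  metabolic_model(mets, reactions, obj$biomass_reaction_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- TSV ----

tsv_paths <- function(prefix)
  paste0(prefix, c(".metabolites.tsv", ".reactions.tsv", ".stoichiometry.tsv"))

num17 <- function(x) sprintf("%.17g", x)

write_model_tsv <- function(model, prefix) {
  p <- tsv_paths(prefix)
  utils::write.table(model$metabolites, p[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  rx <- do.call(rbind, lapply(model$reactions, function(r)
    data.frame(id = r$id, reversible = r$reversible,
               lower_bound = num17(r$lower_bound),
               upper_bound = num17(r$upper_bound),
               gpr = if (is.null(r$gpr)) "" else unparse_gpr(r$gpr),
               objective_coefficient = num17(r$objective_coefficient),
               subsystem = ifelse(is.na(r$subsystem), "", r$subsystem),
               categories = paste(r$categories, collapse = ";"),
               biomass = r$id == model$biomass_reaction_id)))
  utils::write.table(rx, p[2], sep = "\t", quote = FALSE, row.names = FALSE)
  st <- do.call(rbind, lapply(model$reactions, function(r) {
    if (length(r$stoichiometry) == 0) return(NULL)
    data.frame(reaction_id = r$id, metabolite_id = names(r$stoichiometry),
               coefficient = num17(unname(r$stoichiometry)))
  }))
  if (is.null(st)) st <- data.frame(reaction_id = character(),
                                    metabolite_id = character(),
                                    coefficient = character())
  utils::write.table(st, p[3], sep = "\t", quote = FALSE, row.names = FALSE)
}

read_model_tsv <- function(prefix) {
  p <- tsv_paths(prefix)
  missing <- p[!file.exists(p)]
  if (length(missing) > 0)
    stop("TSV model: missing file(s): ", paste(missing, collapse = ", "))
  mets <- utils::read.delim(p[1], colClasses = "character", na.strings = NULL)
  mets[mets == ""] <- NA_character_
  rx_df <- utils::read.delim(p[2], colClasses = "character", na.strings = NULL)
  st_df <- utils::read.delim(p[3], colClasses = "character", na.strings = NULL)
  reactions <- lapply(seq_len(nrow(rx_df)), function(i) {
    row <- rx_df[i, ]
    sel <- st_df$reaction_id == row$id
    st <- as.numeric(st_df$coefficient[sel])
    names(st) <- st_df$metabolite_id[sel]
    reaction(id = row$id,
             stoichiometry = st,
             reversible = as.logical(row$reversible),
             lower_bound = as.numeric(row$lower_bound),
             upper_bound = as.numeric(row$upper_bound),
             gpr = if (nzchar(row$gpr)) row$gpr else NULL,
             objective_coefficient = as.numeric(row$objective_coefficient),
             subsystem = if (nzchar(row$subsystem)) row$subsystem else NA_character_,
             categories = if (nzchar(row$categories))
               strsplit(row$categories, ";", fixed = TRUE)[[1]] else character())
  })
  biomass <- rx_df$id[as.logical(rx_df$biomass)]
  if (length(biomass) != 1)
    stop("TSV model: exactly one reaction must be flagged biomass=TRUE")
  metabolic_model(mets, reactions, biomass)
}

## ---- SBML (Level 3 + fbc conventions) ----

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_id_check <- function(ids) {
  bad <- ids[!grepl("^[A-Za-z0-9_]+$", ids)]
  if (length(bad) > 0)
    stop("identifiers not representable in the SBML dialect: ",
         paste(utils::head(bad, 5), collapse = ", "))
}

write_model_sbml <- function(model, path) {
  rids <- reaction_ids(model)
  sbml_id_check(c(model$metabolites$id, rids, model$genes))
  compartments <- unique(ifelse(is.na(model$metabolites$compartment), "c",
                                model$metabolites$compartment))
  xml_attr_num <- function(x) sprintf("%.17g", x)

  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "false")

  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in compartments)
    xml2::xml_add_child(loc, "compartment", id = cp, constant = "true")

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(los, "species", id = paste0("M_", m$id),
                              compartment = if (is.na(m$compartment)) "c" else m$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(m$name)) xml2::xml_set_attr(sp, "name", m$name)
  }

  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (r in model$reactions) {
    xml2::xml_add_child(lop, "parameter", id = paste0("R_", r$id, "_lb"),
                        value = xml_attr_num(r$lower_bound), constant = "true")
    xml2::xml_add_child(lop, "parameter", id = paste0("R_", r$id, "_ub"),
                        value = xml_attr_num(r$upper_bound), constant = "true")
  }

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(lor, "reaction", id = paste0("R_", r$id),
                              reversible = tolower(as.character(r$reversible)),
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0("R_", r$id, "_lb"),
                              "fbc:upperFluxBound" = paste0("R_", r$id, "_ub"))
    if (!is.na(r$subsystem) || length(r$categories) > 0) {
      notes <- xml2::xml_add_child(rn, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      if (!is.na(r$subsystem))
        xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
      if (length(r$categories) > 0)
        xml2::xml_add_child(body, "p", paste0("CATEGORIES: ",
                                              paste(r$categories, collapse = ";")))
    }
    subs <- r$stoichiometry[r$stoichiometry < 0]
    prods <- r$stoichiometry[r$stoichiometry > 0]
    if (length(subs) > 0) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(subs))
        xml2::xml_add_child(lr, "speciesReference", species = paste0("M_", m),
                            stoichiometry = xml_attr_num(-subs[[m]]),
                            constant = "true")
    }
    if (length(prods) > 0) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prods))
        xml2::xml_add_child(lp, "speciesReference", species = paste0("M_", m),
                            stoichiometry = xml_attr_num(prods[[m]]),
                            constant = "true")
    }
    if (!is.null(r$gpr)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      sbml_write_gpr(gpa, r$gpr)
    }
  }

  loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  cc <- objective_coefficients(model)
  for (id in names(cc)[cc != 0])
    xml2::xml_add_child(lfo, "fbc:fluxObjective", "fbc:reaction" = paste0("R_", id),
                        "fbc:coefficient" = xml_attr_num(cc[[id]]))

  logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes)
    xml2::xml_add_child(logp, "fbc:geneProduct", "fbc:id" = paste0("G_", g),
                        "fbc:label" = g)

  xml2::write_xml(doc, path)
}

sbml_write_gpr <- function(parent, expr) {
  if (expr$kind == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", expr$gene))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", expr$kind))
    for (ch in expr$children) sbml_write_gpr(node, ch)
  }
}

strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

sbml_read_gpr <- function(node) {
  name <- xml2::xml_name(node)  # namespace-stripped by xml_name default? use local
  kids <- xml2::xml_find_all(node, "./*")
  if (grepl("geneProductRef$", name)) {
    g <- xml2::xml_attr(node, "geneProduct")
    return(structure(list(kind = "gene", gene = strip_prefix(g, "G_")),
                     class = "gpr_expression"))
  }
  if (grepl("(and|or)$", name)) {
    children <- lapply(kids, sbml_read_gpr)
    return(gpr_node(sub(".*:", "", name), children))
  }
  # geneProductAssociation wrapper: single child
  sbml_read_gpr(kids[[1]])
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  find <- function(node, ln)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", ln))
  find1 <- function(node, ln)
    xml2::xml_find_first(node, sprintf(".//*[local-name()='%s']", ln))

  sp <- find(doc, "species")
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"))

  params <- find(doc, "parameter")
  pvals <- as.numeric(xml2::xml_attr(params, "value"))
  names(pvals) <- xml2::xml_attr(params, "id")

  objs <- find(doc, "fluxObjective")
  ocoef <- as.numeric(xml2::xml_attr(objs, "coefficient"))
  names(ocoef) <- strip_prefix(xml2::xml_attr(objs, "reaction"), "R_")

  rnodes <- find(doc, "reaction")
  reactions <- lapply(rnodes, function(rn) {
    rid <- strip_prefix(xml2::xml_attr(rn, "id"), "R_")
    sto <- numeric()
    for (ref in xml2::xml_find_all(rn,
        "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
      m <- strip_prefix(xml2::xml_attr(ref, "species"), "M_")
      sto[m] <- -as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(rn,
        "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
      m <- strip_prefix(xml2::xml_attr(ref, "species"), "M_")
      sto[m] <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_node")) sbml_read_gpr(gpa) else NULL
    subsystem <- NA_character_; categories <- character()
    for (pnode in xml2::xml_find_all(rn, ".//*[local-name()='p']")) {
      txt <- xml2::xml_text(pnode)
      if (startsWith(txt, "SUBSYSTEM: "))
        subsystem <- sub("^SUBSYSTEM: ", "", txt)
      if (startsWith(txt, "CATEGORIES: "))
        categories <- strsplit(sub("^CATEGORIES: ", "", txt), ";",
                               fixed = TRUE)[[1]]
    }
    lb <- pvals[[xml2::xml_attr(rn, "lowerFluxBound")]]
    ub <- pvals[[xml2::xml_attr(rn, "upperFluxBound")]]
    reaction(id = rid, stoichiometry = sto,
             reversible = xml2::xml_attr(rn, "reversible") == "true",
             lower_bound = lb, upper_bound = ub, gpr = gpr,
             objective_coefficient = if (rid %in% names(ocoef)) ocoef[[rid]] else 0,
             subsystem = subsystem, categories = categories)
  })
  biomass <- names(ocoef)[which.max(abs(ocoef))]
  metabolic_model(mets, reactions, biomass)
}
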