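#' Specification of a toy metabolic network
#'
#' Describes a small stoichiometrically consistent test network built
#' from motifs with analytically known LP optima: a substrate uptake
#' exchange capped at `exchange_cap`, a linear conversion chain feeding a
#' biomass sink, optional two-reaction detours parallel to chain steps
#' (to exercise parsimonious routing) and optional three-reaction futile
#' cycles (whose flux an L1 minimization must drive to zero).
#'
#' @param n_linear_chain Number of chain conversion reactions (>= 2).
#' @param n_parallel_paths Number of parallel two-reaction detours.
#' @param n_cycles Number of futile-cycle motifs.
#' @param exchange_cap Upper bound of the uptake exchange; this is the
#'   analytic optimum of the biomass objective.
#' @param seed Integer seed (the construction is deterministic; the seed
#'   is recorded so fixtures can be labelled).
#' @return A list of class `"toy_model_spec"`.
#' @export
toy_model_spec <- function(n_linear_chain = 3, n_parallel_paths = 1,
                           n_cycles = 1, exchange_cap = 10, seed = 1) {
  stopifnot(n_linear_chain >= 2, n_parallel_paths >= 0, n_cycles >= 0,
            exchange_cap > 0)
  structure(list(n_linear_chain = as.integer(n_linear_chain),
                 n_parallel_paths = as.integer(n_parallel_paths),
                 n_cycles = as.integer(n_cycles),
                 exchange_cap = exchange_cap, seed = as.integer(seed)),
            class = "toy_model_spec")
}

#' Generate a toy metabolic model with known optima
#'
#' Builds the network described by a [toy_model_spec()]. The biomass
#' optimum equals `exchange_cap` (the chain and detours have capacity
#' 1000 downstream of the capped uptake), and the minimal total absolute
#' flux at that optimum is `exchange_cap * (n_linear_chain + 2)` (uptake +
#' direct chain + biomass; detours and cycles carry zero in the
#' parsimonious solution).
#'
#' Chain reactions carry GPR rules exercising both Boolean operators
#' (an `and` complex on the first step, an `or` isoenzyme pair on the
#' second, single genes elsewhere) and are annotated
#' carbon/catabolic; detour reactions are annotated nitrogen/anabolic.
#'
#' @param spec A [toy_model_spec()].
#' @return A list: `model` ([metabolic_model()]), `known_optimum`,
#'   `known_min_l1`, and `biomass_path_genes` (genes whose rules gate the
#'   direct biomass route).
#' @export
make_toy_model <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))
  k <- spec$n_linear_chain
  mets <- sprintf("M%d", seq_len(k + 1))
  rx <- list(reaction("EX_SRC", c(M1 = 1), lower_bound = 0,
                      upper_bound = spec$exchange_cap,
                      subsystem = "exchange", categories = "exchange"))
  chain_gpr <- function(i) {
    if (i == 1) return("gA1 and gB1")
    if (i == 2) return("gC2 or gD2")
    sprintf("gR%d", i)
  }
  for (i in seq_len(k)) {
    st <- c(-1, 1)
    names(st) <- mets[c(i, i + 1)]
    rx[[length(rx) + 1]] <- reaction(sprintf("R%d", i), st, gpr = chain_gpr(i),
                                     subsystem = "central chain",
                                     categories = c("carbon", "catabolic"))
  }
  for (j in seq_len(spec$n_parallel_paths)) {
    s <- ((j - 1) %% k) + 1
    dm <- sprintf("D%d", j)
    mets <- c(mets, dm)
    st1 <- c(-1, 1); names(st1) <- c(sprintf("M%d", s), dm)
    st2 <- c(-1, 1); names(st2) <- c(dm, sprintf("M%d", s + 1))
    rx[[length(rx) + 1]] <- reaction(sprintf("PD%da", j), st1,
                                     gpr = sprintf("gP%da", j),
                                     subsystem = "nitrogen shunt",
                                     categories = c("nitrogen", "anabolic"))
    rx[[length(rx) + 1]] <- reaction(sprintf("PD%db", j), st2,
                                     gpr = sprintf("gP%db", j),
                                     subsystem = "nitrogen shunt",
                                     categories = c("nitrogen", "anabolic"))
  }
  for (cy in seq_len(spec$n_cycles)) {
    cm <- sprintf("C%d_%d", cy, 1:2)
    mets <- c(mets, cm)
    sts <- list(stats::setNames(c(-1, 1), c("M2", cm[1])),
                stats::setNames(c(-1, 1), c(cm[1], cm[2])),
                stats::setNames(c(-1, 1), c(cm[2], "M2")))
    for (leg in 1:3)
      rx[[length(rx) + 1]] <- reaction(sprintf("CY%d%s", cy, letters[leg]),
                                       sts[[leg]],
                                       gpr = sprintf("gY%d%s", cy, letters[leg]),
                                       subsystem = "futile cycle",
                                       categories = "carbon")
  }
  st_bio <- stats::setNames(-1, sprintf("M%d", k + 1))
  rx[[length(rx) + 1]] <- reaction("BIOMASS", st_bio, objective_coefficient = 1,
                                   subsystem = "biomass",
                                   categories = "anabolic")
  model <- metabolic_model(
    data.frame(id = mets, name = mets, compartment = "c"),
    rx, "BIOMASS")
  assert_valid_model(model)
  chain_genes <- sort(unique(unlist(lapply(seq_len(k), function(i)
    gpr_genes(parse_gpr(chain_gpr(i)))))))
  list(model = model,
       known_optimum = spec$exchange_cap,
       known_min_l1 = spec$exchange_cap * (k + 2),
       biomass_path_genes = chain_genes)
}

#' Specification of a synthetic replicate proteome
#'
#' Describes a proteome intensity table with log-normal replicate noise
#' and an injected differential-expression (DE) signal: in every
#' non-control condition, DE proteins have their mean intensity shifted
#' by `de_log2_shift` on the log2 scale.
#'
#' @param n_proteins Number of proteins.
#' @param n_replicates Replicates per condition (>= 2).
#' @param conditions Condition labels; the first is the control.
#' @param baseline_mean Mean intensity of non-DE proteins (arbitrary
#'   units).
#' @param noise_sigma Replicate noise SD on the log2 scale.
#' @param de_fraction Fraction of proteins that are DE (ignored when
#'   explicit DE identities are supplied to [make_proteome()]).
#' @param de_log2_shift Injected log2 shift of DE proteins in non-control
#'   conditions (negative = downregulation under the treatment).
#' @param seed Integer RNG seed.
#' @return A list of class `"proteome_spec"`.
#' @export
proteome_spec <- function(n_proteins = 50, n_replicates = 3,
                          conditions = c("T35", "T22"), baseline_mean = 20,
                          noise_sigma = 0.2, de_fraction = 0.1,
                          de_log2_shift = -2, seed = 1) {
  stopifnot(n_proteins >= 1, n_replicates >= 2, length(conditions) >= 2,
            baseline_mean > 0, noise_sigma >= 0,
            de_fraction >= 0, de_fraction <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 conditions = conditions, baseline_mean = baseline_mean,
                 noise_sigma = noise_sigma, de_fraction = de_fraction,
                 de_log2_shift = de_log2_shift, seed = as.integer(seed)),
            class = "proteome_spec")
}

#' Generate a synthetic replicate proteome with known DE ground truth
#'
#' Intensities are drawn log-normally: protein mean times
#' `2^rnorm(0, noise_sigma)` per replicate. DE proteins (chosen by
#' `de_genes`, or sampled at `de_fraction` when `de_genes` is `NULL`)
#' have their mean multiplied by `2^de_log2_shift` in every non-control
#' condition, so at zero noise the condition/control mean ratio is
#' exactly `2^de_log2_shift`.
#'
#' @param spec A [proteome_spec()].
#' @param genes Optional protein/gene identifiers to include (e.g. a
#'   model's gene set); padded with generated ids up to `n_proteins`.
#' @param de_genes Optional explicit DE identities (overrides
#'   `de_fraction`).
#' @return A list: `table` (a [proteome_table()]) and `truth` (data.frame
#'   `protein_id`, `is_de`, `log2_shift`).
#' @export
make_proteome <- function(spec = proteome_spec(), genes = NULL,
                          de_genes = NULL) {
  stopifnot(inherits(spec, "proteome_spec"))
  if (!is.null(genes) && length(genes) > spec$n_proteins)
    stop("length(genes) exceeds n_proteins")
  n_extra <- spec$n_proteins - length(genes)
  proteins <- c(genes, if (n_extra > 0) sprintf("prot%04d", seq_len(n_extra)))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  if (is.null(de_genes)) {
    n_de <- round(spec$de_fraction * length(proteins))
    if (spec$de_fraction > 0 && n_de < 1)
      warning("de_fraction > 0 but rounds to zero DE proteins")
    de_genes <- sample(proteins, n_de)
  } else {
    if (!all(de_genes %in% proteins)) stop("de_genes must be among the proteins")
  }
  is_de <- proteins %in% de_genes
  control <- spec$conditions[1]
  rows <- expand.grid(protein_id = proteins, condition = spec$conditions,
                      replicate = seq_len(spec$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  shifted <- is_de[match(rows$protein_id, proteins)] & rows$condition != control
  mu <- spec$baseline_mean * 2^(ifelse(shifted, spec$de_log2_shift, 0))
  rows$intensity <- mu * 2^stats::rnorm(nrow(rows), 0, spec$noise_sigma)
  list(table = proteome_table(rows),
       truth = data.frame(protein_id = proteins, is_de = is_de,
                          log2_shift = ifelse(is_de, spec$de_log2_shift, 0)))
}

#' Write a proteome table to TSV
#'
#' @param table A [proteome_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(table, path) {
  table <- proteome_table(table)
  out <- table
  out$intensity <- num17(out$intensity)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a proteome table from TSV
#'
#' @param path A file written by [write_proteome()] (long form with
#'   columns `protein_id`, `condition`, `replicate`, `intensity`).
#' @return A [proteome_table()].
#' @export
read_proteome <- function(path) {
  proteome_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Generate a self-contained simulation fixture bundle
#'
#' Combines [make_toy_model()] and [make_proteome()] into a directory of
#' files exercising the full pipeline: `model.json`, `proteome.tsv`,
#' `annotation.tsv` (reaction id -> synthetic KEGG-style id) and
#' `truth.json` (the generator's ground truth: DE identities, the
#' analytic biomass optimum and minimal total flux). By default the
#' injected DE proteins are the genes gating the direct biomass route,
#' downregulated in the non-control conditions — so the bundle encodes a
#' temperature-stress-like scenario in which the stress proteome must
#' yield a lower simulated biomass than the control proteome.
#'
#' @param dir Output directory (created if needed).
#' @param model_spec A [toy_model_spec()].
#' @param proteome_spec_ A [proteome_spec()]; its `n_proteins` is raised
#'   to the model's gene count if smaller.
#' @param de_genes DE identities; default the model's biomass-path genes.
#' @return A list with the file `paths` and the in-memory `model`,
#'   `proteome`, `truth` objects.
#' @export
make_bundle <- function(dir, model_spec = toy_model_spec(),
                        proteome_spec_ = proteome_spec(),
                        de_genes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_model(model_spec)
  if (proteome_spec_$n_proteins < length(toy$model$genes))
    proteome_spec_$n_proteins <- length(toy$model$genes)
  if (is.null(de_genes)) de_genes <- toy$biomass_path_genes
  prot <- make_proteome(proteome_spec_, genes = toy$model$genes,
                        de_genes = de_genes)
  rids <- reaction_ids(toy$model)
  ann <- data.frame(reaction_id = rids,
                    kegg_id = sprintf("R%05d", seq_along(rids)))
  paths <- list(model = file.path(dir, "model.json"),
                proteome = file.path(dir, "proteome.tsv"),
                annotation = file.path(dir, "annotation.tsv"),
                truth = file.path(dir, "truth.json"))
  save_model(toy$model, paths$model, format = "json")
  write_proteome(prot$table, paths$proteome)
  utils::write.table(ann, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(known_optimum = toy$known_optimum,
                known_min_l1 = toy$known_min_l1,
                biomass_path_genes = toy$biomass_path_genes,
                de_proteins = prot$truth$protein_id[prot$truth$is_de],
                de_log2_shift = proteome_spec_$de_log2_shift,
                conditions = proteome_spec_$conditions,
                control = proteome_spec_$conditions[1])
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(paths = paths, model = toy$model, proteome = prot$table,
       truth = truth, annotation = ann,
       known_optimum = toy$known_optimum, known_min_l1 = toy$known_min_l1,
       biomass_path_genes = toy$biomass_path_genes)
}
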