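#' Assemble / validate a replicate proteome table
#'
#' The package's proteome container is a long-form data.frame with one row
#' per measured intensity: columns `protein_id`, `condition`, `replicate`
#' and `intensity`. Intensities must be strictly positive (zero or missing
#' measurements are outside scope; drop them upstream).
#'
#' @param x A data.frame with the four columns above (extra columns are
#'   dropped).
#' @return The checked table, classed `"proteome_table"`.
#' @export
proteome_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("protein_id", "condition", "replicate", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("proteome table missing column(s): ", paste(miss, collapse = ", "))
  x <- x[, need]
  x$intensity <- as.numeric(x$intensity)
  if (anyNA(x$intensity) || any(x$intensity <= 0))
    stop("proteome intensities must be strictly positive and non-missing")
  class(x) <- c("proteome_table", "data.frame")
  x
}

#' Normalize replicate intensity columns
#'
#' Rescales each replicate column (a `condition` x `replicate` pair) so
#' that a column-level statistic is equal across all columns of the table,
#' removing between-run loading/acquisition differences before fold
#' changes are computed. The common target is the smallest column
#' statistic, so scaling factors are always <= 1 (columns are scaled down
#' to the least intense run, the usual convention for intensity
#' proteomics).
#'
#' @param raw A [proteome_table()].
#' @param method `"total_intensity"` (equalize column sums; default),
#'   `"median"` (equalize column medians) or `"none"` (identity).
#' @return A [proteome_table()] with rescaled intensities.
#' @export
#' @examples
#' tab <- proteome_table(data.frame(
#'   protein_id = rep(c("p1", "p2"), 2),
#'   condition = "T35", replicate = rep(1:2, each = 2),
#'   intensity = c(40, 60, 80, 120)))
#' normalize_proteome(tab)  # replicate 2 scaled by 0.5
normalize_proteome <- function(raw, method = c("total_intensity", "median", "none")) {
  method <- match.arg(method)
  raw <- proteome_table(raw)
  if (method == "none") return(raw)
  stat <- switch(method, total_intensity = sum, median = stats::median)
  key <- interaction(raw$condition, raw$replicate, drop = TRUE)
  colstat <- tapply(raw$intensity, key, stat)
  target <- min(colstat)
  raw$intensity <- raw$intensity * (target / colstat[key])
  proteome_table(raw)
}

protein_means <- function(table, condition) {
  sel <- table$condition == condition
  m <- tapply(table$intensity[sel], table$protein_id[sel], mean)
  stats::setNames(as.numeric(m), dimnames(m)[[1]])
}

#' Per-protein log2 fold change between two conditions
#'
#' For each protein present in both conditions, computes
#' `log2(mean(condition) / mean(control))` over replicate intensities.
#' Proteins missing from either condition are excluded with a message.
#'
#' @param table A [proteome_table()] (normalize first; see
#'   [normalize_proteome()]).
#' @param condition,control Condition labels present in the table.
#' @return Named numeric vector of log2 fold changes.
#' @export
compute_log2fc <- function(table, condition, control) {
  table <- proteome_table(table)
  for (lab in c(condition, control))
    if (!lab %in% table$condition) stop("condition not in table: ", lab)
  mc <- protein_means(table, condition)
  m0 <- protein_means(table, control)
  shared <- intersect(names(mc), names(m0))
  dropped <- setdiff(union(names(mc), names(m0)), shared)
  if (length(dropped) > 0)
    message(length(dropped), " protein(s) absent from one condition, excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  fc <- log2(mc[shared] / m0[shared])
  names(fc) <- shared
  fc
}

#' Select differentially expressed proteins
#'
#' Applies the two-part rule used to pick expression constraints: a
#' protein is differentially expressed (DE) between `condition` and
#' `control` when its absolute log2 fold change exceeds `fc_threshold`
#' *and* its two-sample t-test p-value is below `alpha`. The test is
#' Welch's unequal-variance t-test on replicate intensities by default.
#' The fold-change threshold is on the log2 scale (the default 1.2
#' corresponds to a ~2.3-fold change) and is applied two-sided.
#'
#' Proteins with fewer than 2 replicates in either group are excluded
#' with a warning (the t-test is undefined for them).
#'
#' @inheritParams compute_log2fc
#' @param fc_threshold Minimum |log2 fold change|; default 1.2.
#' @param alpha Significance level on the (optionally adjusted) p-value;
#'   default 0.05.
#' @param p_adjust `"none"` (default, raw p-values) or `"BH"`
#'   (Benjamini-Hochberg across the tested proteins).
#' @param var_equal Passed to [stats::t.test()]; `FALSE` (Welch) by
#'   default.
#' @return A data.frame with one row per tested protein: `protein_id`,
#'   `log2_fold_change`, `p_value`, `is_de`.
#' @export
select_de <- function(table, condition, control, fc_threshold = 1.2,
                      alpha = 0.05, p_adjust = c("none", "BH"),
                      var_equal = FALSE) {
  p_adjust <- match.arg(p_adjust)
  table <- proteome_table(table)
  fc <- compute_log2fc(table, condition, control)
  ids <- names(fc)
  n_cond <- table(factor(table$protein_id[table$condition == condition], ids))
  n_ctrl <- table(factor(table$protein_id[table$condition == control], ids))
  testable <- ids[n_cond >= 2 & n_ctrl >= 2]
  if (length(testable) < length(ids))
    warning(length(ids) - length(testable),
            " protein(s) with < 2 replicates per group excluded from the t-test")
  pvals <- vapply(testable, function(pid) {
    x <- table$intensity[table$protein_id == pid & table$condition == condition]
    y <- table$intensity[table$protein_id == pid & table$condition == control]
    stats::t.test(x, y, var.equal = var_equal)$p.value
  }, 0)
  if (p_adjust == "BH") pvals <- stats::p.adjust(pvals, method = "BH")
  res <- data.frame(protein_id = testable,
                    log2_fold_change = unname(fc[testable]),
                    p_value = unname(pvals),
                    row.names = NULL)
  res$is_de <- abs(res$log2_fold_change) > fc_threshold & res$p_value < alpha
  res
}

#' Build an expression map for one condition
#'
#' The expression map carries, per protein/gene, the level `p` used as a
#' flux bound magnitude by [apply_eflux()]: the mean normalized intensity
#' of that protein in the chosen condition. When `de_only = TRUE` only
#' proteins flagged DE (in the `de` table from [select_de()]) are kept,
#' matching the practice of constraining the model with the significantly
#' DE proteins only.
#'
#' @inheritParams compute_log2fc
#' @param de_only Restrict the map to DE proteins?
#' @param de Required when `de_only = TRUE`: a [select_de()] result.
#' @return Named non-negative numeric vector (protein/gene id -> level).
#' @export
to_expression_map <- function(table, condition, de_only = FALSE, de = NULL) {
  table <- proteome_table(table)
  if (!condition %in% table$condition) stop("condition not in table: ", condition)
  p <- protein_means(table, condition)
  if (de_only) {
    if (is.null(de)) stop("de_only = TRUE requires a select_de() result in 'de'")
    p <- p[names(p) %in% de$protein_id[de$is_de]]
  }
  if (length(p) == 0)
    warning("empty expression map: the model will be largely unconstrained")
  out <- as.numeric(p)
  names(out) <- names(p)
  out
}
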