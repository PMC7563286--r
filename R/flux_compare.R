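#' Log2 / SD transform of a flux distribution
#'
#' Prepares one condition's fluxes for cross-condition comparison:
#' strictly positive fluxes are log2-transformed and divided by the
#' standard deviation of the log2 values of that dataset's positive
#' fluxes (so each dataset's transformed values have unit SD); fluxes
#' less than or equal to zero cannot be log-transformed and are carried
#' through unchanged with a `nonpositive` flag, to be reported as their
#' own class downstream.
#'
#' @param fd An optimal [flux_distribution()].
#' @return A list with `table` (data.frame `reaction_id`, `flux`,
#'   `transformed`, `nonpositive`) and `sd` (the normalization constant).
#' @export
transform_flux <- function(fd) {
  stopifnot(inherits(fd, "flux_distribution"))
  if (fd$status != "optimal") stop("transform_flux requires an optimal solution")
  v <- fd$fluxes
  pos <- v > 0
  if (!any(pos)) {
    warning("all fluxes are nonpositive; empty transformed set")
    s <- NA_real_
  } else {
    lg <- log2(v[pos])
    s <- if (sum(pos) >= 2) stats::sd(lg) else NA_real_
    if (is.na(s) || s == 0) {
      warning("SD of log2 fluxes is degenerate (", sum(pos),
              " positive flux(es)); using 1")
      s <- 1
    }
  }
  tr <- rep(NA_real_, length(v))
  if (any(pos)) tr[pos] <- log2(v[pos]) / s
  list(table = data.frame(reaction_id = names(v), flux = unname(v),
                          transformed = tr, nonpositive = !pos,
                          row.names = NULL),
       sd = s)
}

#' Per-reaction fold changes between two flux distributions
#'
#' The fold change of reaction `i` is the difference of the
#' SD-normalized log2 fluxes, `transformed_b - transformed_a` (see
#' [transform_flux()]; each distribution is normalized with its own SD).
#' Reactions nonpositive in either distribution get `NA` and are
#' classified `"nonpositive"` downstream rather than compared
#' numerically.
#'
#' @param fd_a Baseline (control) [flux_distribution()].
#' @param fd_b Comparison [flux_distribution()]; must cover the same
#'   reaction set.
#' @return Named numeric vector of fold changes (`NA` where either flux
#'   is nonpositive), with the two SDs in attributes `sd_a`, `sd_b`.
#' @export
fold_changes <- function(fd_a, fd_b) {
  ids_a <- names(fd_a$fluxes); ids_b <- names(fd_b$fluxes)
  if (!setequal(ids_a, ids_b) || length(ids_a) != length(ids_b)) {
    diff <- union(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
    stop("mismatched reaction sets; symmetric difference: ",
         paste(diff, collapse = ", "))
  }
  ta <- transform_flux(fd_a)
  tb <- transform_flux(fd_b)
  ord <- match(ids_a, tb$table$reaction_id)
  fc <- tb$table$transformed[ord] - ta$table$transformed
  names(fc) <- ids_a
  attr(fc, "sd_a") <- ta$sd
  attr(fc, "sd_b") <- tb$sd
  fc
}

#' Data-driven significance cut-off for flux fold changes
#'
#' Scans an ordered grid of candidate cut-offs and returns the smallest
#' candidate `c` for which the proportion of reactions with `|fc| > c`
#' falls below `max_proportion` of the total reaction number, i.e. the
#' least stringent cut-off under which fewer than (by default) 30% of
#' reactions are called significantly changed. The exceedance proportion
#' is non-increasing in `c`, so this minimal candidate is well defined.
#'
#' @param fcs Per-reaction fold changes ([fold_changes()]); `NA` entries
#'   (nonpositive reactions) count in the total but can never exceed a
#'   cut-off.
#' @param max_proportion Maximum tolerated affected fraction, default
#'   0.30.
#' @param grid Increasing candidate cut-offs; default `0.001` steps from
#'   0 to the largest |fold change|.
#' @return The selected cut-off (a single non-negative number).
#' @export
determine_cutoff <- function(fcs, max_proportion = 0.30, grid = NULL) {
  a <- abs(fcs[is.finite(fcs)])
  if (length(a) == 0) stop("no finite fold changes")
  n_total <- length(fcs)
  if (is.null(grid)) grid <- unique(c(seq(0, max(a), by = 0.001), max(a)))
  grid <- sort(grid)
  prop <- cutoff_exceedance(fcs, grid)
  ok <- prop < max_proportion
  if (!any(ok))
    stop("no grid candidate keeps the affected proportion below ",
         max_proportion, "; extend the grid")
  grid[which(ok)[1]]
}

#' @rdname determine_cutoff
#' @param cutoffs Cut-off values at which to evaluate the exceedance
#'   proportion `#{|fc| > c} / n_total`.
#' @return For `cutoff_exceedance`, the proportion at each cut-off.
#' @export
cutoff_exceedance <- function(fcs, cutoffs) {
  a <- sort(abs(fcs[is.finite(fcs)]))
  n_total <- length(fcs)
  # count of |fc| > c via binary search on the sorted magnitudes
  (length(a) - findInterval(cutoffs, a)) / n_total
}

#' Classify reactions by flux fold change
#'
#' Assigns each reaction one of four classes: `"up"` (`fc > cutoff`),
#' `"down"` (`fc < -cutoff`), `"unchanged"` (|fc| within the cut-off) or
#' `"nonpositive"` (flux <= 0 in either condition, excluded from the
#' numeric comparison). These are the four colour classes used on
#' metabolic-map overlays (blue / red / light green / gray).
#'
#' @param fcs Fold changes from [fold_changes()].
#' @param cutoff Non-negative significance cut-off (e.g. from
#'   [determine_cutoff()]).
#' @param fd_a,fd_b Optionally, the two distributions, to carry raw
#'   fluxes into the result table.
#' @param conditions Length-2 character vector of condition labels.
#' @return A `"flux_comparison"`: list with `table` (data.frame
#'   `reaction_id`, `flux_a`, `flux_b`, `fold_change`, `class`), `cutoff`,
#'   `sd_a`, `sd_b`, `conditions`.
#' @export
classify <- function(fcs, cutoff, fd_a = NULL, fd_b = NULL,
                     conditions = c("a", "b")) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) || cutoff < 0)
    stop("cutoff must be a single non-negative number")
  cls <- ifelse(!is.finite(fcs), "nonpositive",
         ifelse(fcs > cutoff, "up",
         ifelse(fcs < -cutoff, "down", "unchanged")))
  tab <- data.frame(reaction_id = names(fcs),
                    flux_a = if (is.null(fd_a)) NA_real_ else
                      unname(fd_a$fluxes[names(fcs)]),
                    flux_b = if (is.null(fd_b)) NA_real_ else
                      unname(fd_b$fluxes[names(fcs)]),
                    fold_change = unname(fcs),
                    class = unname(cls),
                    row.names = NULL)
  structure(list(table = tab, cutoff = cutoff,
                 sd_a = attr(fcs, "sd_a"), sd_b = attr(fcs, "sd_b"),
                 conditions = conditions),
            class = "flux_comparison")
}

#' @export
print.flux_comparison <- function(x, ...) {
  counts <- table(factor(x$table$class,
                         c("up", "down", "unchanged", "nonpositive")))
  cat(sprintf("<flux_comparison> %s vs %s, cutoff=%.4g | up=%d down=%d unchanged=%d nonpositive=%d\n",
              x$conditions[1], x$conditions[2], x$cutoff,
              counts["up"], counts["down"], counts["unchanged"],
              counts["nonpositive"]))
  invisible(x)
}

#' Compare two flux distributions end to end
#'
#' Convenience composition of [fold_changes()], [determine_cutoff()] and
#' [classify()].
#'
#' @inheritParams fold_changes
#' @inheritParams determine_cutoff
#' @param cutoff Optional fixed cut-off overriding the data-driven one.
#' @param conditions Labels for the two distributions.
#' @return A `"flux_comparison"` (see [classify()]).
#' @export
compare_fluxes <- function(fd_a, fd_b, max_proportion = 0.30, cutoff = NULL,
                           conditions = c("a", "b")) {
  fcs <- fold_changes(fd_a, fd_b)
  if (is.null(cutoff)) cutoff <- determine_cutoff(fcs, max_proportion)
  classify(fcs, cutoff, fd_a = fd_a, fd_b = fd_b, conditions = conditions)
}

#' Correlation between two flux distributions
#'
#' @inheritParams fold_changes
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The correlation coefficient over shared reactions, or `NA`
#'   (with a warning) when undefined (constant vector).
#' @export
flux_correlation <- function(fd_a, fd_b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(names(fd_a$fluxes), names(fd_b$fluxes))
  if (length(shared) < 3) stop("need at least 3 shared reactions")
  x <- fd_a$fluxes[shared]; y <- fd_b$fluxes[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: constant flux vector")
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' Pathway- and category-level summary of a flux comparison
#'
#' Aggregates the per-reaction classes over the model's `subsystem`
#' annotations (unannotated reactions fall into `"unassigned"`) and over
#' its category tags (`carbon`, `nitrogen`, `anabolic`, `catabolic`,
#' `exchange`). A reaction is *affected* when classed up or down. The C/N
#' ratio is the affected proportion among carbon-tagged reactions divided
#' by that among nitrogen-tagged reactions (the inverse is also
#' reported); values are `NA` when a denominator is zero or no reaction
#' carries the tag.
#'
#' @param cmp A `"flux_comparison"` (see [classify()]).
#' @param model The [metabolic_model()] carrying the annotations.
#' @return A `"pathway_summary"`: list with data.frames `pathways` and
#'   `categories` (columns `n_total`, `n_up`, `n_down`, `n_unchanged`,
#'   `n_nonpositive`, `pct_affected`), plus `cn_ratio` and `nc_ratio`.
#' @export
pathway_summary <- function(cmp, model) {
  stopifnot(inherits(cmp, "flux_comparison"))
  tab <- cmp$table
  rx <- model$reactions[match(tab$reaction_id, reaction_ids(model))]
  subsys <- vapply(rx, function(r)
    if (is.na(r$subsystem) || !nzchar(r$subsystem)) "unassigned" else r$subsystem, "")

  count_block <- function(groups) {
    lv <- sort(unique(unlist(groups$keys)))
    rows <- lapply(lv, function(g) {
      sel <- groups$member(g)
      cl <- tab$class[sel]
      n <- sum(sel)
      aff <- sum(cl %in% c("up", "down"))
      data.frame(group = g, n_total = n, n_up = sum(cl == "up"),
                 n_down = sum(cl == "down"),
                 n_unchanged = sum(cl == "unchanged"),
                 n_nonpositive = sum(cl == "nonpositive"),
                 pct_affected = if (n > 0) 100 * aff / n else NA_real_)
    })
    do.call(rbind, rows)
  }

  pathways <- count_block(list(keys = list(subsys),
                               member = function(g) subsys == g))
  names(pathways)[1] <- "pathway"

  cats <- lapply(rx, `[[`, "categories")
  all_tags <- c("carbon", "nitrogen", "anabolic", "catabolic", "exchange")
  categories <- count_block(list(
    keys = list(intersect(all_tags, unique(unlist(cats)))),
    member = function(g) vapply(cats, function(cc) g %in% cc, TRUE)))
  if (!is.null(categories)) names(categories)[1] <- "category"

  affected_prop <- function(tag) {
    if (is.null(categories) || !tag %in% categories$category) return(NA_real_)
    row <- categories[categories$category == tag, ]
    if (row$n_total == 0) return(NA_real_)
    (row$n_up + row$n_down) / row$n_total
  }
  pc <- affected_prop("carbon"); pn <- affected_prop("nitrogen")
  cn <- if (is.na(pc) || is.na(pn) || pn == 0) NA_real_ else pc / pn
  nc <- if (is.na(pc) || is.na(pn) || pc == 0) NA_real_ else pn / pc

  structure(list(pathways = pathways, categories = categories,
                 cn_ratio = cn, nc_ratio = nc),
            class = "pathway_summary")
}

#' @export
print.pathway_summary <- function(x, ...) {
  cat("<pathway_summary>\n")
  print(x$pathways, row.names = FALSE)
  if (!is.null(x$categories)) print(x$categories, row.names = FALSE)
  cat(sprintf("  C/N affected ratio: %.4g (N/C: %.4g)\n", x$cn_ratio, x$nc_ratio))
  invisible(x)
}

#' Export a flux comparison as a KEGG Mapper colour file
#'
#' Writes the two-column text accepted by the KEGG Mapper "Color" tool:
#' one line per annotated reaction, `KEGG-id  colour`, with blue for
#' upregulated, red for downregulated, lightgreen for unchanged and gray
#' for nonpositive reactions. Reactions without a KEGG annotation are
#' omitted (their count is reported in a message).
#'
#' @param cmp A `"flux_comparison"`.
#' @param annotation Mapping from reaction id to KEGG reaction/KO id: a
#'   named character vector, or a data.frame with columns `reaction_id`
#'   and `kegg_id`.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
kegg_export <- function(cmp, annotation, path) {
  stopifnot(inherits(cmp, "flux_comparison"))
  if (is.data.frame(annotation)) {
    ann <- annotation$kegg_id
    names(ann) <- annotation$reaction_id
  } else ann <- annotation
  colours <- c(up = "blue", down = "red", unchanged = "lightgreen",
               nonpositive = "gray")
  tab <- cmp$table
  mapped <- tab$reaction_id %in% names(ann)
  if (any(!mapped))
    message(sum(!mapped), " reaction(s) without KEGG annotation omitted")
  lines <- sprintf("%s %s", ann[tab$reaction_id[mapped]],
                   colours[tab$class[mapped]])
  writeLines(lines, path)
  invisible(path)
}

#' Export a flux comparison table to TSV
#'
#' @param cmp A `"flux_comparison"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(cmp, path) {
  utils::write.table(cmp$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
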