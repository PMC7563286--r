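fd_of <- function(v, stage = "pfba") {
  flux_distribution(v, objective_value = sum(v), status = "optimal",
                    stage = stage)
}

test_that("the log2/SD transform follows its definition", {
  v <- c(r1 = 4, r2 = 8, r3 = 0, r4 = -2)
  tr <- transform_flux(fd_of(v))
  s <- sd(log2(c(4, 8)))
  expect_equal(tr$sd, s)
  expect_equal(tr$table$transformed[1:2], c(2, 3) / s)
  # nonpositive fluxes: original value carried, flagged
  expect_true(all(tr$table$nonpositive[3:4]))
  expect_equal(tr$table$flux[3:4], c(0, -2))
  expect_true(all(is.na(tr$table$transformed[3:4])))
  # transformed positives have SD exactly 1 on random vectors
  set.seed(9)
  for (i in 1:5) {
    rv <- rlnorm(30, 0, 1)
    names(rv) <- sprintf("r%02d", 1:30)
    tri <- transform_flux(fd_of(rv))
    expect_equal(sd(tri$table$transformed), 1, tolerance = 1e-12)
  }
  expect_warning(transform_flux(fd_of(c(a = 0, b = -1))), "nonpositive")
})

test_that("fold changes difference the per-dataset transforms and are antisymmetric", {
  va <- c(r1 = 4, r2 = 16, r3 = 0)
  vb <- c(r1 = 8, r2 = 4, r3 = 2)
  fc <- fold_changes(fd_of(va), fd_of(vb))
  sa <- sd(log2(c(4, 16))); sb <- sd(log2(c(8, 4, 2)))
  expect_equal(fc[["r1"]], log2(8) / sb - log2(4) / sa)
  expect_true(is.na(fc[["r3"]]))
  # identical distributions: all zero
  expect_equal(unname(fold_changes(fd_of(va), fd_of(va)))[1:2], c(0, 0))
  # antisymmetry
  rev <- fold_changes(fd_of(vb), fd_of(va))
  expect_equal(fc[1:2], -rev[1:2])
  expect_error(fold_changes(fd_of(va), fd_of(c(r1 = 1, rX = 2, r3 = 3))),
               "r2.*rX|rX.*r2")
})

test_that("the cut-off search returns the minimal grid candidate under the cap", {
  fcs <- c(a = 0, b = 0, c = 0, d = 5)
  # only d strictly exceeds c = 0, so 1/4 < 0.30 holds at the smallest
  # grid candidate already
  expect_identical(determine_cutoff(fcs), 0)
  expect_identical(determine_cutoff(c(a = 0, b = 0)), 0)
  # brute-force agreement on random vectors
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(40, 0, 2)
    names(x) <- sprintf("r%02d", 1:40)
    grid <- seq(0, max(abs(x)) + 0.001, by = 0.001)
    got <- determine_cutoff(x, grid = grid)
    brute <- grid[sapply(grid, function(cc) mean(abs(x) > cc) < 0.30)][1]
    expect_identical(got, brute)
  }
  expect_error(determine_cutoff(c(a = NA_real_)), "finite")
})

test_that("exceedance is non-increasing in the cut-off", {
  set.seed(22)
  x <- rnorm(100, 0, 1.5)
  grid <- seq(0, 6, by = 0.01)
  prop <- cutoff_exceedance(x, grid)
  expect_true(all(diff(prop) <= 0))
  # and agrees with direct counting
  expect_equal(prop[50], mean(abs(x) > grid[50]))
})

test_that("classification respects the cut-off symmetric in sign", {
  fcs <- c(up1 = 1.5, dn1 = -1.5, un1 = 0.3, un2 = -1.206, np = NA)
  cmp <- classify(fcs, cutoff = 1.206)
  expect_identical(cmp$table$class,
                   c("up", "down", "unchanged", "unchanged", "nonpositive"))
  # classes partition the reaction set
  expect_identical(nrow(cmp$table), length(fcs))
  expect_error(classify(fcs, cutoff = -1), "non-negative")
})

test_that("flux correlations agree with a hand-coded reference", {
  set.seed(31)
  va <- rlnorm(20); names(va) <- sprintf("r%02d", 1:20)
  vb <- va * rlnorm(20, 0, 0.3)
  expect_equal(flux_correlation(fd_of(va), fd_of(va)), 1)
  neg <- -va; names(neg) <- names(va)
  expect_equal(flux_correlation(fd_of(va), fd_of(neg)), -1)
  expect_equal(flux_correlation(fd_of(va), fd_of(vb)),
               pearson_oracle(va, vb), tolerance = 1e-10)
  expect_equal(flux_correlation(fd_of(va), fd_of(vb), method = "spearman"),
               cor(rank(va), rank(vb)), tolerance = 1e-10)
  expect_warning(
    flux_correlation(fd_of(c(a = 1, b = 1, c = 1)), fd_of(c(a = 1, b = 2, c = 3))),
    "constant")
})

test_that("pathway and category summaries count what the hand count says", {
  # 2 carbon reactions (1 up) vs 4 nitrogen reactions (1 up): affected
  # proportions 50% and 25%, C/N ratio 2
  rx <- c(list(reaction("c1", c(M = 1), subsystem = "glycolysis",
                        categories = "carbon"),
               reaction("c2", c(M = 1), subsystem = "glycolysis",
                        categories = "carbon")),
          lapply(1:4, function(i)
            reaction(paste0("n", i), c(M = 1), subsystem = "nitrogen assim",
                     categories = "nitrogen")),
          list(reaction("BIO", c(M = -1), objective_coefficient = 1,
                        subsystem = "biomass")))
  m <- metabolic_model(data.frame(id = "M"), rx, "BIO")
  fcs <- c(c1 = 2, c2 = 0, n1 = 2, n2 = 0, n3 = 0, n4 = -0.1, BIO = NA)
  cmp <- classify(fcs, cutoff = 1)
  ps <- pathway_summary(cmp, m)
  gly <- ps$pathways[ps$pathways$pathway == "glycolysis", ]
  expect_identical(gly$n_total, 2L)
  expect_identical(gly$n_up, 1L)
  expect_equal(gly$pct_affected, 50)
  nit <- ps$categories[ps$categories$category == "nitrogen", ]
  expect_equal(nit$pct_affected, 25)
  expect_equal(ps$cn_ratio, 2)
  expect_equal(ps$nc_ratio, 0.5)
  # counts sum to totals in every pathway
  with(ps$pathways, expect_equal(n_up + n_down + n_unchanged + n_nonpositive,
                                 n_total))
  # all-unchanged comparison: zero affected everywhere, C/N undefined
  cmp0 <- classify(setNames(rep(0, 7), names(fcs)), cutoff = 1)
  ps0 <- pathway_summary(cmp0, m)
  expect_true(all(ps0$pathways$pct_affected == 0))
  expect_true(is.na(ps0$cn_ratio))
})

test_that("KEGG export writes one coloured line per annotated reaction", {
  fcs <- c(r1 = 2, r2 = -2, r3 = 0, r4 = NA)
  cmp <- classify(fcs, cutoff = 1.206)
  ann <- c(r1 = "R00243", r2 = "R00001", r3 = "R00002", r4 = "R00003")
  path <- withr::local_tempfile(fileext = ".txt")
  kegg_export(cmp, ann, path)
  lines <- readLines(path)
  expect_identical(lines[1], "R00243 blue")
  expect_identical(lines, c("R00243 blue", "R00001 red", "R00002 lightgreen",
                            "R00003 gray"))
  # partial annotation: omitted lines are counted, output length matches
  expect_message(kegg_export(cmp, ann[1:2], path), "2 reaction")
  expect_identical(length(readLines(path)), 2L)
  expect_message(kegg_export(cmp, character(), path), "4 reaction")
  expect_identical(length(readLines(path)), 0L)
})
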