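make_tab <- function(intensity, proteins = c("p1", "p2"), conditions = "T35",
                     replicates = NULL) {
  if (is.null(replicates))
    replicates <- length(intensity) / (length(proteins) * length(conditions))
  proteome_table(data.frame(
    protein_id = proteins,
    condition = rep(conditions, each = length(proteins)),
    replicate = rep(seq_len(replicates),
                    each = length(proteins) * length(conditions)),
    intensity = intensity))
}

test_that("normalization equalizes the column statistic", {
  tab <- make_tab(c(40, 60, 80, 120))  # replicate totals 100 and 200
  expect_identical(normalize_proteome(tab, method = "none"), tab)
  norm <- normalize_proteome(tab, method = "total_intensity")
  # second replicate column scaled by 0.5
  expect_equal(norm$intensity, c(40, 60, 40, 60))
  # hand-scaled 3-protein table with a known 3x loading artifact
  tab3 <- proteome_table(data.frame(
    protein_id = rep(c("a", "b", "c"), 2), condition = "T35",
    replicate = rep(1:2, each = 3),
    intensity = c(1, 2, 3, 3 * c(1, 2, 3))))
  norm3 <- normalize_proteome(tab3)
  expect_equal(norm3$intensity, rep(c(1, 2, 3), 2))
  med <- normalize_proteome(tab3, method = "median")
  expect_equal(as.numeric(tapply(med$intensity, med$replicate, median)),
               c(2, 2))
  expect_error(proteome_table(data.frame(protein_id = "a", condition = "x",
                                         replicate = 1, intensity = 0)),
               "positive")
})

test_that("log2 fold changes match their definition and are antisymmetric", {
  tab <- make_tab(c(4, 16, 8, 4), conditions = c("T35", "T22"),
                  replicates = 1)
  fc <- suppressMessages(compute_log2fc(tab, "T22", "T35"))
  expect_equal(fc, c(p1 = 1, p2 = -2))
  expect_equal(suppressMessages(compute_log2fc(tab, "T35", "T35")),
               c(p1 = 0, p2 = 0))
  # antisymmetry and brute-force recomputation on a random table
  set.seed(11)
  big <- proteome_table(data.frame(
    protein_id = rep(sprintf("p%02d", 1:20), each = 6),
    condition = rep(rep(c("T35", "T40"), each = 3), 20),
    replicate = rep(1:3, 40),
    intensity = rlnorm(120, 3, 0.5)))
  fwd <- compute_log2fc(big, "T40", "T35")
  rev <- compute_log2fc(big, "T35", "T40")
  expect_equal(fwd, -rev[names(fwd)])
  for (pid in c("p03", "p17")) {
    x <- big$intensity[big$protein_id == pid & big$condition == "T40"]
    y <- big$intensity[big$protein_id == pid & big$condition == "T35"]
    expect_equal(fwd[[pid]], log2(mean(x) / mean(y)))
  }
})

test_that("the DE rule combines the fold-change and p-value thresholds", {
  # p1: 2^1.5-fold shift with tiny variance -> DE; p2: 2-fold (log2 fc = 1.0,
  # below the 1.2 threshold) -> not DE despite a tiny p-value
  eps <- c(-0.001, 0, 0.001)
  tab <- proteome_table(data.frame(
    protein_id = rep(rep(c("p1", "p2"), each = 3), 2),
    condition = rep(c("T35", "T22"), each = 6),
    replicate = rep(1:3, 4),
    intensity = c(1 + eps, 1 + eps, 2^1.5 * (1 + eps), 2 * (1 + eps))))
  de <- select_de(tab, "T22", "T35")
  expect_identical(de$is_de[de$protein_id == "p1"], TRUE)
  expect_lt(de$p_value[de$protein_id == "p2"], 0.001)
  expect_identical(de$is_de[de$protein_id == "p2"], FALSE)
  # the flag is exactly the conjunction of the two thresholds
  expect_identical(de$is_de, abs(de$log2_fold_change) > 1.2 & de$p_value < 0.05)
})

test_that("t-test p-values match a hand-coded Welch reference to 1e-10", {
  set.seed(5)
  prot <- make_proteome(proteome_spec(n_proteins = 30, de_fraction = 0.2,
                                      de_log2_shift = 1, seed = 5))
  de <- select_de(prot$table, "T22", "T35")
  for (i in seq_len(nrow(de))) {
    pid <- de$protein_id[i]
    x <- prot$table$intensity[prot$table$protein_id == pid &
                                prot$table$condition == "T22"]
    y <- prot$table$intensity[prot$table$protein_id == pid &
                                prot$table$condition == "T35"]
    expect_equal(de$p_value[i], welch_p(x, y), tolerance = 1e-10)
  }
})

test_that("proteins lacking replicates are excluded with a warning", {
  tab <- proteome_table(data.frame(
    protein_id = c(rep("p1", 6), "p2", "p2"),
    condition = c(rep(c("T35", "T22"), each = 3), "T35", "T22"),
    replicate = c(rep(1:3, 2), 1, 1),
    intensity = abs(rnorm(8)) + 1))
  expect_warning(de <- select_de(tab, "T22", "T35"), "< 2 replicates")
  expect_identical(de$protein_id, "p1")
})

test_that("expression maps carry condition means, optionally DE-restricted", {
  tab <- make_tab(c(4, 16, 8, 4), conditions = c("T35", "T22"), replicates = 1)
  m <- to_expression_map(tab, "T22")
  expect_equal(m, c(p1 = 8, p2 = 4))
  de <- data.frame(protein_id = c("p1", "p2"), is_de = c(TRUE, FALSE))
  m_de <- to_expression_map(tab, "T22", de_only = TRUE, de = de)
  expect_equal(m_de, c(p1 = 8))
  expect_warning(
    to_expression_map(tab, "T22", de_only = TRUE,
                      de = data.frame(protein_id = character(),
                                      is_de = logical())),
    "unconstrained")
})
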