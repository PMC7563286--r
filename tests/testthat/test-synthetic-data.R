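test_that("toy models validate and carry their analytic optima", {
  toy <- make_toy_model(toy_model_spec(n_linear_chain = 3, exchange_cap = 10))
  expect_true(is_valid_model(toy$model))
  expect_identical(toy$known_optimum, 10)
  expect_identical(toy$known_min_l1, 10 * (3 + 2))
  expect_equal(solve_fba(toy$model)$objective_value, 10)
  # with a two-reaction detour parallel to a chain step, the enumerated
  # minimal-L1 routing goes through the direct step: the analytic value
  # does not grow
  toy2 <- make_toy_model(toy_model_spec(n_linear_chain = 3,
                                        n_parallel_paths = 1))
  pf <- minimize_total_flux(toy2$model,
                            z_opt = solve_fba(toy2$model)$objective_value)
  expect_equal(pf$total_flux, toy2$known_min_l1, tolerance = 1e-6)
})

test_that("generation is deterministic: same spec, byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec_m <- toy_model_spec(seed = 7)
  spec_p <- proteome_spec(seed = 7)
  b1 <- make_bundle(d1, spec_m, spec_p)
  b2 <- make_bundle(d2, spec_m, spec_p)
  for (f in names(b1$paths))
    expect_identical(readLines(b1$paths[[f]]), readLines(b2$paths[[f]]))
  # a different proteome seed changes the proteome but not the model
  b3 <- make_bundle(withr::local_tempdir(), spec_m, proteome_spec(seed = 8))
  expect_identical(readLines(b1$paths$model), readLines(b3$paths$model))
  expect_false(identical(readLines(b1$paths$proteome),
                         readLines(b3$paths$proteome)))
})

test_that("noiseless DE injection shifts condition means exactly", {
  prot <- make_proteome(proteome_spec(n_proteins = 10, noise_sigma = 0,
                                      de_fraction = 0.5, de_log2_shift = 1,
                                      seed = 3))
  tab <- prot$table
  for (pid in prot$truth$protein_id) {
    ratio <- mean(tab$intensity[tab$protein_id == pid & tab$condition == "T22"]) /
      mean(tab$intensity[tab$protein_id == pid & tab$condition == "T35"])
    expect_equal(ratio, if (prot$truth$is_de[prot$truth$protein_id == pid]) 2 else 1)
  }
})

test_that("with no injected signal the t-test p-values are calibrated", {
  # de_fraction = 0: the rate of p < alpha should sit near alpha
  # (binomial tolerance +- 2 SE over 200 null proteins)
  prot <- make_proteome(proteome_spec(n_proteins = 200, n_replicates = 3,
                                      noise_sigma = 0.2, de_fraction = 0,
                                      seed = 17))
  de <- select_de(prot$table, "T22", "T35")
  alpha <- 0.05
  se <- sqrt(alpha * (1 - alpha) / nrow(de))
  expect_lt(abs(mean(de$p_value < alpha) - alpha), 2 * se + 1e-12)
  # and none is flagged DE (the fold-change gate is far from 1.2)
  expect_identical(sum(de$is_de), 0L)
})

test_that("bundles drive the full pipeline and encode the stress narrative", {
  dir <- withr::local_tempdir()
  bundle <- make_bundle(dir, toy_model_spec(seed = 2), proteome_spec(seed = 2))
  model <- load_model(bundle$paths$model)
  tab <- normalize_proteome(read_proteome(bundle$paths$proteome))
  de <- select_de(tab, "T22", "T35")
  # the injected DE proteins (biomass-path genes) are recovered
  expect_setequal(de$protein_id[de$is_de], bundle$truth$de_proteins)
  m_ctrl <- to_expression_map(tab, "T35", de_only = TRUE, de = de)
  m_str <- to_expression_map(tab, "T22", de_only = TRUE, de = de)
  fd_ctrl <- simulate_fluxes(model, m_ctrl)
  fd_str <- simulate_fluxes(model, m_str)
  # downshifted biomass-path expression lowers the simulated biomass
  expect_lt(fd_str$objective_value, fd_ctrl$objective_value)
  # comparison + pathway summary + KEGG export run end to end
  cmp <- suppressWarnings(compare_fluxes(fd_ctrl, fd_str,
                                         conditions = c("T35", "T22")))
  expect_identical(nrow(cmp$table), length(model$reactions))
  ps <- pathway_summary(cmp, model)
  expect_true(all(ps$pathways$n_total > 0))
  kegg <- file.path(dir, "kegg.txt")
  kegg_export(cmp, bundle$annotation, kegg)
  expect_identical(length(readLines(kegg)), length(model$reactions))
})

test_that("a bundle with no DE proteins compares a condition with itself", {
  dir <- withr::local_tempdir()
  bundle <- make_bundle(dir, toy_model_spec(seed = 4),
                        proteome_spec(seed = 4, de_fraction = 0),
                        de_genes = character())
  model <- load_model(bundle$paths$model)
  tab <- normalize_proteome(read_proteome(bundle$paths$proteome))
  m_ctrl <- to_expression_map(tab, "T35")
  m_str <- to_expression_map(tab, "T22")
  fd_ctrl <- simulate_fluxes(model, m_ctrl)
  fd_str <- simulate_fluxes(model, m_str)
  fcs <- suppressWarnings(fold_changes(fd_ctrl, fd_str))
  for (cutoff in c(0.01, 0.5, 1.206)) {
    cmp <- classify(fcs, cutoff)
    expect_identical(sum(cmp$table$class %in% c("up", "down")), 0L)
  }
})
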