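test_that("FBA solves the hand-solved chain LP", {
  # uptake capped at 10, conversion at 20, biomass at 30: Z* = 10 with all
  # three fluxes at 10 (unique vertex)
  m <- hand_chain_model(10, 20, 30)
  fd <- solve_fba(m)
  expect_identical(fd$status, "optimal")
  expect_equal(fd$objective_value, 10)
  expect_equal(unname(fd$fluxes), c(10, 10, 10))
  # bottleneck moves with the tightest bound
  expect_equal(solve_fba(hand_chain_model(50, 7, 30))$objective_value, 7)
})

test_that("a closed system carries zero flux and a forced demand is infeasible", {
  m <- hand_chain_model(0, 20, 30)  # exchange shut
  fd <- solve_fba(m)
  expect_identical(fd$status, "optimal")
  expect_equal(fd$objective_value, 0)
  expect_equal(max(abs(fd$fluxes)), 0)

  m2 <- hand_chain_model(0, 20, 30)
  m2$reactions[[3]]$lower_bound <- 1  # biomass demanded with no source
  fd2 <- solve_fba(m2)
  expect_identical(fd2$status, "infeasible")
  expect_true(all(is.na(fd2$fluxes)))
})

test_that("optimal solutions are mass balanced within 1e-6", {
  for (i in 1:8) {
    toy <- make_toy_model(random_toy_spec(100 + i))
    b <- apply_eflux(toy$model, random_levels(toy$model, 100 + i))
    for (fd in list(solve_fba(toy$model, b),
                    simulate_fluxes(toy$model,
                                    random_levels(toy$model, 100 + i)))) {
      expect_identical(fd$status, "optimal")
      S <- stoichiometric_matrix(toy$model)
      expect_lt(max(abs(as.numeric(S %*% fd$fluxes))), 1e-6)
      idx <- match(names(fd$fluxes), b$reaction_id)
      expect_true(all(fd$fluxes >= b$lower_bound[idx] - 1e-6 &
                        fd$fluxes <= b$upper_bound[idx] + 1e-6))
    }
  }
})

test_that("the L1 stage routes flux through the direct path", {
  toy <- make_toy_model(toy_model_spec(n_linear_chain = 3,
                                       n_parallel_paths = 1, n_cycles = 0))
  fba <- solve_fba(toy$model)
  pf <- minimize_total_flux(toy$model, z_opt = fba$objective_value)
  expect_equal(pf$objective_value, toy$known_optimum, tolerance = 1e-6)
  # detour reactions idle; the analytically enumerated minimal L1 is attained
  expect_equal(unname(pf$fluxes[c("PD1a", "PD1b")]), c(0, 0), tolerance = 1e-9)
  expect_equal(pf$total_flux, toy$known_min_l1, tolerance = 1e-6)
})

test_that("the L1 stage silences futile cycles", {
  toy <- make_toy_model(toy_model_spec(n_linear_chain = 2,
                                       n_parallel_paths = 0, n_cycles = 1))
  fba <- solve_fba(toy$model)
  pf <- minimize_total_flux(toy$model, z_opt = fba$objective_value)
  expect_equal(max(abs(pf$fluxes[c("CY1a", "CY1b", "CY1c")])), 0,
               tolerance = 1e-9)
})

test_that("pFBA preserves biomass and never increases total flux", {
  for (i in 1:6) {
    toy <- make_toy_model(random_toy_spec(200 + i))
    lv <- random_levels(toy$model, 200 + i)
    b <- apply_eflux(toy$model, lv)
    fba <- solve_fba(toy$model, b)
    pf <- minimize_total_flux(toy$model, b, z_opt = fba$objective_value)
    expect_identical(pf$status, "optimal")
    expect_gte(pf$objective_value, fba$objective_value - 1e-6)
    expect_lte(pf$total_flux, sum(abs(fba$fluxes)) + 1e-9)
  }
  # an already-unique optimum is left untouched
  m <- hand_chain_model(10, 20, 30)
  fba <- solve_fba(m)
  pf <- minimize_total_flux(m, z_opt = fba$objective_value)
  expect_equal(pf$fluxes, fba$fluxes, tolerance = 1e-6)
})

test_that("gamma relaxes the biomass constraint of the L1 stage", {
  toy <- make_toy_model(toy_model_spec())
  fba <- solve_fba(toy$model)
  pf <- minimize_total_flux(toy$model, z_opt = fba$objective_value,
                            gamma = 0.5)
  expect_gte(pf$objective_value, 0.5 * fba$objective_value - 1e-6)
  expect_lte(pf$total_flux,
             minimize_total_flux(toy$model,
                                 z_opt = fba$objective_value)$total_flux + 1e-9)
  expect_error(minimize_total_flux(toy$model, z_opt = 1, gamma = 0), "gamma")
})

test_that("the exclusion list drops reactions from the minimized sum", {
  toy <- make_toy_model(toy_model_spec())
  fba <- solve_fba(toy$model)
  pf <- minimize_total_flux(toy$model, z_opt = fba$objective_value,
                            exclude = "EX_SRC")
  expect_equal(pf$total_flux,
               sum(abs(pf$fluxes[names(pf$fluxes) != "EX_SRC"])))
})

test_that("solver objectives match the independent LP oracle", {
  for (i in 1:15) {
    toy <- make_toy_model(random_toy_spec(300 + i))
    b <- apply_eflux(toy$model, random_levels(toy$model, 300 + i))
    z <- solve_fba(toy$model, b)$objective_value
    z_ref <- lp_oracle_objective(toy$model, b)
    expect_equal(z, z_ref, tolerance = 1e-6)
  }
})

test_that("the composed simulation reproduces the generator's optimum", {
  toy <- make_toy_model(toy_model_spec())
  # saturating expression on every gene: biomass capped by the exchange
  lv <- rep(1000, length(toy$model$genes))
  names(lv) <- toy$model$genes
  wt <- simulate_fluxes(toy$model, lv)
  expect_identical(wt$stage, "pfba")
  expect_equal(wt$objective_value, toy$known_optimum, tolerance = 1e-6)
  # severing the biomass path abolishes growth
  ko <- simulate_fluxes(toy$model, lv, knockouts = "R2")
  expect_equal(ko$objective_value, 0, tolerance = 1e-9)
  # overexpression by factor 1 is the identity perturbation
  oe1 <- simulate_fluxes(toy$model, lv, overexpressions = "R2", oe_factor = 1)
  expect_equal(oe1$fluxes, wt$fluxes, tolerance = 1e-9)
})
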