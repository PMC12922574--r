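test_that("Fisher information: structure, scale law and conditioning", {
  st <- liver_state(dT2 = 30)
  Fi <- fisher_information(st, b_set("liver_consensus"), c(50, 60, 100),
                           sigma = 0.025)
  expect_equal(dim(Fi), c(5L, 5L))
  expect_equal(Fi, t(Fi), tolerance = 1e-10)
  expect_true(all(eigen(Fi, symmetric = TRUE, only.values = TRUE)$values > 0))
  # doubling sigma divides every entry by four
  Fi2 <- fisher_information(st, b_set("liver_consensus"), c(50, 60, 100),
                            sigma = 0.05)
  expect_equal(Fi2, Fi / 4, tolerance = 1e-10)
  expect_true(is.finite(attr(Fi, "condition")))
  # per-b averages enter as diagonal weights: doubling all averages
  # doubles the information
  Fw <- fisher_information(st, b_set("liver_consensus"), c(50, 60, 100),
                           sigma = 0.025, averages = rep(2L, 6))
  expect_equal(Fw, 2 * Fi, tolerance = 1e-10)
  expect_error(fisher_information(st, c(0, 10), 50, 0.025), "more points")
})

test_that("CRLB of f: positivity and monotone gain from added echo times", {
  st <- liver_state(dT2 = 30)
  b <- b_set("liver_consensus")
  sd3 <- crlb_sd_f(st, b, c(50, 60, 100), 0.025)
  expect_gt(sd3, 0)
  # adding a design point never increases the bound (information adds)
  sd4 <- crlb_sd_f(st, b, c(50, 60, 80, 100), 0.025,
                   reference_te = 50)
  expect_lte(sd4, sd3 + 1e-12)
  # sd scales linearly in sigma
  expect_equal(crlb_sd_f(st, b, c(50, 60, 100), 0.05),
               2 * sd3, tolerance = 1e-10)
})

test_that("nRMSE objective: permutation invariance, positivity, sigma scaling", {
  sp <- design_space(te_set("te2"), b_set("liver_consensus"), 3)
  v1 <- nrmse_objective(c(50, 60, 100), sp)
  expect_gt(v1, 0)
  expect_equal(nrmse_objective(c(100, 50, 60), sp), v1)
  sp2 <- sp; sp2$sigma <- 2 * sp$sigma
  expect_equal(nrmse_objective(c(50, 60, 100), sp2), 2 * v1,
               tolerance = 1e-10)
})

test_that("exhaustive search finds the printed in-vivo-space optimum", {
  sp <- design_space(te_set("te1"), b_set("invivo16"), 3)
  res <- optimize_tes_exhaustive(sp)
  expect_equal(res$te_subset, c(47, 67, 72))
  expect_equal(res$n_evals, 20L)
  # k = |candidates| returns the full set
  sp_all <- design_space(c(50, 60, 100), b_set("liver_consensus"), 3)
  expect_equal(optimize_tes_exhaustive(sp_all)$te_subset, c(50, 60, 100))
  expect_error(optimize_tes_exhaustive(sp, max_evals = 5), "budget")
})

test_that("consensus-space optimum spans TE 50 to 100", {
  sp <- design_space(te_set("te2"), b_set("liver_consensus"), 3)
  res <- optimize_tes_exhaustive(sp)
  expect_equal(res$n_evals, 165L)
  expect_equal(max(res$te_subset), 100)
  expect_equal(min(res$te_subset), 50)
})

test_that("genetic algorithm is seeded-deterministic and matches the oracle", {
  sp <- design_space(te_set("te1"), b_set("invivo16"), 3)
  opts <- ga_options(population = 100, generations = 30, seed = 7)
  g1 <- optimize_tes_ga(sp, opts)
  g2 <- optimize_tes_ga(sp, opts)
  expect_identical(g1$te_subset, g2$te_subset)
  expect_identical(g1$objective, g2$objective)
  ex <- optimize_tes_exhaustive(sp)
  for (seed in 1:3) {
    ga <- optimize_tes_ga(sp, ga_options(population = 100,
                                         generations = 30, seed = seed))
    expect_equal(ga$te_subset, ex$te_subset)
    expect_equal(ga$objective, ex$objective, tolerance = 1e-12)
  }
  # a different subset size on the same space
  sp2 <- design_space(te_set("te1"), b_set("invivo16"), 2)
  ex2 <- optimize_tes_exhaustive(sp2)
  ga2 <- optimize_tes_ga(sp2, ga_options(population = 100,
                                         generations = 30, seed = 1))
  expect_equal(ga2$te_subset, ex2$te_subset)
  # larger protocols are never worse than smaller ones at the optimum
  sp3 <- design_space(te_set("te1"), b_set("invivo16"), 4)
  ex3 <- optimize_tes_exhaustive(sp3)
  expect_lte(ex3$objective, ex$objective)
  expect_lte(ex$objective, ex2$objective)
})

test_that("Monte-Carlo protocol validation: deterministic limit and CRLB inequality", {
  sp <- design_space(te_set("te2"), b_set("liver_consensus"), 3,
                     sigma = 0.025)
  mc0 <- local({
    sp0 <- sp; sp0$sigma <- 0
    validate_protocol_mc(c(50, 60, 100), sp0, n_rep = 2)
  })
  expect_true(all(mc0$sd < 1e-12))
  # noisy validation: empirical SD respects the bound (within MC slop)
  mc <- validate_protocol_mc(c(50, 60, 100), sp, n_rep = 150, seed = 13)
  st <- sp$state
  st$relax <- relaxation_params(800, 800, 27, median(sp$t2_fluid_values))
  bound <- crlb_sd_f(st, sp$b_values, c(50, 60, 100), sp$sigma)
  expect_gt(mc$sd[["f"]], 0.8 * bound)
})
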