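test_that("noiseless dataset generation: anchor, shape and reductions", {
  st <- liver_state(dT1 = 300, dT2 = 20)
  grid <- acq_grid(b_set("invivo16"), te_set("te1"),
                   tr_values = seq(2000, 4000, by = 500))
  ds <- generate_dataset(st, grid)
  expect_equal(dim(ds$values), c(16, 6, 5))
  # normalization anchor: b = 0 at (reference TE, reference TR) is exactly 1
  expect_equal(ds$values[1, 1, 1], 1)
  # with equal relaxation times the b-profile equals the plain model
  ds0 <- generate_dataset(liver_state(), grid)
  expect_equal(unname(ds0$values[, 1, 1]),
               ivim_signal(liver_state()$ivim, grid$b_values),
               tolerance = 1e-12)
  expect_equal(ds0$values[grid$b_values == 100, 1, 1], 0.8189948,
               tolerance = 1e-6)
  # per-TE normalization pins every b = 0 value to 1
  dpt <- generate_dataset(st, grid, normalization = "per_te")
  expect_true(all(abs(dpt$values[1, , ] - 1) < 1e-12))
})

test_that("Rician corruption: zero-noise identity, reproducibility, positivity", {
  ds <- generate_dataset(liver_state(dT2 = 10), grid_invivo())
  expect_identical(add_rician_noise(ds, noise_model(0))$values, ds$values)
  n1 <- add_rician_noise(ds, noise_model(0.025, seed = 9))
  n2 <- add_rician_noise(ds, noise_model(0.025, seed = 9))
  expect_identical(n1$values, n2$values)
  expect_true(all(n1$values >= 0))
  expect_false(identical(n1$values,
                         add_rician_noise(ds, noise_model(0.025, seed = 10))$values))
  # snr bookkeeping
  expect_equal(noise_model(0.025)$snr_at_s0, 40)
  expect_equal(noise_model(0.03)$snr_at_s0, 1 / 0.03)
})

test_that("Rician noise floor at zero signal has mean sigma*sqrt(pi/2)", {
  set.seed(123)
  sigma <- 0.025
  n <- 1e5
  draws <- sqrt(rnorm(n, 0, sigma)^2 + rnorm(n, 0, sigma)^2)
  # mean sigma*sqrt(pi/2), SD sigma*sqrt(2 - pi/2) (Rayleigh closed form)
  se <- sigma * sqrt(2 - pi / 2) / sqrt(n)
  expect_lt(abs(mean(draws) - sigma * sqrt(pi / 2)), 3 * se)
  # the same holds through the dataset pathway
  zero_ds <- generate_dataset(liver_state(), grid_invivo())
  zero_ds$values[] <- 0
  noisy <- add_rician_noise(zero_ds, noise_model(sigma, seed = 1))
  expect_lt(abs(mean(noisy$values) - sigma * sqrt(pi / 2)),
            3 * sigma / sqrt(length(noisy$values)))
})

test_that("per-b averaging reduces the effective noise by sqrt(n_avg)", {
  grid <- acq_grid(b_set("invivo16"), 47, 4000,
                   averages = rep(4L, 16))
  ds <- generate_dataset(liver_state(), grid)
  set.seed(21)
  res_avg <- replicate(400, {
    add_rician_noise(ds, noise_model(0.02))$values[8, 1, 1]
  })
  grid1 <- acq_grid(b_set("invivo16"), 47, 4000)
  ds1 <- generate_dataset(liver_state(), grid1)
  res_one <- replicate(400, {
    add_rician_noise(ds1, noise_model(0.02))$values[8, 1, 1]
  })
  ratio <- sd(res_one) / sd(res_avg)
  expect_gt(ratio, 1.6)   # sqrt(4) = 2 within Monte-Carlo slop
  expect_lt(ratio, 2.5)
})

test_that("Monte-Carlo driver: deterministic at sigma = 0, recovery at SNR 40", {
  st <- liver_state(dT2 = 20)
  grid <- grid_invivo()
  mc0 <- run_monte_carlo(st, grid, noise_model(0), 3, mc_fitter_2d())
  expect_true(all(mc0$sd < 1e-12))
  expect_equal(mc0$n_fail, 0L)
  # noiseless 1D bias matches the closed-form oracle
  st5 <- liver_state(dT2 = 5)
  mc1 <- run_monte_carlo(st5, grid, noise_model(0), 1, mc_fitter_1d(52))
  expect_equal(mc1$bias_pct[["f"]],
               percent_bias(apparent_f(st5, 52, 4000), 0.095),
               tolerance = 1e-3)
  # parameter recovery with noise: mean f within its Monte-Carlo CI
  mc <- run_monte_carlo(st, grid, noise_model(0.025, seed = 4), 200,
                        mc_fitter_2d())
  ci_half <- 3 * mc$sd[["f"]] / sqrt(mc$n_rep - mc$n_fail)
  expect_lt(abs(mc$mean[["f"]] - 0.095), ci_half + 0.01)
})

test_that("ensemble comparison: effect size and one-sided F-test calibration", {
  fake <- function(x) structure(list(estimates = cbind(f = x)),
                                class = "mc_summary")
  set.seed(31)
  a <- fake(rnorm(500, sd = 8)); b <- fake(rnorm(500, sd = 10))
  cmp <- summarize_comparison(a, b)
  expect_equal(cmp$delta_sigma_pct, 100 * (cmp$sd_a - cmp$sd_b) / cmp$sd_b)
  expect_lt(cmp$p_value, 0.05)   # genuinely smaller variance detected
  # equal variances, large n: p close to 1/2 on average and the test holds
  # its nominal type-I error rate
  set.seed(32)
  pvals <- replicate(400, {
    summarize_comparison(fake(rnorm(300)), fake(rnorm(300)))$p_value
  })
  expect_lt(abs(mean(pvals) - 0.5), 0.05)
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.01)
  expect_error(summarize_comparison(fake(rep(1, 5)), fake(rep(2, 5))),
               "zero SD")
})

test_that("image phantom: constancy, truth maps and background floor", {
  grid <- grid_consensus(te_set("te1"))
  st <- s0_unit_observed(liver_state(dT2 = 30), 47)
  ph <- make_image_phantom(matrix("liver", 3, 3), list(liver = st), grid)
  nodes <- expand.grid(b = grid$b_values, te = grid$te_values)
  ser <- matrix(t2ivim_signal(st$ivim, st$relax$T2_tissue,
                              st$relax$T2_fluid, st$s0,
                              nodes$b, nodes$te),
                nrow = length(grid$b_values))
  for (iy in 1:3) expect_equal(ph$values[iy, 1, , ], ser,
                               tolerance = 1e-12, ignore_attr = TRUE)
  lay <- disc_layout(10)
  ph2 <- make_image_phantom(lay, list(liver = st), grid,
                            noise_model(0.025, seed = 2))
  expect_equal(unique(ph2$truth$f[lay == "liver"]), 0.095)
  expect_true(all(is.na(ph2$truth$f[lay == "background"])))
  bgidx <- which(lay == "background", arr.ind = TRUE)
  bgvals <- ph2$values[cbind(bgidx[, 1], bgidx[, 2], 1, 1)]
  expect_lt(abs(mean(bgvals) - 0.025 * sqrt(pi / 2)),
            4 * 0.025 / sqrt(length(bgvals)))
  expect_error(make_image_phantom(matrix("oops", 2, 2), list(liver = st),
                                  grid), "oops")
})
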