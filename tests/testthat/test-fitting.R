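test_that("1D fit recovers the generating parameters from clean biexponential data", {
  liver <- liver_state()
  b <- b_set("invivo16")
  y <- ivim_signal(liver$ivim, b)
  est <- coef(fit_ivim(y, b))
  expect_equal(est[["f"]], 0.095, tolerance = 1e-3)
  expect_equal(est[["D"]], 0.0010, tolerance = 1e-3)
  expect_equal(est[["D_star"]], 0.067, tolerance = 1e-3)
  # monoexponential input: the perfusion compartment vanishes
  y0 <- exp(-b * 0.0016)
  expect_lt(coef(fit_ivim(y0, b))[["f"]], 1e-3)
  # guards
  expect_error(fit_ivim(y[1:3], b[1:3]), "4 distinct")
  expect_error(fit_ivim(-y, b), "positive")
})

test_that("1D fit of relaxation-biased data lands on the apparent fraction", {
  st <- liver_state(dT2 = 5)
  ds <- generate_dataset(st, grid_invivo())
  ser <- extract_te_series(ds, 52)
  fit <- fit_ivim(ser$signals, ser$b_values)   # auto free scale
  expect_equal(coef(fit)[["f"]], 0.1242122, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("joint 2D fit recovers all five generative parameters from clean data", {
  st <- liver_state(dT1 = 0, dT2 = 25)
  ds <- generate_dataset(st, grid_invivo())
  fit <- fit_t2ivim(ds)
  est <- coef(fit)
  truth <- c(f = 0.095, D = 0.0010, D_star = 0.067,
             T2_tissue = 27, T2_fluid = 52)
  for (p in names(truth))
    expect_equal(est[[p]], truth[[p]], tolerance = 5e-3)
  expect_true(fit$converged)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  # free-S0 absolute-scale route recovers the same parameters
  abs_ds <- generate_dataset(st, grid_invivo(), normalization = "absolute")
  fit2 <- fit_t2ivim(abs_ds, fit_s0 = TRUE)
  for (p in names(truth))
    expect_equal(coef(fit2)[[p]], truth[[p]], tolerance = 5e-3)
})

test_that("2D fit identifiability guards", {
  st <- liver_state(dT2 = 25)
  single_te <- acq_grid(b_set("invivo16"), 52, 4000)
  expect_error(fit_t2ivim(generate_dataset(st, single_te)),
               "at least 2 echo times")
  per_te <- generate_dataset(st, grid_invivo(), normalization = "per_te")
  expect_error(fit_t2ivim(per_te), "allow_relative_t2")
  # opting in fits the reduced parametrization and still recovers f and
  # the transverse-rate difference
  fit <- fit_t2ivim(per_te, allow_relative_t2 = TRUE)
  expect_equal(coef(fit)[["f"]], 0.095, tolerance = 5e-3)
  expect_equal(coef(fit)[["dR2"]], 1 / 52 - 1 / 27, tolerance = 1e-3)
})

test_that("compartment-label repair keeps D* >= D", {
  # truth with an inverted T2 ordering (fluid T2 shorter than tissue T2)
  st <- tissue_state(ivim_params(0.12, 0.0012, 0.05),
                     relaxation_params(800, 800, 45, 30))
  ds <- generate_dataset(st, grid_invivo())
  fit <- fit_t2ivim(ds)
  est <- coef(fit)
  expect_gte(est[["D_star"]], est[["D"]])
  # the fitted signal still matches the data regardless of labeling
  expect_lt(max(abs(residuals(fit))), 1e-6)
  # symmetric truth: equal T2s recovered as (numerically) equal
  st_eq <- liver_state(dT2 = 0)
  fit_eq <- fit_t2ivim(generate_dataset(st_eq, grid_invivo()))
  expect_equal(coef(fit_eq)[["T2_tissue"]], coef(fit_eq)[["T2_fluid"]],
               tolerance = 0.05)
  expect_equal(coef(fit_eq)[["f"]], 0.095, tolerance = 0.01)
})

test_that("data-driven defaults are sensible and bracket their bounds", {
  b <- b_set("invivo16")
  liver <- liver_state()
  y <- ivim_signal(liver$ivim, b)
  o <- default_fit_options("ivim_1d", y, b)
  expect_true(all(o$start >= o$lower & o$start <= o$upper))
  expect_equal(o$start[["D"]], 0.0010, tolerance = 0.2)
  # monoexponential data: initial perfusion fraction collapses to the floor
  o0 <- default_fit_options("ivim_1d", exp(-b * 0.0016), b)
  expect_lte(o0$start[["f"]], 0.02)
  # 2D defaults include a plausible T2 from the b = 0 TE decay
  ds <- generate_dataset(liver_state(dT2 = 10), grid_invivo(),
                         normalization = "absolute")
  o2 <- default_fit_options("t2ivim_2d", ds$values[, , 1], b,
                            te_set("te1"), fit_s0 = TRUE)
  expect_true(all(o2$start >= o2$lower & o2$start <= o2$upper))
  expect_equal(o2$start[["T2_tissue"]], 27, tolerance = 0.35)
  expect_error(fit_options(c(f = 2), c(f = 0), c(f = 1)), "outside bounds")
})

test_that("model-object methods behave like a classic fitted model", {
  st <- liver_state(dT2 = 25)
  ds <- generate_dataset(st, grid_invivo())
  fit <- fit_t2ivim(ds)
  expect_s3_class(fit, "ivim_fit")
  expect_named(coef(fit), c("f", "D", "D_star", "T2_tissue", "T2_fluid"))
  expect_equal(fitted(fit) + residuals(fit), fit$data$y)
  expect_equal(predict(fit), fitted(fit))
  # prediction off the grid reproduces the forward model
  pr <- predict(fit, b = c(0, 300), te = c(47, 47))
  expect_equal(length(pr), 2L)
  expect_equal(pr[1], 1, tolerance = 1e-6)  # anchor point
  s <- summary(fit)
  expect_true(all(is.finite(s$coefficients[, "Std. Error"])))
  expect_output(print(fit), "T2-IVIM")
  # simulate draws noisy replicates of the fitted curve
  sim <- simulate(fit, nsim = 3, seed = 1, sigma = 0.02)
  expect_equal(dim(sim), c(length(fit$data$y), 3L))
  expect_true(all(sim >= 0))
})
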