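test_that("scheme files round-trip and shipped presets match the standard sets", {
  grid <- acq_grid(b_set("invivo16"), te_set("te1"), c(2000, 4000),
                   averages = c(rep(3L, 5), rep(4L, 7), rep(5L, 4)))
  f <- tempfile(fileext = ".yaml")
  write_scheme(grid, f, meta = list(note = "round trip"))
  back <- load_scheme(f)
  expect_equal(back$b_values, grid$b_values)
  expect_equal(back$te_values, grid$te_values)
  expect_equal(back$tr_values, grid$tr_values)
  expect_equal(back$averages, grid$averages)
  expect_equal(back$reference_te, grid$reference_te)
  # shipped presets
  cons <- load_scheme("liver_consensus")
  expect_equal(cons$b_values, c(0, 10, 20, 100, 200, 550))
  vivo <- load_scheme("invivo_16b_6te")
  expect_equal(vivo$te_values, seq(47, 72, 5))
  expect_equal(length(vivo$b_values), 16L)
})

test_that("malformed schemes fail with named-field errors", {
  write_bad <- function(doc) {
    f <- tempfile(fileext = ".yaml"); yaml::write_yaml(doc, f); f
  }
  expect_error(load_scheme(write_bad(list(b_values = c(-5, 0, 10),
                                          te_values = 50))),
               "b_values")
  expect_error(load_scheme(write_bad(list(b_values = c(10, 20, 30),
                                          te_values = 50))),
               "b = 0")
  expect_error(load_scheme(write_bad(list(b_values = c(0, 10),
                                          te_values = c(50, 50)))),
               "te_values")
  expect_error(load_scheme(write_bad(list(te_values = 50))), "b_values")
  expect_error(load_scheme(tempfile()), "not found")
})

test_that("signal tables round-trip across repetitions", {
  st <- liver_state(dT2 = 15)
  grid <- grid_consensus(te_set("te1"))
  clean <- generate_dataset(st, grid)
  reps <- lapply(1:3, function(i)
    add_rician_noise(clean, noise_model(0.02, seed = i)))
  f <- tempfile(fileext = ".tsv")
  write_signal_table(reps, f)
  back <- read_signal_table(f, grid)
  expect_equal(dim(back$values), c(6, 6, 1, 3))
  for (i in 1:3)
    expect_equal(back$values[, , 1, i], reps[[i]]$values[, , 1],
                 ignore_attr = TRUE, tolerance = 1e-12)
  # single dataset round trip
  f2 <- tempfile(fileext = ".tsv")
  write_signal_table(clean, f2)
  expect_equal(read_signal_table(f2, grid)$values[, , 1],
               clean$values[, , 1], ignore_attr = TRUE)
})

test_that("NIfTI stacks round-trip with the b-fastest volume ordering", {
  grid <- grid_consensus(te_set("te1"))
  st <- s0_unit_observed(liver_state(dT2 = 30), 47)
  ph <- make_image_phantom(disc_layout(8), list(liver = st), grid,
                           noise_model(0.02, seed = 3))
  nvol <- length(grid$b_values) * length(grid$te_values)
  flat <- array(ph$values, dim = c(8, 8, nvol))   # b fastest within TE
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(flat), f)
  stack <- read_image_stack(f, grid)
  expect_equal(stack$values, ph$values, ignore_attr = TRUE,
               tolerance = 1e-6)
  # volume-count mismatch is rejected with the expected/found counts
  bad <- array(flat[, , 1:(nvol - 1)], dim = c(8, 8, nvol - 1))
  f2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(bad), f2)
  expect_error(read_image_stack(f2, grid), "expected 36.*found 35")
})

test_that("parameter maps are written as one NIfTI per parameter plus ROI table", {
  grid <- grid_consensus(te_set("te1"))
  st <- s0_unit_observed(liver_state(dT2 = 30), 47)
  lay <- matrix("liver", 4, 4)
  maps <- ideal_fit_image(make_image_phantom(lay, list(liver = st), grid))
  prefix <- file.path(tempdir(), "maps_test")
  files <- write_maps(maps, prefix, labels = lay)
  expect_true(any(grepl("_f\\.nii\\.gz$", files)))
  expect_true(file.exists(paste0(prefix, "_roi.tsv")))
  fmap <- as.array(RNifti::readNifti(paste0(prefix, "_f.nii.gz")))
  expect_equal(matrix(fmap, 4, 4), maps$maps$f, tolerance = 1e-6)
})

test_that("command-line interface: seeded determinism and validation exit codes", {
  skip_if_not(nzchar(Sys.which("Rscript")))
  cli <- system.file("cli", "t2ivim.R", package = "t2ivim")
  skip_if_not(nzchar(cli))
  run_cli <- function(...) {
    suppressWarnings(system2("Rscript", c(cli, ...), stdout = TRUE,
                             stderr = FALSE))
  }
  out1 <- file.path(tempdir(), "sim1.tsv")
  out2 <- file.path(tempdir(), "sim2.tsv")
  status1 <- system2("Rscript", c(cli, "simulate", "--preset", "liver",
                                  "--scheme", "liver_consensus",
                                  "--snr", "40", "--nrep", "3",
                                  "--seed", "1", "--out", out1),
                     stdout = FALSE, stderr = FALSE)
  status2 <- system2("Rscript", c(cli, "simulate", "--preset", "liver",
                                  "--scheme", "liver_consensus",
                                  "--snr", "40", "--nrep", "3",
                                  "--seed", "1", "--out", out2),
                     stdout = FALSE, stderr = FALSE)
  expect_equal(status1, 0L)
  expect_equal(status2, 0L)
  expect_identical(readLines(out1), readLines(out2))
  # 2D fit on a single-TE table exits with the validation code
  grid1 <- acq_grid(b_set("liver_consensus"), 50, 4000)
  ds1 <- generate_dataset(liver_state(dT2 = 10), grid1)
  tab <- file.path(tempdir(), "single_te.tsv")
  write_signal_table(ds1, tab)
  scheme1 <- file.path(tempdir(), "single_te.yaml")
  write_scheme(grid1, scheme1)
  status3 <- system2("Rscript", c(cli, "fit", "--signals", tab,
                                  "--scheme", scheme1, "--mode", "2d",
                                  "--out", file.path(tempdir(), "f.json")),
                     stdout = FALSE, stderr = FALSE)
  expect_equal(status3, 2L)
})
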