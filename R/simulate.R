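#' Rician noise model
#'
#' Magnitude-image noise: a signal `v` is replaced by
#' `sqrt((v + n1)^2 + n2^2)` with `n1, n2 ~ Normal(0, sigma^2)`. `sigma` is
#' expressed on the normalized signal scale, so the signal-to-noise ratio at
#' S0 is exactly `1/sigma` (e.g. sigma 0.025 is SNR 40, sigma 0.03 is
#' SNR 33). At zero signal the Rician mean is `sigma * sqrt(pi/2)` — the
#' familiar background noise floor of magnitude MRI.
#'
#' @param sigma Noise SD on the normalized signal scale, `>= 0`.
#' @param seed Optional integer seed for reproducible draws.
#' @return An object of class `"noise_model"` with elements `sigma`,
#'   `snr_at_s0` (`1/sigma`, `Inf` when noiseless) and `seed`.
#' @export
noise_model <- function(sigma, seed = NULL) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  structure(list(sigma = sigma,
                 snr_at_s0 = if (sigma > 0) 1 / sigma else Inf,
                 seed = seed),
            class = "noise_model")
}

#' Generate a noiseless signal dataset over an acquisition grid
#'
#' Evaluates the relaxation-compensated forward model at every
#' (b, TE, TR) node of the grid and normalizes the whole array by the
#' b = 0 signal at the grid's normalization anchor
#' (`reference_te`, `reference_tr`). This "per-reference" normalization
#' keeps the absolute TE decay across echoes, which is what makes both
#' compartmental T2 values identifiable in the joint b-TE fit.
#'
#' @param state A [tissue_state()].
#' @param grid An [acq_grid()].
#' @param normalization `"per_reference"` (default; single anchor),
#'   `"per_te"` (each (TE, TR) column normalized by its own b = 0 value —
#'   the conventional IVIM convention, which destroys absolute T2
#'   information), or `"absolute"` (raw relaxation-weighted signal in `s0`
#'   units).
#' @return An object of class `"signal_dataset"`: a list with the values
#'   array (dim b x TE x TR), the grid, the normalization tag and the
#'   generating state.
#' @export
generate_dataset <- function(state, grid,
                             normalization = c("per_reference", "per_te",
                                               "absolute")) {
  stopifnot(inherits(state, "tissue_state"), inherits(grid, "acq_grid"))
  normalization <- match.arg(normalization)
  nodes <- expand.grid(b = grid$b_values, te = grid$te_values,
                       tr = grid$tr_values, KEEP.OUT.ATTRS = FALSE)
  raw <- relaxation_weighted_signal(state, nodes$b, nodes$te, nodes$tr)
  values <- array(raw, dim = c(length(grid$b_values), length(grid$te_values),
                               length(grid$tr_values)),
                  dimnames = list(b = grid$b_values, te = grid$te_values,
                                  tr = grid$tr_values))
  values <- switch(normalization,
    per_reference = values / relaxation_weighted_signal(
      state, 0, grid$reference_te, grid$reference_tr),
    per_te = sweep(values, 2:3, values[1, , , drop = FALSE], "/"),
    absolute = values)
  structure(list(values = values, grid = grid,
                 normalization = normalization, state = state),
            class = "signal_dataset")
}

#' @export
print.signal_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Signal dataset: %d b x %d TE x %d TR (%s normalization)\n",
              d[1], d[2], d[3], x$normalization))
  invisible(x)
}

# Draw Rician-corrupted magnitudes from noiseless values v.
rician_draw <- function(v, sigma) {
  sqrt((v + stats::rnorm(length(v), 0, sigma))^2 +
       stats::rnorm(length(v), 0, sigma)^2)
}

#' Add Rician noise to a signal dataset
#'
#' Replaces every value `v` by `sqrt((v + n1)^2 + n2^2)` with independent
#' Gaussian `n1, n2` of SD `sigma`. Noise is added on the dataset's own
#' (normalized) scale. When the grid specifies per-b averages, that many
#' independent Rician draws are averaged per point, reducing the effective
#' noise SD by `sqrt(n_avg)` (while keeping the small-signal Rician bias of
#' each draw).
#'
#' @param ds A [generate_dataset()] result.
#' @param noise A [noise_model()]. With `sigma = 0` the dataset is returned
#'   unchanged. A non-`NULL` `seed` makes the draw reproducible without
#'   disturbing the caller's RNG state.
#' @param use_averages Honour `grid$averages` if present (default TRUE).
#' @return A `signal_dataset` with noisy values (always `>= 0`).
#' @export
add_rician_noise <- function(ds, noise, use_averages = TRUE) {
  stopifnot(inherits(ds, "signal_dataset"), inherits(noise, "noise_model"))
  if (noise$sigma == 0) return(ds)
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(noise$seed)
  }
  avg <- if (use_averages && !is.null(ds$grid$averages))
    ds$grid$averages else rep(1L, length(ds$grid$b_values))
  v <- ds$values
  if (all(avg == 1L)) {
    v[] <- rician_draw(v, noise$sigma)
  } else {
    nav <- array(avg, dim = dim(v))  # averages vary along b (first margin)
    acc <- array(0, dim = dim(v))
    for (k in seq_len(max(avg))) {
      draw <- rician_draw(ds$values, noise$sigma)
      live <- nav >= k
      acc[live] <- acc[live] + draw[live]
    }
    v <- acc / nav
  }
  ds$values <- v
  ds
}

#' Monte-Carlo ensemble of noisy fits
#'
#' Draws `n_rep` independent Rician-noised replicates of the dataset
#' generated from `state` over `grid`, applies `fitter` to each, and
#' summarizes the per-parameter ensemble. Failed fits (errors or
#' non-convergence flagged by the fitter) are excluded and counted.
#'
#' @param state A [tissue_state()].
#' @param grid An [acq_grid()].
#' @param noise A [noise_model()]; its `seed` (if any) seeds the whole
#'   ensemble.
#' @param n_rep Number of repetitions, `>= 1`.
#' @param fitter Function taking a `signal_dataset` and returning a named
#'   numeric vector of estimates (e.g. a wrapper around [fit_ivim()] or
#'   [fit_t2ivim()]), with optional attribute `converged`.
#' @param truth Optional named vector of true values used for the percent
#'   bias; defaults to the generative parameters of `state`.
#' @param normalization Passed to [generate_dataset()].
#' @return An object of class `"mc_summary"`: per-parameter `mean`, `sd`,
#'   `bias_pct`, the retained estimates matrix, `n_rep`, `n_fail`.
#' @export
run_monte_carlo <- function(state, grid, noise, n_rep, fitter,
                            truth = NULL,
                            normalization = "per_reference") {
  stopifnot(n_rep >= 1)
  clean <- generate_dataset(state, grid, normalization = normalization)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  if (is.null(truth)) {
    truth <- c(f = state$ivim$f, D = state$ivim$D,
               D_star = state$ivim$D_star,
               T2_tissue = state$relax$T2_tissue,
               T2_fluid = state$relax$T2_fluid)
  }
  draws <- vector("list", n_rep)
  n_fail <- 0L
  for (i in seq_len(n_rep)) {
    noisy <- if (noise$sigma > 0)
      add_rician_noise(clean, noise_model(noise$sigma)) else clean
    est <- tryCatch(fitter(noisy), error = function(e) NULL)
    ok <- !is.null(est) && all(is.finite(est)) &&
      (is.null(attr(est, "converged")) || isTRUE(attr(est, "converged")))
    if (ok) draws[[i]] <- est else n_fail <- n_fail + 1L
  }
  est <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  if (is.null(est) || nrow(est) == 0L)
    stop("all ", n_rep, " Monte-Carlo repetitions failed to fit")
  mu <- colMeans(est)
  sdv <- apply(est, 2, stats::sd)
  common <- intersect(names(mu), names(truth))
  bias <- rep(NA_real_, length(mu)); names(bias) <- names(mu)
  bias[common] <- percent_bias(mu[common], truth[common])
  structure(list(mean = mu, sd = sdv, bias_pct = bias,
                 estimates = est, truth = truth,
                 n_rep = n_rep, n_fail = n_fail),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Monte-Carlo summary over %d repetitions (%d failed)\n",
              x$n_rep, x$n_fail))
  tab <- rbind(mean = x$mean, sd = x$sd, `bias (%)` = x$bias_pct)
  print(signif(tab, digits))
  invisible(x)
}

#' Compare two Monte-Carlo ensembles: effect size and one-sided F-test
#'
#' For a given parameter, computes the relative SD difference
#' `delta_sigma = 100 * (sd_a - sd_b) / sd_b` (percent; negative means `a`
#' is less variable) and a one-sided F-test of H1: `sigma_a < sigma_b`
#' using the variance ratio with `(n_a - 1, n_b - 1)` degrees of freedom.
#'
#' @param a,b [run_monte_carlo()] summaries of the same parameter.
#' @param parameter Parameter name to compare (default `"f"`).
#' @return A list with `delta_sigma_pct`, `p_value`, `sd_a`, `sd_b`,
#'   `df` (the two degrees of freedom).
#' @export
summarize_comparison <- function(a, b, parameter = "f") {
  stopifnot(inherits(a, "mc_summary"), inherits(b, "mc_summary"))
  xa <- a$estimates[, parameter]; xb <- b$estimates[, parameter]
  if (length(xa) < 2L || length(xb) < 2L)
    stop("need at least two retained repetitions in each ensemble")
  sda <- stats::sd(xa); sdb <- stats::sd(xb)
  if (sdb == 0) stop("reference ensemble has zero SD; ratio undefined")
  ratio <- (sda / sdb)^2
  df <- c(length(xa) - 1L, length(xb) - 1L)
  list(delta_sigma_pct = 100 * (sda - sdb) / sdb,
       p_value = stats::pf(ratio, df[1], df[2]),
       sd_a = sda, sd_b = sdb, df = df)
}

#' Synthetic multi-(b, TE) image phantom
#'
#' Builds a voxel-wise 4D image stack (y, x, b, TE) from a region-label
#' layout and per-region tissue states, using the T2-compensated forward
#' model ([t2ivim_signal()]) with each region's `s0`, then adds Rician
#' noise. Regions labelled `"background"` get zero signal (pure noise
#' floor). True parameter maps are attached for benchmarking.
#'
#' @param layout Integer or character matrix of region labels.
#' @param states Named list of [tissue_state()] keyed by region label;
#'   a `"background"` label needs no state.
#' @param grid An [acq_grid()] (its TR is ignored by the T2-only model).
#' @param noise A [noise_model()].
#' @return An object of class `"image_stack"`: `values` (4D array
#'   y x x x b x TE), `grid`, `truth` (list of parameter matrices), `mask`
#'   (TRUE where not background).
#' @export
make_image_phantom <- function(layout, states, grid, noise = noise_model(0)) {
  stopifnot(is.matrix(layout), inherits(grid, "acq_grid"))
  labs <- unique(as.vector(layout))
  unknown <- setdiff(setdiff(labs, "background"), names(states))
  if (length(unknown))
    stop("no tissue state for region label(s): ",
         paste(unknown, collapse = ", "))
  nb <- length(grid$b_values); nte <- length(grid$te_values)
  ny <- nrow(layout); nx <- ncol(layout)
  vals <- array(0, dim = c(ny, nx, nb, nte))
  pars <- c("f", "D", "D_star", "T2_tissue", "T2_fluid", "s0")
  truth <- stats::setNames(
    lapply(pars, function(p) matrix(NA_real_, ny, nx)), pars)
  nodes <- expand.grid(b = grid$b_values, te = grid$te_values,
                       KEEP.OUT.ATTRS = FALSE)
  for (lab in setdiff(labs, "background")) {
    st <- states[[lab]]
    series <- t2ivim_signal(st$ivim, st$relax$T2_tissue, st$relax$T2_fluid,
                            st$s0, nodes$b, nodes$te)
    idx <- which(layout == lab, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      vals[idx[r, 1], idx[r, 2], , ] <- series
    truth$f[idx] <- st$ivim$f; truth$D[idx] <- st$ivim$D
    truth$D_star[idx] <- st$ivim$D_star
    truth$T2_tissue[idx] <- st$relax$T2_tissue
    truth$T2_fluid[idx] <- st$relax$T2_fluid
    truth$s0[idx] <- st$s0
  }
  if (noise$sigma > 0) {
    if (!is.null(noise$seed)) set.seed(noise$seed)
    vals[] <- rician_draw(vals, noise$sigma)
  }
  structure(list(values = vals, grid = grid, truth = truth,
                 mask = layout != "background"),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Image stack: %d x %d voxels, %d b x %d TE volumes\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
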