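#' Fitting options for the IVIM and T2-IVIM least-squares fits
#'
#' Start values, box bounds and solver controls for the bounded nonlinear
#' least-squares fits. Most users never call this directly:
#' [default_fit_options()] derives data-driven starts and physical bounds.
#'
#' @param start Named numeric vector of initial values.
#' @param lower,upper Named numeric vectors of box bounds; must bracket
#'   `start`.
#' @param max_iter Maximum solver iterations.
#' @param ftol Relative reduction tolerance on the sum of squares.
#' @return An object of class `"fit_options"`.
#' @export
fit_options <- function(start, lower, upper, max_iter = 300, ftol = 1e-12) {
  stopifnot(is.numeric(start), !is.null(names(start)),
            length(lower) == length(start), length(upper) == length(start))
  lower <- lower[names(start)]; upper <- upper[names(start)]
  if (any(start < lower | start > upper)) {
    bad <- names(start)[start < lower | start > upper]
    stop("start values outside bounds for: ", paste(bad, collapse = ", "))
  }
  if (ftol <= 0) stop("'ftol' must be positive")
  structure(list(start = start, lower = lower, upper = upper,
                 max_iter = as.integer(max_iter), ftol = ftol),
            class = "fit_options")
}

# Global physical bounds shared by all fits.
.param_bounds <- function() {
  list(lower = c(f = 0, D = 1e-5, D_star = 1e-5,
                 T2_tissue = 5, T2_fluid = 5, S0 = 1e-8, dR2 = -0.2),
       upper = c(f = 1, D = 5e-3, D_star = 0.5,
                 T2_tissue = 500, T2_fluid = 500, S0 = Inf, dR2 = 0.2))
}

#' Data-driven default fitting options
#'
#' Builds [fit_options()] from the data: `D` from a log-linear fit over the
#' high-b regime (b >= 200 s/mm^2, or the upper half of the b range when
#' fewer than two such points exist), `f` from the gap between the b = 0
#' signal and the back-extrapolated monoexponential intercept,
#' `D* = 10 D`, and (for the joint model) both T2 values from the
#' log-linear TE decay of the b = 0 signals. Bounds are global physical
#' ranges: f in \[0, 1\], D in \[1e-5, 5e-3\], D* in \[1e-5, 0.5\] mm^2/s,
#' T2 in \[5, 500\] ms.
#'
#' @param model `"ivim_1d"` (per-TE biexponential) or `"t2ivim_2d"` (joint
#'   b-TE model).
#' @param signals Signal values: a vector over `b_values` for `"ivim_1d"`,
#'   a b x TE matrix for `"t2ivim_2d"`.
#' @param b_values b-values in s/mm^2.
#' @param te_values Echo times in ms (2D model only).
#' @param fit_s0 Include a free scale `S0`.
#' @return A [fit_options()] object.
#' @export
default_fit_options <- function(model = c("ivim_1d", "t2ivim_2d"), signals,
                                b_values, te_values = NULL, fit_s0 = FALSE) {
  model <- match.arg(model)
  bnd <- .param_bounds()
  if (model == "ivim_1d") {
    y <- as.numeric(signals)
  } else {
    signals <- as.matrix(signals)
    y <- signals[, 1]  # shortest TE column seeds the diffusion parameters
  }
  if (length(y) != length(b_values))
    stop("signal length does not match b_values")
  hi <- b_values >= 200
  if (sum(hi) < 2) hi <- b_values >= stats::median(b_values)
  ll <- stats::lm.fit(cbind(1, b_values[hi]), log(pmax(y[hi], 1e-12)))
  cf <- unname(ll$coefficients)
  D0 <- min(max(-cf[2], 2e-5), 4.5e-3)
  s0_b0 <- unname(y[b_values == 0][1])
  f0 <- 1 - exp(cf[1]) / s0_b0
  f0 <- min(max(f0, 0.01), 0.6)
  Ds0 <- min(max(10 * D0, 5e-3), 0.45)
  if (model == "ivim_1d") {
    start <- c(f = f0, D = D0, D_star = Ds0)
    if (fit_s0) start <- c(start, S0 = s0_b0)
  } else {
    if (is.null(te_values) || length(te_values) != ncol(signals))
      stop("'te_values' must match the columns of the signal matrix")
    y0 <- pmax(signals[which(b_values == 0)[1], ], 1e-12)
    t2fit <- stats::lm.fit(cbind(1, te_values), log(y0))
    T2hat <- -1 / min(unname(t2fit$coefficients[2]), -1 / 480)
    T2hat <- min(max(T2hat, 6), 480)
    start <- c(f = f0, D = D0, D_star = Ds0,
               T2_tissue = T2hat,
               T2_fluid = min(max(1.3 * T2hat, 6), 480))
    if (fit_s0)
      start <- c(start, S0 = s0_b0 * exp(min(te_values) / T2hat))
  }
  keep <- names(start)
  upper <- bnd$upper[keep]
  if (fit_s0) upper["S0"] <- 20 * max(start["S0"], 1)
  fit_options(start = start, lower = bnd$lower[keep], upper = upper)
}

# Forward model + Jacobian over flattened (b, te) points, parameters as a
# named vector p over any subset of (f, D, D_star, T2_tissue, T2_fluid, S0).
# Absent T2 entries mean the plain biexponential; absent S0 means scale 1.
.model_eval <- function(p, b, te = NULL) {
  S0 <- if ("S0" %in% names(p)) p[["S0"]] else 1
  A <- if (!is.null(te)) exp(-te / p[["T2_tissue"]]) else 1
  B <- if (!is.null(te)) exp(-te / p[["T2_fluid"]]) else 1
  eD <- exp(-b * p[["D"]]); eDs <- exp(-b * p[["D_star"]])
  S0 * ((1 - p[["f"]]) * A * eD + p[["f"]] * B * eDs)
}

.model_jac <- function(p, b, te = NULL) {
  S0 <- if ("S0" %in% names(p)) p[["S0"]] else 1
  A <- if (!is.null(te)) exp(-te / p[["T2_tissue"]]) else 1
  B <- if (!is.null(te)) exp(-te / p[["T2_fluid"]]) else 1
  eD <- exp(-b * p[["D"]]); eDs <- exp(-b * p[["D_star"]])
  J <- cbind(
    f = S0 * (-A * eD + B * eDs),
    D = -S0 * (1 - p[["f"]]) * A * b * eD,
    D_star = -S0 * p[["f"]] * B * b * eDs)
  if (!is.null(te)) {
    J <- cbind(J,
      T2_tissue = S0 * (1 - p[["f"]]) * A * (te / p[["T2_tissue"]]^2) * eD,
      T2_fluid = S0 * p[["f"]] * B * (te / p[["T2_fluid"]]^2) * eDs)
  }
  if ("S0" %in% names(p))
    J <- cbind(J, S0 = ((1 - p[["f"]]) * A * eD + p[["f"]] * B * eDs))
  J[, names(p), drop = FALSE]
}

# Anchor-normalized forward model: the plain model divided by its own
# b = 0 value at the reference TE — the simulation normalization, which
# removes the scale parameter while keeping absolute TE decay.
.model_eval_anchored <- function(p, b, te, te_ref) {
  .model_eval(p, b, te) / .model_eval(p, 0, te_ref)
}

.model_jac_anchored <- function(p, b, te, te_ref) {
  m0 <- .model_eval(p, 0, te_ref)
  J0 <- .model_jac(p, 0, te_ref)
  m <- .model_eval(p, b, te)
  (.model_jac(p, b, te) - (m / m0) %o% drop(J0)) / m0
}

# Bounded Levenberg-Marquardt driver shared by the 1D and 2D fits.
.lm_fit <- function(y, b, te, options, weights = NULL, te_ref = NULL) {
  w <- if (is.null(weights)) rep(1, length(y)) else sqrt(weights)
  res_fn <- function(par) {
    p <- stats::setNames(par, names(options$start))
    m <- if (is.null(te_ref)) .model_eval(p, b, te)
         else .model_eval_anchored(p, b, te, te_ref)
    w * (m - y)
  }
  jac_fn <- function(par) {
    p <- stats::setNames(par, names(options$start))
    J <- if (is.null(te_ref)) .model_jac(p, b, te)
         else .model_jac_anchored(p, b, te, te_ref)
    w * J
  }
  out <- minpack.lm::nls.lm(
    par = options$start, lower = options$lower, upper = options$upper,
    fn = res_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = options$max_iter, ftol = options$ftol, ptol = 1e-12))
  est <- stats::setNames(out$par, names(options$start))
  list(estimates = est, deviance = out$deviance,
       converged = out$info %in% 1:4, info = out$info,
       message = out$message, niter = out$niter)
}

# Compartment-label repair: the biexponential is symmetric under the full
# relabeling (f, D, D*, T2t, T2f) -> (1-f, D*, D, T2f, T2t), which leaves
# the fitted signal unchanged. Enforce D* >= D; for the joint model prefer
# the labeling with T2_fluid >= T2_tissue when it also keeps D* >= D.
.repair_labels <- function(est) {
  swap <- function(e) {
    e[c("f", "D", "D_star")] <- c(1 - e[["f"]], e[["D_star"]], e[["D"]])
    if (all(c("T2_tissue", "T2_fluid") %in% names(e)))
      e[c("T2_tissue", "T2_fluid")] <- e[c("T2_fluid", "T2_tissue")]
    e
  }
  swapped <- FALSE
  has_t2 <- all(c("T2_tissue", "T2_fluid") %in% names(est))
  if (has_t2 && est[["T2_fluid"]] < est[["T2_tissue"]]) {
    cand <- swap(est)
    if (cand[["D_star"]] >= cand[["D"]]) { est <- cand; swapped <- TRUE }
  }
  if (est[["D_star"]] < est[["D"]]) { est <- swap(est); swapped <- TRUE }
  attr(est, "swapped") <- swapped
  est
}

.new_ivim_fit <- function(est, fit, y, b, te, options, model, extra = NULL,
                          te_ref = NULL) {
  p <- stats::setNames(as.numeric(est), names(est))
  p <- p[intersect(names(p),
                   c("f", "D", "D_star", "T2_tissue", "T2_fluid", "S0"))]
  fitted <- if (is.null(te_ref)) .model_eval(p, b, te)
            else .model_eval_anchored(p, b, te, te_ref)
  structure(c(list(
    coefficients = p, model = model,
    data = list(y = y, b = b, te = te),
    fitted.values = fitted, residuals = y - fitted,
    deviance = fit$deviance, converged = fit$converged,
    info = fit$info, message = fit$message, niter = fit$niter,
    swapped = isTRUE(attr(est, "swapped")), options = options,
    te_ref = te_ref), extra),
    class = "ivim_fit")
}

#' Fit the conventional IVIM model to a single-TE b-series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box
#' constraints) of the biexponential IVIM model to signals acquired at one
#' echo time: a one-step fit of (f, D, D*) and, optionally, a free scale
#' S0. Non-convergence is flagged on the returned object, not raised.
#' Compartment ordering D* >= D is restored by label swapping
#' (f -> 1 - f) when the optimizer lands on the mirrored labeling.
#'
#' @param signals Positive signal values, one per b-value.
#' @param b_values Distinct b-values in s/mm^2 including 0; at least 4.
#' @param options A [fit_options()]; `NULL` (default) uses
#'   [default_fit_options()].
#' @param fit_s0 Fit a free scale. Default `NULL`: a free scale is added
#'   when the b = 0 signal is not already 1 (i.e. the series is not
#'   normalized to its own S0).
#' @return An object of class `"ivim_fit"` with the usual [coef()],
#'   [predict()], [residuals()], [summary()] and [plot()] methods.
#' @examples
#' liver <- tissue_preset("liver")
#' y <- ivim_signal(liver$ivim, b_set("invivo16"))
#' coef(fit_ivim(y, b_set("invivo16")))
#' @export
fit_ivim <- function(signals, b_values, options = NULL, fit_s0 = NULL) {
  signals <- as.numeric(signals)
  if (length(unique(b_values)) < 4L || !0 %in% b_values)
    stop("need at least 4 distinct b-values including b = 0")
  if (length(signals) != length(b_values))
    stop("signal/b-value length mismatch")
  if (any(signals <= 0)) stop("signals must be positive")
  if (is.null(fit_s0))
    fit_s0 <- abs(signals[b_values == 0][1] - 1) > 1e-6
  if (is.null(options))
    options <- default_fit_options("ivim_1d", signals, b_values,
                                   fit_s0 = fit_s0)
  if (length(signals) < length(options$start))
    stop("fewer data points than free parameters")
  fit <- .lm_fit(signals, b_values, te = NULL, options)
  est <- .repair_labels(fit$estimates)
  .new_ivim_fit(est, fit, signals, b_values, te = NULL, options,
                model = "ivim_1d")
}

#' Joint 2D T2-IVIM fit over the (b, TE) plane
#'
#' Estimates (f, D, D*, T2_tissue, T2_fluid) — and by default a free scale
#' S0 — in a single bounded least-squares problem over all (b, TE)
#' combinations. The 2D data are flattened to one series by concatenating
#' the b-profiles of successive echo times (b ascending within each TE,
#' TEs ascending); the forward model is [t2ivim_signal()] (absolute T2
#' decay, no T1 terms).
#'
#' Identifiability requires at least two echo times and absolute TE decay:
#' per-TE-normalized input carries only the difference of transverse
#' relaxation rates, so it is refused unless `allow_relative_t2 = TRUE`,
#' in which case the fit parametrizes `dR2 = 1/T2_fluid - 1/T2_tissue`
#' (1/ms) instead of the two T2 values.
#'
#' When the fluid compartment comes out with the shorter T2, the
#' compartment labels are swapped (f -> 1 - f, D <-> D*, T2 <-> T2), which
#' leaves the fitted signal unchanged; the ordering D* >= D always wins if
#' the two orderings conflict.
#'
#' @param ds A [generate_dataset()] result, or a b x TE numeric matrix.
#' @param grid Required [acq_grid()] when `ds` is a bare matrix.
#' @param options A [fit_options()]; `NULL` uses [default_fit_options()].
#' @param fit_s0 Fit a free scale S0. Default `NULL`: datasets carrying
#'   the `"per_reference"` normalization tag are fitted with the
#'   anchor-normalized model (the forward model divided by its own b = 0
#'   value at the reference TE — no free scale, the simulation
#'   convention); everything else gets a free S0 (the in-vivo
#'   convention). `fit_s0 = TRUE` forces the free-scale absolute model.
#' @param allow_relative_t2 Accept per-TE-normalized input and report
#'   `dR2` only.
#' @param tr_index Which TR plane of a 3D dataset array to fit (default 1).
#' @return An `"ivim_fit"` object (subclass `"t2ivim_fit"`).
#' @export
fit_t2ivim <- function(ds, grid = NULL, options = NULL, fit_s0 = NULL,
                       allow_relative_t2 = FALSE, tr_index = 1L) {
  anchored <- FALSE
  if (inherits(ds, "signal_dataset")) {
    grid <- ds$grid
    per_te <- identical(ds$normalization, "per_te")
    anchored <- identical(ds$normalization, "per_reference") &&
      !isTRUE(fit_s0)
    vals <- ds$values[, , tr_index]
  } else {
    if (is.null(grid)) stop("'grid' is required with a bare signal matrix")
    vals <- as.matrix(ds)
    per_te <- all(abs(vals[grid$b_values == 0, ] - 1) < 1e-9)
  }
  if (is.null(fit_s0)) fit_s0 <- !anchored
  if (length(grid$te_values) < 2L)
    stop("joint T2-IVIM fit needs at least 2 echo times; ",
         "a single TE cannot separate the compartmental T2 values")
  if (length(unique(grid$b_values)) < 4L)
    stop("need at least 4 distinct b-values")
  if (per_te && !allow_relative_t2)
    stop("per-TE-normalized input: absolute T2 decay is lost and only ",
         "dR2 = 1/T2_fluid - 1/T2_tissue is identifiable. ",
         "Pass allow_relative_t2 = TRUE to fit that reduced model.")
  ord <- order(grid$te_values)
  vals <- vals[, ord, drop = FALSE]
  tes <- grid$te_values[ord]
  y <- as.vector(vals)                       # b fastest, then TE: flattened
  b <- rep(grid$b_values, times = length(tes))
  te <- rep(tes, each = length(grid$b_values))
  if (per_te) return(.fit_t2ivim_relative(y, b, te, grid, vals, tes))
  if (is.null(options))
    options <- default_fit_options("t2ivim_2d", vals, grid$b_values, tes,
                                   fit_s0 = fit_s0 && !anchored)
  w <- if (!is.null(grid$averages))
    rep(grid$averages, times = length(tes)) else NULL
  fit <- .lm_fit(y, b, te, options, weights = w,
                 te_ref = if (anchored) grid$reference_te)
  est <- .repair_labels(fit$estimates)
  out <- .new_ivim_fit(est, fit, y, b, te, options, model = "t2ivim_2d",
                       te_ref = if (anchored) grid$reference_te)
  class(out) <- c("t2ivim_fit", class(out))
  out
}

# Reduced 2D model for per-TE-normalized data: signal at (b, te) is
# (1 - g) e^{-bD} + g e^{-bD*} with a TE-dependent apparent fraction
# g(te) = f e^{-te dR2} / (1 - f + f e^{-te dR2}).
.fit_t2ivim_relative <- function(y, b, te, grid, vals, tes) {
  bnd <- .param_bounds()
  o1 <- default_fit_options("ivim_1d", vals[, 1], grid$b_values)
  start <- c(o1$start, dR2 = 0.005)
  options <- fit_options(start,
                         lower = c(o1$lower, dR2 = bnd$lower[["dR2"]]),
                         upper = c(o1$upper, dR2 = bnd$upper[["dR2"]]))
  model <- function(p, b, te) {
    w <- exp(-te * p[["dR2"]])
    g <- p[["f"]] * w / (1 - p[["f"]] + p[["f"]] * w)
    (1 - g) * exp(-b * p[["D"]]) + g * exp(-b * p[["D_star"]])
  }
  res_fn <- function(par) {
    model(stats::setNames(par, names(start)), b, te) - y
  }
  out <- minpack.lm::nls.lm(par = start, lower = options$lower,
                            upper = options$upper, fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = options$max_iter,
                              ftol = options$ftol, ptol = 1e-12))
  est <- stats::setNames(out$par, names(start))
  if (est[["D_star"]] < est[["D"]]) {
    est[c("f", "D", "D_star")] <-
      c(1 - est[["f"]], est[["D_star"]], est[["D"]])
    est[["dR2"]] <- -est[["dR2"]]
  }
  fitted <- model(est, b, te)
  structure(list(coefficients = est, model = "t2ivim_relative",
                 data = list(y = y, b = b, te = te),
                 fitted.values = fitted, residuals = y - fitted,
                 deviance = out$deviance, converged = out$info %in% 1:4,
                 info = out$info, message = out$message, niter = out$niter,
                 swapped = FALSE, options = options),
            class = c("t2ivim_fit", "ivim_fit"))
}

#' Extract the single-TE b-series from a dataset
#'
#' Pulls one echo time's b-profile out of a [generate_dataset()] result —
#' the input the conventional per-TE fit operates on.
#'
#' @param ds A `signal_dataset`.
#' @param te Echo time (must match a grid value).
#' @param tr_index TR plane (default 1).
#' @param renormalize Divide by the series' own b = 0 value (default
#'   FALSE).
#' @return List with `signals` and `b_values`.
#' @export
extract_te_series <- function(ds, te, tr_index = 1L, renormalize = FALSE) {
  stopifnot(inherits(ds, "signal_dataset"))
  j <- match(te, ds$grid$te_values)
  if (is.na(j)) stop("TE ", te, " not in the grid")
  y <- ds$values[, j, tr_index]
  if (renormalize) y <- y / y[ds$grid$b_values == 0][1]
  list(signals = y, b_values = ds$grid$b_values)
}

# ---- methods -------------------------------------------------------------

#' @export
print.ivim_fit <- function(x, digits = 4, ...) {
  lab <- switch(x$model, ivim_1d = "Conventional IVIM fit (single TE)",
                t2ivim_2d = "Joint 2D T2-IVIM fit",
                t2ivim_relative = "Joint 2D T2-IVIM fit (relative dR2 mode)")
  cat(lab, "\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("residual sum of squares: %.4g over %d points%s\n",
              x$deviance, length(x$data$y),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (x$swapped) cat("note: compartment labels swapped to enforce D* >= D\n")
  invisible(x)
}

#' @export
coef.ivim_fit <- function(object, ...) object$coefficients

#' @export
fitted.ivim_fit <- function(object, ...) object$fitted.values

#' @export
residuals.ivim_fit <- function(object, ...) object$residuals

#' @export
deviance.ivim_fit <- function(object, ...) object$deviance

#' Predict signal from a fitted IVIM / T2-IVIM model
#'
#' @param object An `"ivim_fit"`.
#' @param b,te New design points; defaults to the fitted ones. `te` is
#'   ignored by the single-TE model.
#' @param ... Unused.
#' @return Predicted signal values.
#' @export
predict.ivim_fit <- function(object, b = NULL, te = NULL, ...) {
  if (is.null(b)) return(object$fitted.values)
  if (object$model == "t2ivim_2d") {
    if (is.null(te)) stop("'te' required for the 2D model")
    n <- max(length(b), length(te))
    b <- rep_len(b, n); te <- rep_len(te, n)
    p <- object$coefficients
    if (is.null(object$te_ref)) .model_eval(p, b, te)
    else .model_eval_anchored(p, b, te, object$te_ref)
  } else if (object$model == "ivim_1d") {
    .model_eval(object$coefficients, b, te = NULL)
  } else {
    stop("prediction is not defined for the relative-dR2 model off the ",
         "fitted grid")
  }
}

#' @export
summary.ivim_fit <- function(object, ...) {
  n <- length(object$data$y); k <- length(object$coefficients)
  s2 <- object$deviance / max(n - k, 1)
  J <- if (object$model %in% c("ivim_1d", "t2ivim_2d"))
    .model_jac(object$coefficients, object$data$b, object$data$te) else NULL
  se <- rep(NA_real_, k)
  if (!is.null(J)) {
    JtJ <- crossprod(J)
    cv <- tryCatch(solve(JtJ) * s2, error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  out <- list(coefficients = cbind(Estimate = object$coefficients,
                                   `Std. Error` = se),
              sigma = sqrt(s2), df = n - k, model = object$model,
              converged = object$converged, niter = object$niter)
  class(out) <- "summary.ivim_fit"
  out
}

#' @export
print.summary.ivim_fit <- function(x, digits = 4, ...) {
  cat("Model:", x$model, "\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("residual SD %.4g on %d degrees of freedom (%d iterations)\n",
              x$sigma, x$df, x$niter))
  if (!x$converged) cat("warning: solver did not converge\n")
  invisible(x)
}

#' Plot a fitted IVIM / T2-IVIM signal decay
#'
#' Data points and fitted curves versus b, one curve per echo time for the
#' joint model, on a log signal axis.
#'
#' @param x An `"ivim_fit"`.
#' @param ... Passed to [plot.default()].
#' @export
plot.ivim_fit <- function(x, ...) {
  b <- x$data$b; y <- x$data$y; te <- x$data$te
  grp <- if (is.null(te)) factor(rep(1, length(b))) else factor(te)
  cols <- seq_len(nlevels(grp))
  graphics::plot(b, y, log = "y", col = cols[grp], pch = 16,
                 xlab = "b (s/mm^2)", ylab = "signal", ...)
  for (i in seq_len(nlevels(grp))) {
    sel <- grp == levels(grp)[i]
    ord <- order(b[sel])
    graphics::lines(b[sel][ord], x$fitted.values[sel][ord], col = cols[i])
  }
  if (!is.null(te))
    graphics::legend("topright", legend = paste("TE", levels(grp)),
                     col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Simulate noisy replicates from a fitted model
#'
#' Draws Rician-noised copies of the fitted signal at the fitted design
#' points — a quick parametric bootstrap.
#'
#' @param object An `"ivim_fit"`.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param sigma Rician noise SD; defaults to the residual SD.
#' @param ... Unused.
#' @return Matrix with one column per replicate.
#' @export
simulate.ivim_fit <- function(object, nsim = 1, seed = NULL,
                              sigma = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma))
    sigma <- sqrt(object$deviance /
                  max(length(object$data$y) - length(object$coefficients), 1))
  mu <- object$fitted.values
  replicate(nsim, rician_draw(mu, sigma))
}
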