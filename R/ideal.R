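#' Multiresolution ladder for IDEAL fitting
#'
#' The sequence of image shapes the coarse-to-fine IDEAL fit walks
#' through. For a 176 x 176 input this is exactly the eleven steps
#' 1, 2, 4, 8, 16, 32, 64, 96, 128, 152, 176 (square). Other sizes
#' generalize the same ratios: powers of two up to ~40% of the largest
#' dimension, then ~55%, ~73% and ~86% of full size, then full size;
#' non-square inputs scale the second dimension proportionally.
#'
#' @param shape Integer vector `c(ny, nx)` (a scalar means square).
#' @return An object of class `"resolution_ladder"`: a list of
#'   `c(ny, nx)` shapes with strictly increasing areas ending at `shape`.
#' @export
resolution_ladder <- function(shape) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  ny <- as.integer(shape[1]); nx <- as.integer(shape[2])
  if (ny < 1L || nx < 1L) stop("shape must be at least 1 x 1")
  n <- max(ny, nx)
  sizes <- 2^(0:30)
  sizes <- sizes[sizes <= 0.4 * n]
  sizes <- c(sizes, round(n * 6 / 11), round(n * 8 / 11),
             round(n * 19 / 22), n)
  sizes <- sort(unique(pmax(1L, as.integer(sizes))))
  steps <- lapply(sizes, function(s)
    c(max(1L, as.integer(round(ny * s / n))),
      max(1L, as.integer(round(nx * s / n)))))
  steps[[length(steps)]] <- c(ny, nx)
  areas <- vapply(steps, prod, numeric(1))
  steps <- steps[!duplicated(areas)]
  structure(steps, class = "resolution_ladder")
}

#' @export
print.resolution_ladder <- function(x, ...) {
  cat("Resolution ladder (", length(x), " steps): ",
      paste(vapply(x, function(s) paste(s, collapse = "x"), character(1)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Area-averaging (anti-aliased) resize via interval-overlap weight
# matrices: out = Wy %*% mat %*% t(Wx), each row of W averaging the source
# interval a target pixel covers.
.area_weights <- function(n_to, n_from) {
  W <- matrix(0, n_to, n_from)
  scale <- n_from / n_to
  for (i in seq_len(n_to)) {
    lo <- (i - 1) * scale; hi <- i * scale
    j0 <- floor(lo) + 1; j1 <- ceiling(hi)
    for (j in j0:min(j1, n_from)) {
      W[i, j] <- max(0, min(hi, j) - max(lo, j - 1))
    }
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

# Bilinear resize with pixel-center alignment and edge clamping.
.bilinear_weights <- function(n_to, n_from) {
  W <- matrix(0, n_to, n_from)
  scale <- n_from / n_to
  for (i in seq_len(n_to)) {
    src <- (i - 0.5) * scale + 0.5   # source pixel-center coordinate
    j0 <- floor(src)
    frac <- src - j0
    j0c <- min(max(j0, 1), n_from); j1c <- min(max(j0 + 1, 1), n_from)
    W[i, j0c] <- W[i, j0c] + (1 - frac)
    W[i, j1c] <- W[i, j1c] + frac
  }
  W
}

resize_area <- function(mat, ny, nx) {
  .area_weights(ny, nrow(mat)) %*% mat %*% t(.area_weights(nx, ncol(mat)))
}

resize_bilinear <- function(mat, ny, nx) {
  .bilinear_weights(ny, nrow(mat)) %*% mat %*%
    t(.bilinear_weights(nx, ncol(mat)))
}

#' 3 x 3 Gaussian smoothing with reflect padding
#'
#' Convolves a 2D image with a normalized 3 x 3 Gaussian kernel (SD
#' `sigma` pixels), reflecting the image at the borders. A constant image
#' is returned unchanged.
#'
#' @param image 2D numeric matrix.
#' @param sigma Kernel SD in pixels (default 0.8, the usual choice for a
#'   3 x 3 support).
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(image, sigma = 0.8) {
  stopifnot(is.matrix(image))
  g <- stats::dnorm(-1:1, sd = sigma)
  kernel <- outer(g, g); kernel <- kernel / sum(kernel)
  ny <- nrow(image); nx <- ncol(image)
  ref <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  out <- matrix(0, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    out <- out + kernel[dy + 2, dx + 2] *
      image[ref(seq_len(ny) + dy, ny), ref(seq_len(nx) + dx, nx)]
  }
  out
}

.map_params <- c("f", "D", "D_star", "T2_tissue", "T2_fluid", "S0")

# Absolute minimum half-widths so a near-zero prior does not collapse the
# box to a point.
.min_halfwidth <- c(f = 0.01, D = 5e-5, D_star = 2e-3,
                    T2_tissue = 2, T2_fluid = 2, S0 = 0.01)

#' Voxel-wise T2-IVIM parameter maps via the IDEAL multiresolution scheme
#'
#' Fits the joint 2D T2-IVIM model to every voxel of a (y, x, b, TE)
#' image stack coarse-to-fine: at each [resolution_ladder()] step the
#' stack is downsampled by area averaging and each pixel is fitted with
#' start values and box bounds centered on the bilinearly upsampled
#' estimates of the previous (coarser) step — bound half-widths of 50%
#' for S0 and 20% for f, D, D*, T2_tissue and T2_fluid. The first (1 x 1)
#' step fits the whole-image mean series with [default_fit_options()].
#' The spatial prior regularizes the voxel-wise problem, trading a little
#' spatial resolution of the parameter fields for a large variance
#' reduction relative to independent per-voxel fits.
#'
#' @param stack An [make_image_phantom()]-style `image_stack` (fields
#'   `values` 4D array, `grid`, optional `mask`).
#' @param fit_s0 Fit a free per-voxel scale (default TRUE, the in-vivo
#'   convention).
#' @param mask_threshold Voxels whose b = 0, shortest-TE signal is below
#'   this fraction of the image's robust (99th percentile) maximum are
#'   treated as background when the stack has no mask (default 0.05).
#' @param frac_s0,frac_par Relative bound half-widths around the
#'   interpolated priors (defaults 0.5 and 0.2).
#' @return An object of class `"parameter_maps"`: named list of 2D maps
#'   (`f`, `D`, `D_star`, `T2_tissue`, `T2_fluid`, `S0`), plus
#'   `converged` and `failed` logical masks and the grid. Background
#'   voxels carry `NA`.
#' @export
ideal_fit_image <- function(stack, fit_s0 = TRUE, mask_threshold = 0.05,
                            frac_s0 = 0.5, frac_par = 0.2) {
  stopifnot(inherits(stack, "image_stack") || (is.list(stack) &&
            !is.null(stack$values) && !is.null(stack$grid)))
  vals <- stack$values
  grid <- stack$grid
  d <- dim(vals)
  if (length(d) != 4L) stop("stack values must be a 4D (y, x, b, TE) array")
  ny <- d[1]; nx <- d[2]
  if (length(grid$te_values) < 2L)
    stop("IDEAL mapping uses the 2D model: need at least 2 echo times")
  mask <- stack$mask
  if (is.null(mask)) {
    s0img <- vals[, , which(grid$b_values == 0)[1],
                  which.min(grid$te_values)]
    mask <- s0img >= mask_threshold * stats::quantile(s0img, 0.99)
  }
  if (!any(mask)) {
    warning("all voxels are background; returning empty maps")
    empty <- matrix(NA_real_, ny, nx)
    return(structure(list(
      maps = stats::setNames(rep(list(empty), length(.map_params)),
                             .map_params),
      converged = matrix(FALSE, ny, nx), failed = matrix(FALSE, ny, nx),
      grid = grid), class = "parameter_maps"))
  }
  ladder <- resolution_ladder(c(ny, nx))
  bnd <- .param_bounds()
  pars <- if (fit_s0) .map_params else setdiff(.map_params, "S0")
  prior <- NULL   # named list of parameter matrices at the previous shape
  final_conv <- matrix(FALSE, ny, nx)
  for (step in seq_along(ladder)) {
    shp <- ladder[[step]]
    # downsample every (b, TE) volume and the mask to this shape
    dvals <- array(0, dim = c(shp[1], shp[2], d[3], d[4]))
    for (ib in seq_len(d[3])) for (it in seq_len(d[4]))
      dvals[, , ib, it] <- resize_area(vals[, , ib, it], shp[1], shp[2])
    dmask <- resize_area(mask + 0, shp[1], shp[2]) > 0.25
    if (!any(dmask)) dmask[which.max(resize_area(mask + 0, shp[1], shp[2]))] <- TRUE
    cur <- stats::setNames(
      lapply(pars, function(p) matrix(NA_real_, shp[1], shp[2])), pars)
    conv <- matrix(FALSE, shp[1], shp[2])
    if (!is.null(prior)) {
      up <- lapply(prior, resize_bilinear, ny = shp[1], nx = shp[2])
    }
    for (iy in seq_len(shp[1])) for (ix in seq_len(shp[2])) {
      if (!dmask[iy, ix]) next
      series <- matrix(dvals[iy, ix, , ], nrow = d[3])
      if (any(series <= 0)) series <- pmax(series, 1e-9)
      if (is.null(prior)) {
        opts <- NULL   # data-driven defaults at the 1 x 1 step
      } else {
        p0 <- vapply(pars, function(p) up[[p]][iy, ix], numeric(1))
        frac <- ifelse(pars == "S0", frac_s0, frac_par)
        hw <- pmax(abs(p0) * frac, .min_halfwidth[pars])
        lower <- pmax(p0 - hw, bnd$lower[pars])
        upper <- pmin(p0 + hw, bnd$upper[pars])
        upper <- pmax(upper, lower + 1e-12)
        start <- pmin(pmax(p0, lower), upper)
        opts <- fit_options(stats::setNames(start, pars),
                            stats::setNames(lower, pars),
                            stats::setNames(upper, pars))
      }
      fit <- tryCatch(
        fit_t2ivim(series, grid = grid, options = opts, fit_s0 = fit_s0),
        error = function(e) NULL)
      if (is.null(fit)) next
      est <- coef(fit)
      for (p in pars) cur[[p]][iy, ix] <- est[[p]]
      conv[iy, ix] <- fit$converged
    }
    # fill unfitted (background at this scale) with the map median so the
    # bilinear prior for the next level has no holes
    for (p in pars) {
      m <- cur[[p]]
      if (anyNA(m)) m[is.na(m)] <- stats::median(m, na.rm = TRUE)
      cur[[p]] <- m
    }
    prior <- cur
    final_conv <- conv
  }
  maps <- prior
  for (p in pars) maps[[p]][!mask] <- NA_real_
  if (!fit_s0) maps$S0 <- matrix(NA_real_, ny, nx)
  structure(list(maps = maps[.map_params[.map_params %in% names(maps)]],
                 converged = final_conv & mask,
                 failed = mask & !final_conv, grid = grid),
            class = "parameter_maps")
}

#' Independent per-voxel 2D fits (no spatial prior)
#'
#' The unregularized counterpart of [ideal_fit_image()]: every masked
#' voxel is fitted independently with data-driven defaults. Mainly a
#' baseline for quantifying the variance reduction the multiresolution
#' prior buys.
#'
#' @inheritParams ideal_fit_image
#' @return A `"parameter_maps"` object.
#' @export
voxel_fit_image <- function(stack, fit_s0 = TRUE, mask_threshold = 0.05) {
  vals <- stack$values; grid <- stack$grid
  d <- dim(vals); ny <- d[1]; nx <- d[2]
  mask <- stack$mask
  if (is.null(mask)) {
    s0img <- vals[, , which(grid$b_values == 0)[1],
                  which.min(grid$te_values)]
    mask <- s0img >= mask_threshold * stats::quantile(s0img, 0.99)
  }
  pars <- if (fit_s0) .map_params else setdiff(.map_params, "S0")
  maps <- stats::setNames(
    lapply(.map_params, function(p) matrix(NA_real_, ny, nx)), .map_params)
  conv <- matrix(FALSE, ny, nx)
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (!mask[iy, ix]) next
    series <- matrix(vals[iy, ix, , ], nrow = d[3])
    series <- pmax(series, 1e-9)
    fit <- tryCatch(fit_t2ivim(series, grid = grid, fit_s0 = fit_s0),
                    error = function(e) NULL)
    if (is.null(fit)) next
    est <- coef(fit)
    for (p in pars) maps[[p]][iy, ix] <- est[[p]]
    conv[iy, ix] <- fit$converged
  }
  structure(list(maps = maps, converged = conv, failed = mask & !conv,
                 grid = grid),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  d <- dim(x$converged)
  cat(sprintf("Parameter maps %d x %d: %d fitted, %d failed\n",
              d[1], d[2], sum(x$converged), sum(x$failed)))
  invisible(x)
}

#' Difference map between two sets of parameter maps
#'
#' Voxel-wise `reference - maps` for one parameter — e.g. the difference
#' between an f map from a shortened protocol and the ground-truth map
#' from the full protocol.
#'
#' @param maps,reference `"parameter_maps"` objects of the same shape.
#' @param parameter Parameter name (default `"f"`).
#' @return 2D matrix of differences.
#' @export
delta_map <- function(maps, reference, parameter = "f") {
  a <- maps$maps[[parameter]]; b <- reference$maps[[parameter]]
  if (is.null(a) || is.null(b)) stop("unknown parameter: ", parameter)
  if (!all(dim(a) == dim(b))) stop("map shapes differ: ",
                                   paste(dim(a), collapse = "x"), " vs ",
                                   paste(dim(b), collapse = "x"))
  b - a
}

#' ROI summaries of parameter maps
#'
#' Per-region statistics of each parameter map: mean, SD, median and —
#' when a reference is supplied — the percent difference of the region
#' median to the reference's.
#'
#' @param maps A `"parameter_maps"` object.
#' @param labels Region-label matrix (character or integer); voxels
#'   labelled `"background"` (or NA) are skipped.
#' @param reference Optional `"parameter_maps"` to compare against.
#' @return A data frame with columns `region`, `parameter`, `n`, `mean`,
#'   `sd`, `median` and (with a reference) `pct_diff_median`.
#' @export
roi_summary <- function(maps, labels, reference = NULL) {
  stopifnot(is.matrix(labels))
  if (!all(dim(labels) == dim(maps$converged)))
    stop("label matrix shape does not match the maps")
  regions <- setdiff(unique(as.vector(labels)), c("background", NA))
  rows <- list()
  for (reg in regions) {
    sel <- labels == reg
    for (p in names(maps$maps)) {
      v <- maps$maps[[p]][sel]
      v <- v[is.finite(v)]
      if (!length(v)) next
      row <- data.frame(region = reg, parameter = p, n = length(v),
                        mean = mean(v), sd = stats::sd(v),
                        median = stats::median(v))
      if (!is.null(reference)) {
        rv <- reference$maps[[p]][sel]
        rv <- rv[is.finite(rv)]
        row$pct_diff_median <- if (length(rv) && stats::median(rv) != 0)
          100 * (row$median - stats::median(rv)) / stats::median(rv)
        else NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
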