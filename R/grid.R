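#' Acquisition grid: the (b, TE, TR) design
#'
#' Describes a diffusion-weighted acquisition scheme: the b-values
#' (diffusion weighting, s/mm^2), echo times TE and repetition times TR
#' (ms), optional per-b signal averages, and the normalization anchor
#' (`reference_te`, `reference_tr`) — the (TE, TR) node whose b = 0 signal
#' all simulated datasets are normalized to.
#'
#' @param b_values Non-negative b-values in s/mm^2, ascending, first = 0.
#' @param te_values Echo times in ms, unique, positive.
#' @param tr_values Repetition times in ms, positive (often a singleton).
#' @param averages Optional positive integer vector of per-b averages,
#'   recycled length `length(b_values)`; `NULL` means single average.
#' @param reference_te Normalization TE; defaults to the smallest TE.
#' @param reference_tr Normalization TR; defaults to the first TR.
#' @return An object of class `"acq_grid"`.
#' @examples
#' acq_grid(b_set("liver_consensus"), te_values = seq(50, 100, 5),
#'          tr_values = 4000)
#' @export
acq_grid <- function(b_values, te_values, tr_values = 4000, averages = NULL,
                     reference_te = min(te_values),
                     reference_tr = tr_values[1]) {
  b_values <- as.numeric(b_values)
  te_values <- as.numeric(te_values)
  tr_values <- as.numeric(tr_values)
  if (length(b_values) == 0L || length(te_values) == 0L ||
      length(tr_values) == 0L)
    stop("acquisition grid must have at least one b, TE and TR value")
  if (any(b_values < 0))
    stop("field 'b_values': negative b-value (", min(b_values), ")")
  if (is.unsorted(b_values, strictly = TRUE))
    stop("field 'b_values': must be strictly ascending")
  if (b_values[1] != 0)
    stop("field 'b_values': must include b = 0 as the first entry")
  if (anyDuplicated(te_values))
    stop("field 'te_values': duplicate echo times")
  if (any(te_values <= 0)) stop("field 'te_values': must be positive")
  if (any(tr_values <= 0)) stop("field 'tr_values': must be positive")
  if (!is.null(averages)) {
    averages <- as.integer(rep_len(averages, length(b_values)))
    if (any(averages < 1L)) stop("field 'averages': must be >= 1")
  }
  if (!reference_te %in% te_values)
    stop("field 'reference_te': ", reference_te, " not among te_values")
  if (!reference_tr %in% tr_values)
    stop("field 'reference_tr': ", reference_tr, " not among tr_values")
  structure(list(b_values = b_values, te_values = te_values,
                 tr_values = tr_values, averages = averages,
                 reference_te = reference_te, reference_tr = reference_tr),
            class = "acq_grid")
}

#' @export
print.acq_grid <- function(x, ...) {
  cat("Acquisition grid:\n")
  cat("  b (s/mm^2): ", paste(x$b_values, collapse = ", "), "\n")
  cat("  TE (ms):    ", paste(x$te_values, collapse = ", "),
      " [reference ", x$reference_te, "]\n", sep = "")
  cat("  TR (ms):    ", paste(x$tr_values, collapse = ", "),
      " [reference ", x$reference_tr, "]\n", sep = "")
  if (!is.null(x$averages))
    cat("  averages:   ", paste(x$averages, collapse = ", "), "\n")
  invisible(x)
}

#' Standard b-value and echo-time sets
#'
#' The acquisition sets used throughout the liver/kidney simulation studies:
#' `b_set()` returns one of the named b-value vectors and `te_set()` one of
#' the candidate echo-time ranges.
#'
#' * `"invivo16"` — the 16-b in-vivo-style protocol:
#'   0, 10, 20, 30, 50, 70, 100, 150, 200, 250, 300, 350, 450, 550, 650,
#'   750 s/mm^2.
#' * `"liver_consensus"` — six community-consensus liver b-values
#'   0, 10, 20, 100, 200, 550 s/mm^2 (CRLB-derived).
#' * `"kidney6"` — the six-point kidney set 0, 10, 100, 200, 500, 800.
#'
#' Echo-time sets: `"te1"` = 47–72 ms in 5 ms steps (6 values, the in vivo
#' range); `"te2"` = 50–100 ms in 5 ms steps (11 values, the extended
#' design range).
#'
#' @param name Set name (see Details).
#' @return A numeric vector.
#' @export
b_set <- function(name = c("invivo16", "liver_consensus", "kidney6")) {
  switch(match.arg(name),
    invivo16 = c(0, 10, 20, 30, 50, 70, 100, 150, 200, 250, 300, 350,
                 450, 550, 650, 750),
    liver_consensus = c(0, 10, 20, 100, 200, 550),
    kidney6 = c(0, 10, 100, 200, 500, 800))
}

#' @rdname b_set
#' @export
te_set <- function(name = c("te1", "te2")) {
  switch(match.arg(name),
    te1 = seq(47, 72, by = 5),
    te2 = seq(50, 100, by = 5))
}

#' Built-in tissue presets for 3T liver and kidney phantoms
#'
#' Biologically realistic IVIM and relaxation parameters at 3 Tesla used by
#' the numerical phantoms. The liver preset is f = 0.095, D = 0.0010 mm^2/s,
#' D* = 0.067 mm^2/s, T1 tissue 800 ms, T2 tissue 27 ms; the kidney preset
#' is f = 0.15, D = 0.0016 mm^2/s, D* = 0.012 mm^2/s, T1 tissue 1200 ms,
#' T2 tissue 67 ms. Fluid relaxation times default to the tissue values
#' (zero difference) so that studies sweep `dT1`/`dT2` explicitly via
#' [with_relaxation_deltas()] or the arguments here.
#'
#' @param organ `"liver"` or `"kidney"`.
#' @param dT1,dT2 Fluid-minus-tissue relaxation differences in ms
#'   (default 0). The study grids are dT1 0–600 ms (liver) / 0–600 ms
#'   (kidney) and T2 fluid 27–87 ms (liver) / 67–150 ms (kidney).
#' @param s0 Signal scale (default 1).
#' @return A [tissue_state()].
#' @examples
#' tissue_preset("liver", dT2 = 5)
#' @export
tissue_preset <- function(organ = c("liver", "kidney"), dT1 = 0, dT2 = 0,
                          s0 = 1) {
  organ <- match.arg(organ)
  base <- switch(organ,
    liver = list(ivim = ivim_params(0.095, 0.0010, 0.067),
                 T1 = 800, T2 = 27),
    kidney = list(ivim = ivim_params(0.15, 0.0016, 0.012),
                  T1 = 1200, T2 = 67))
  tissue_state(
    ivim = base$ivim,
    relax = relaxation_params(T1_tissue = base$T1, T1_fluid = base$T1 + dT1,
                              T2_tissue = base$T2, T2_fluid = base$T2 + dT2),
    s0 = s0)
}

#' T2-fluid evaluation grid for protocol design
#'
#' The fluid-compartment T2 scenarios over which the design objective is
#' summed: 27–87 ms in 5 ms steps for liver (13 values), 67–150 ms in
#' 15 ms steps for kidney.
#'
#' @param organ `"liver"` or `"kidney"`.
#' @return Numeric vector of T2 fluid values in ms.
#' @export
t2_fluid_grid <- function(organ = c("liver", "kidney")) {
  switch(match.arg(organ),
    liver = seq(27, 87, by = 5),
    kidney = seq(67, 150, by = 15))
}
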