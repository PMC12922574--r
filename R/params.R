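#' IVIM parameter set
#'
#' Bundles the three parameters of the biexponential intravoxel incoherent
#' motion (IVIM) model: the pseudo-diffusion volume fraction `f` (the signal
#' fraction attributed to capillary flow, often called the perfusion
#' fraction), the molecular diffusion coefficient `D`, and the
#' pseudo-diffusion coefficient `D_star` of the flowing compartment.
#'
#' The IVIM framework assumes pseudo-diffusion is substantially faster than
#' molecular diffusion, so `D_star >= D` is enforced at construction; this
#' also prevents silent compartment-label switching downstream.
#'
#' @param f Pseudo-diffusion volume fraction, dimensionless in `[0, 1]`.
#' @param D Diffusion coefficient in mm^2/s, strictly positive.
#' @param D_star Pseudo-diffusion coefficient in mm^2/s, `>= D`.
#' @return An object of class `"ivim_params"`: a named list with elements
#'   `f`, `D`, `D_star`.
#' @examples
#' ivim_params(f = 0.095, D = 0.0010, D_star = 0.067)  # liver at 3T
#' @export
ivim_params <- function(f, D, D_star) {
  stopifnot(is.numeric(f), length(f) == 1L, is.numeric(D), length(D) == 1L,
            is.numeric(D_star), length(D_star) == 1L)
  if (f < 0 || f > 1) stop("'f' must lie in [0, 1], got ", f)
  if (D <= 0) stop("'D' must be strictly positive, got ", D)
  if (D_star < D) {
    stop("'D_star' (", D_star, ") must be >= 'D' (", D,
         "): pseudo-diffusion is the fast compartment")
  }
  structure(list(f = f, D = D, D_star = D_star), class = "ivim_params")
}

#' Compartmental relaxation times
#'
#' Longitudinal (T1) and transverse (T2) relaxation times of the tissue
#' (parenchymal) and fluid (flow-related: blood, pre-urine) compartments,
#' all in milliseconds. The differences `T1_fluid - T1_tissue` and
#' `T2_fluid - T2_tissue` drive the echo-time dependent bias of the
#' conventional IVIM perfusion fraction; they are derived on demand (see
#' [delta_t1()] / [delta_t2()]), never stored.
#'
#' @param T1_tissue,T1_fluid,T2_tissue,T2_fluid Relaxation times in ms,
#'   all strictly positive.
#' @return An object of class `"relaxation_params"`.
#' @export
relaxation_params <- function(T1_tissue, T1_fluid, T2_tissue, T2_fluid) {
  v <- c(T1_tissue = T1_tissue, T1_fluid = T1_fluid,
         T2_tissue = T2_tissue, T2_fluid = T2_fluid)
  if (any(!is.finite(v)) || any(v <= 0)) {
    bad <- names(v)[!is.finite(v) | v <= 0]
    stop("relaxation times must be finite and strictly positive; offending: ",
         paste(bad, collapse = ", "))
  }
  structure(as.list(v), class = "relaxation_params")
}

#' @rdname relaxation_params
#' @param relax A `relaxation_params` object.
#' @export
delta_t1 <- function(relax) relax$T1_fluid - relax$T1_tissue

#' @rdname relaxation_params
#' @export
delta_t2 <- function(relax) relax$T2_fluid - relax$T2_tissue

#' Tissue state: IVIM parameters plus compartmental relaxation times
#'
#' The complete generative description of a voxel or phantom region:
#' IVIM parameters, compartmental relaxation times, and an overall signal
#' scale `s0` (arbitrary units; the forward models normalize it away unless
#' asked not to).
#'
#' @param ivim An [ivim_params()] object.
#' @param relax A [relaxation_params()] object.
#' @param s0 Signal scale at b = 0 before relaxation weighting; positive.
#' @return An object of class `"tissue_state"`.
#' @seealso [tissue_preset()] for the built-in liver/kidney presets.
#' @export
tissue_state <- function(ivim, relax, s0 = 1) {
  stopifnot(inherits(ivim, "ivim_params"), inherits(relax, "relaxation_params"))
  if (!is.numeric(s0) || length(s0) != 1L || s0 <= 0)
    stop("'s0' must be a positive scalar")
  structure(list(ivim = ivim, relax = relax, s0 = s0),
            class = "tissue_state")
}

#' @export
print.ivim_params <- function(x, ...) {
  cat(sprintf("IVIM parameters: f = %.4g, D = %.4g mm^2/s, D* = %.4g mm^2/s\n",
              x$f, x$D, x$D_star))
  invisible(x)
}

#' @export
print.relaxation_params <- function(x, ...) {
  cat(sprintf(
    "Relaxation times (ms): T1 tissue/fluid = %g/%g, T2 tissue/fluid = %g/%g\n",
    x$T1_tissue, x$T1_fluid, x$T2_tissue, x$T2_fluid))
  cat(sprintf("  dT1 = %g ms, dT2 = %g ms\n", delta_t1(x), delta_t2(x)))
  invisible(x)
}

#' @export
print.tissue_state <- function(x, ...) {
  cat("Tissue state (s0 =", x$s0, ")\n")
  print(x$ivim)
  print(x$relax)
  invisible(x)
}

#' Update a tissue state's relaxation-time differences
#'
#' Convenience for the simulation studies, which sweep the fluid-minus-tissue
#' relaxation differences: returns a copy of `state` whose fluid relaxation
#' times are `T1_tissue + dT1` and `T2_tissue + dT2`.
#'
#' @param state A [tissue_state()].
#' @param dT1,dT2 Fluid-minus-tissue relaxation differences in ms; `NULL`
#'   leaves the corresponding fluid time unchanged.
#' @return A modified `tissue_state`.
#' @export
with_relaxation_deltas <- function(state, dT1 = NULL, dT2 = NULL) {
  stopifnot(inherits(state, "tissue_state"))
  r <- state$relax
  if (!is.null(dT1)) r$T1_fluid <- r$T1_tissue + dT1
  if (!is.null(dT2)) r$T2_fluid <- r$T2_tissue + dT2
  state$relax <- relaxation_params(r$T1_tissue, r$T1_fluid,
                                   r$T2_tissue, r$T2_fluid)
  state
}
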