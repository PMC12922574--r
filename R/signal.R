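#' Conventional biexponential IVIM signal
#'
#' The two-compartment IVIM decay
#' \deqn{S(b)/S_0 = (1 - f)\,e^{-bD} + f\,e^{-bD^*}}
#' where `f` is the pseudo-diffusion volume fraction, `D` the molecular
#' diffusion coefficient and `D*` the pseudo-diffusion coefficient. Both
#' compartments are assumed to share identical relaxation times; see
#' [relaxation_ivim_signal()] for the model that drops that assumption.
#'
#' @param p An [ivim_params()] object.
#' @param b b-value(s) in s/mm^2, non-negative (vectorized).
#' @return Normalized signal in (0, 1], same length as `b`.
#' @examples
#' liver <- tissue_preset("liver")
#' ivim_signal(liver$ivim, b = c(0, 100, 750))
#' @export
ivim_signal <- function(p, b) {
  stopifnot(inherits(p, "ivim_params"))
  if (any(b < 0)) stop("b-values must be non-negative")
  (1 - p$f) * exp(-b * p$D) + p$f * exp(-b * p$D_star)
}

# Unnormalized relaxation-weighted compartment sum: the numerator of the
# relaxation-compensated model. Vectorized over b, te, tr (recycled).
relaxation_weighted_signal <- function(state, b, te, tr) {
  p <- state$ivim; r <- state$relax
  w_t <- (1 - exp(-tr / r$T1_tissue)) * exp(-te / r$T2_tissue)
  w_f <- (1 - exp(-tr / r$T1_fluid)) * exp(-te / r$T2_fluid)
  state$s0 * ((1 - p$f) * w_t * exp(-b * p$D) +
              p$f * w_f * exp(-b * p$D_star))
}

#' Relaxation-compensated IVIM signal
#'
#' Extends the IVIM model with compartmental relaxation weighting: each
#' compartment is scaled by its own T1 saturation-recovery factor
#' \eqn{(1 - e^{-TR/T1})} and T2 decay \eqn{e^{-TE/T2}}, and the result is
#' normalized by the b = 0 signal at the same (TE, TR):
#' \deqn{\frac{S}{S_0} =
#'   \frac{(1-f)\,w_t\,e^{-bD} + f\,w_f\,e^{-bD^*}}
#'        {(1-f)\,w_t + f\,w_f}, \quad
#'   w_x = (1 - e^{-TR/T1_x})\,e^{-TE/T2_x}.}
#' When the two compartments' relaxation times coincide the weights cancel
#' and this reduces exactly to [ivim_signal()]. When they differ, the
#' effective compartment fractions become TE/TR dependent — the origin of
#' the echo-time bias in the conventional perfusion fraction.
#'
#' @param state A [tissue_state()].
#' @param b b-value(s) in s/mm^2, non-negative.
#' @param te Echo time in ms, positive.
#' @param tr Repetition time in ms, positive.
#' @return Normalized signal in (0, 1]; invariant to `state$s0`.
#' @export
relaxation_ivim_signal <- function(state, b, te, tr) {
  stopifnot(inherits(state, "tissue_state"))
  if (any(b < 0)) stop("b-values must be non-negative")
  if (any(te <= 0)) stop("'te' must be positive")
  if (any(tr <= 0)) stop("'tr' must be positive")
  relaxation_weighted_signal(state, b, te, tr) /
    relaxation_weighted_signal(state, 0, te, tr)
}

#' T2-compensated IVIM signal with explicit scale (2D fitting model)
#'
#' The forward model of the joint b-TE fit: T2 decay is kept in absolute
#' form (no per-TE normalization) and the overall scale S0 is explicit,
#' while T1 terms are omitted:
#' \deqn{S(b, TE) = S_0\left[(1-f)\,e^{-TE/T2_{tissue}}e^{-bD}
#'       + f\,e^{-TE/T2_{fluid}}e^{-bD^*}\right].}
#' Keeping the absolute TE decay is what makes both compartmental T2 values
#' (not only their difference) identifiable from multi-TE data.
#'
#' @param p An [ivim_params()] object.
#' @param t2_tissue,t2_fluid Compartmental T2 values in ms, positive.
#' @param s0 Signal scale, positive.
#' @param b b-value(s) in s/mm^2.
#' @param te Echo time(s) in ms, non-negative (vectorized with `b`).
#' @return Signal in the units of `s0`.
#' @export
t2ivim_signal <- function(p, t2_tissue, t2_fluid, s0, b, te) {
  stopifnot(inherits(p, "ivim_params"))
  if (any(b < 0)) stop("b-values must be non-negative")
  if (t2_tissue <= 0 || t2_fluid <= 0) stop("T2 values must be positive")
  if (any(te < 0)) stop("'te' must be non-negative")
  s0 * ((1 - p$f) * exp(-te / t2_tissue) * exp(-b * p$D) +
        p$f * exp(-te / t2_fluid) * exp(-b * p$D_star))
}

#' Apparent perfusion fraction of a conventional fit (closed form)
#'
#' The pseudo-diffusion volume fraction that a conventional (single-TE)
#' IVIM fit recovers from noiseless relaxation-compensated signals at a
#' given (TE, TR). Because the relaxation weights rescale each compartment
#' by a constant at fixed (TE, TR), the per-TE-normalized signal is exactly
#' a biexponential with the same D, D* and the apparent fraction
#' \deqn{f_{app} = \frac{f\,w_f}{(1-f)\,w_t + f\,w_f}, \quad
#'       w_x = (1 - e^{-TR/T1_x})\,e^{-TE/T2_x},}
#' so this closed form is the exact global minimizer of the conventional
#' least-squares fit — a useful oracle for validating fitters.
#'
#' @param state A [tissue_state()].
#' @param te Echo time in ms.
#' @param tr Repetition time in ms.
#' @return The apparent fraction in `[0, 1]` (vectorized over `te`/`tr`).
#' @examples
#' liver <- tissue_preset("liver", dT2 = 5)
#' apparent_f(liver, te = 52, tr = 4000)  # ~0.1242, a +31% bias
#' @export
apparent_f <- function(state, te, tr) {
  stopifnot(inherits(state, "tissue_state"))
  p <- state$ivim; r <- state$relax
  w_t <- (1 - exp(-tr / r$T1_tissue)) * exp(-te / r$T2_tissue)
  w_f <- (1 - exp(-tr / r$T1_fluid)) * exp(-te / r$T2_fluid)
  p$f * w_f / ((1 - p$f) * w_t + p$f * w_f)
}

#' Percent bias of an estimate
#'
#' `100 * (estimate - truth) / truth`.
#'
#' @param estimate Estimated value(s).
#' @param truth True value(s); must be nonzero.
#' @return Percent bias.
#' @export
percent_bias <- function(estimate, truth) {
  if (any(truth == 0)) stop("'truth' must be nonzero for a percent bias")
  100 * (estimate - truth) / truth
}
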