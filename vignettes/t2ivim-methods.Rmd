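---
title: "Relaxation-compensated T2-IVIM: models, fitting and protocol design"
author: "t2ivim package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relaxation-compensated T2-IVIM: models, fitting and protocol design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2ivim)
```

## The problem

Intravoxel incoherent motion (IVIM) imaging separates molecular diffusion
from capillary-flow "pseudo-diffusion" by acquiring diffusion-weighted MR
images over a range of b-values and fitting the biexponential decay

$$\frac{S(b)}{S_0} = (1-f)\,e^{-bD} + f\,e^{-bD^*},$$

where $f$ is the pseudo-diffusion volume fraction (perfusion fraction),
$D$ the tissue diffusion coefficient (mm²/s) and $D^*$ the
pseudo-diffusion coefficient of the flowing compartment ($D^* \gg D$).
This model silently assumes that both compartments share the same
relaxation times. They do not: body fluids (blood, pre-urine) have longer
T2 than parenchyma, so each compartment carries its own echo-time
weighting and the *apparent* perfusion fraction grows with TE. The
relaxation-compensated signal model makes the weighting explicit:

$$\frac{S}{S_0} =
\frac{(1-f)\,w_t\,e^{-bD} + f\,w_f\,e^{-bD^*}}
     {(1-f)\,w_t + f\,w_f},
\qquad
w_x = \left(1 - e^{-TR/T1_x}\right) e^{-TE/T2_x}.$$

Because the weights rescale each compartment by a constant at fixed
(TE, TR), a conventional single-TE fit of such data is *exactly*
biexponential — it simply converges to the apparent fraction

$$f_{app}(TE, TR) = \frac{f\,w_f}{(1-f)\,w_t + f\,w_f},$$

which the package exposes as `apparent_f()`. This closed form is the
global minimizer of the conventional least-squares fit on noiseless data,
and the package's test suite uses it as an independent oracle for the
numerical fitter. For the liver preset (f = 0.095, T2 tissue 27 ms) a
fluid–tissue T2 difference of only 5 ms biases $f$ by about +31% at
TE = 52 ms and +45% at TE = 72 ms; T1 differences matter much less once
TR ≥ 3000 ms, because the saturation-recovery factors approach 1.

The remedy implemented here is the **joint 2D T2-IVIM fit**: acquire the
b-profile at several echo times and fit
$(f, D, D^*, T2_{tissue}, T2_{fluid})$ in a single nonlinear
least-squares problem over the whole (b, TE) plane, using the
T2-compensated forward model (no T1 terms)

$$S(b, TE) = S_0\left[(1-f)\,e^{-TE/T2_{tissue}}\,e^{-bD}
 + f\,e^{-TE/T2_{fluid}}\,e^{-bD^*}\right].$$

## Tissue presets and study conditions

`tissue_preset()` carries the two phantoms used throughout:

| parameter | liver (3T) | kidney (3T) |
|---|---|---|
| f | 0.095 | 0.15 |
| D (mm²/s) | 0.0010 | 0.0016 |
| D* (mm²/s) | 0.067 | 0.012 |
| T1 tissue (ms) | 800 | 1200 |
| T2 tissue (ms) | 27 | 67 |

Fluid relaxation times default to the tissue values; studies sweep the
differences explicitly (`dT1`, `dT2` arguments, or
`with_relaxation_deltas()`). The standard acquisition sets are the 16-b
in-vivo protocol (0–750 s/mm²), the six consensus liver b-values
{0, 10, 20, 100, 200, 550} s/mm², echo times 47–72 ms (in vivo) or
50–100 ms (design range) in 5 ms steps, and TR 2000–4000 ms. Rician
noise is parameterized by its SD on the normalized signal scale, so
SNR at S0 is exactly 1/σ (σ = 0.025 is SNR 40). The fluid-T2 scenario
grid for liver protocol design is 27–87 ms in 5 ms steps (13 values).

## Normalization conventions — the load-bearing choice

Three normalizations are first-class, and which one a dataset carries
decides what is identifiable:

* **`per_reference`** (simulator default): everything is divided by the
  b = 0 signal at a single anchor (smallest TE, simulation TR). Absolute
  TE decay across echoes is preserved, so *both* compartmental T2 values
  are identifiable by the joint fit. `fit_t2ivim()` then uses the
  *anchor-normalized* forward model — the T2-compensated model divided by
  its own b = 0 value at the reference TE — with no free scale. Fitting a
  free S0 on such data is possible but wasteful: in Monte-Carlo runs it
  inflated SD(f) by roughly 40%.
* **`per_te`**: each echo's series is divided by its own b = 0 value
  (the conventional IVIM convention, and the form in which the
  relaxation-compensated equation is usually written). All absolute T2
  information is destroyed; only the transverse-rate difference
  $\Delta R_2 = 1/T2_{fluid} - 1/T2_{tissue}$ survives. `fit_t2ivim()`
  refuses such data unless `allow_relative_t2 = TRUE`, in which case it
  fits the reduced parametrization $(f, D, D^*, \Delta R_2)$.
* **`absolute`**: raw relaxation-weighted signal; the in-vivo convention
  with a free per-voxel S0 (the default for image stacks).

The variance-reduction benchmark (below) is run under `per_te`
normalization, where every echo time sees SNR 40 at its own S0 — the
design under which the 1D and 2D estimators face the same per-echo noise
and the comparison is meaningful. Under the anchor convention the
shortest-TE 1D fit is already efficient for its own apparent fraction
(its empirical SD matches its CRLB) and no joint estimator can undercut
it; the joint fit's advantage there is accuracy, not variance.

## Fitting

Both fits are one-step bounded nonlinear least squares via
`minpack.lm::nls.lm` (Levenberg–Marquardt with box constraints) with
analytic Jacobians. Segmented estimation is used only to build start
values (`default_fit_options()`): D from a log-linear fit over
b ≥ 200 s/mm² (or the upper half of the b range), f from the gap between
the b = 0 signal and the back-extrapolated monoexponential intercept
(clamped to [0.01, 0.6]), D* = 10 D, and both T2 values from the
log-linear TE decay of the b = 0 signals. Global physical bounds are
f ∈ [0, 1], D ∈ [10⁻⁵, 5·10⁻³] mm²/s, D* ∈ [10⁻⁵, 0.5] mm²/s,
T2 ∈ [5, 500] ms. Convergence tolerance is 10⁻¹² on the relative sum of
squares, 300 iterations maximum; non-convergence is flagged on the
returned object, never raised.

The biexponential is symmetric under relabeling
$(f, D, D^*, T2_t, T2_f) \to (1-f, D^*, D, T2_f, T2_t)$, which leaves the
fitted curve unchanged. The package resolves the label degeneracy by
preferring $T2_{fluid} \ge T2_{tissue}$ when that labeling also keeps
$D^* \ge D$, and enforcing $D^* \ge D$ unconditionally otherwise (the
IVIM definition of the fast compartment wins ties). Swaps are recorded on
the fit object. Fit failures inside Monte-Carlo ensembles are excluded
and counted rather than imputed.

Fitted models are classic S3 objects with `print()`, `coef()`,
`summary()` (with linearized standard errors), `predict()`,
`residuals()`, `plot()` and `simulate()` (Rician parametric bootstrap)
methods.

## Protocol design: CRLB and the nRMSE objective

Under Gaussian noise the Fisher information of a (b, TE) design is
$F = \sigma^{-2} J^\top W J$, with $J$ the analytic Jacobian of the
T2-compensated model over the design points and $W$ per-point averages.
The design-mode parameter set is $(f, D, D^*, T2_{tissue}, T2_{fluid})$
with the scale fixed by normalization: the model is linearized at the
constant scale that makes its b = 0 signal at the reference TE equal 1,
so $\sigma$ and $J$ live on the same normalized-signal scale the
simulator produces. (Without this scaling the bound comes out several
times larger than any observed Monte-Carlo SD, because σ is defined
relative to a unit anchor.) `crlb_sd_f()` is the square root of the
(f, f) entry of $F^{-1}$.

The design objective is the normalized RMSE of f summed over the
fluid-T2 scenario grid:

$$\mathrm{nRMSE}(\mathcal{TE}) =
 \sum_{i=1}^{N_{T2_{fluid}}} \frac{\sqrt{\beta_i^2 + \sigma_{f,i}^2}}{f}.$$

The bias policy is $\beta = 0$ by default: the joint model is correctly
specified for its own data, so the asymptotic bias vanishes and the
objective reduces to a sum of coefficients of variation; a small
Monte-Carlo plug-in (`bias = "mc"`) is available for the finite-sample
term. The radical is read as $\sqrt{\beta^2 + \sigma^2}/f$, per the
"normalized RMSE" name.

Subset search is exhaustive (`optimize_tes_exhaustive()`, the
deterministic oracle, lexicographic tie-break) or by an integer-coded
genetic algorithm (`optimize_tes_ga()`): chromosomes are k distinct
candidate indices; tournament selection of size 2, uniform crossover
with duplicate repair, per-gene mutation to an unused candidate, the
fittest 5% carried over unchanged, stopping at the generation cap or
when the best objective improves by less than the tolerance over a
10-generation stall window. Full-scale defaults are population 10 000
and 100 generations with tolerance 0.001; the test suite uses population
100–200 and 30–50 generations, which reaches the exhaustive optimum on
every space with ≤ a few hundred subsets. With the liver preset, SNR 40
and TR 4000 ms, the optimal 3-TE subset for the in-vivo space
(16 b × TE 47–72 ms) is {47, 67, 72} ms, and for the consensus-b design
space (TE 50–100 ms) the optimum spans 50 to 100 ms.
`validate_protocol_mc()` closes the loop: simulate → joint fit →
ensemble summary, confirming the CRLB-based ranking with actual fitted
variances.

## IDEAL multiresolution mapping

`ideal_fit_image()` produces voxel-wise parameter maps by fitting
coarse-to-fine over a resolution ladder: for a 176 × 176 image the steps
are 1, 2, 4, 8, 16, 32, 64, 96, 128, 152, 176; other sizes generalize
the same ratios (powers of two up to ~40% of full size, then ~55%, ~73%,
~86% and full). At each step every volume is downsampled by exact
interval-overlap **area averaging** (anti-aliased, mean-preserving), and
each pixel is fitted with start values and box bounds centered on the
**bilinearly** upsampled previous-step estimates — half-widths of ±50%
for S0 and ±20% for f, D, D*, and both T2 values. Small absolute minimum
half-widths (0.01 for f, 5·10⁻⁵ for D, 2·10⁻³ for D*, 2 ms for T2)
prevent a near-zero prior from collapsing a box to a point. The 1 × 1
step uses the data-driven defaults. Background voxels — below 5% of the
robust (99th percentile) maximum of the b = 0, shortest-TE image when no
mask is supplied — are never fitted and carry `NA`; at coarse scales,
unfitted cells are median-filled only so the bilinear prior has no
holes. `voxel_fit_image()` is the unregularized per-voxel baseline; on the
noisy two-region phantom the multiresolution prior cuts the voxel-wise
SD of f by roughly a third at equal region medians.
`gaussian_smooth()` (3 × 3 kernel, SD 0.8 px, symmetric-reflect padding)
mirrors the pre-processing applied to registered in-vivo images;
registration itself is out of scope and assumed done.

## What the simulator does and does not emulate

`generate_dataset()` + `add_rician_noise()` reproduce the numerical
phantom conditions: noiseless relaxation-weighted signals on the full
(b, TE, TR) grid, single-average magnitude data with Rician noise of
fixed SD on the normalized scale, and optional per-b averaging
(averaging independent Rician draws, which keeps the small-signal
magnitude bias of each draw). `make_image_phantom()` adds piecewise
constant spatial layouts with truth maps and a pure-noise background.
None of this emulates motion, imperfect registration, partial-volume
mixing at organ boundaries, fat signal, eddy-current or
gradient-nonlinearity effects, spatially varying coil sensitivity, or
physiological variability between acquisitions. Passing the synthetic
benchmarks therefore demonstrates correctness of the estimators under
the stated noise model, not in-vivo performance; in-vivo group results
(which require the original scans) are outside what this package can
reproduce.

## Numerical and design choices worth knowing

* **Units**: b in s/mm², D and D* in mm²/s, all times in ms; σ on the
  normalized signal scale.
* **Reference anchor**: smallest TE in the grid and the first TR, unless
  overridden in `acq_grid()`.
* **Per-b averaging** defaults to off in simulations (the tabulated
  averages belong to the in-vivo protocol); when present it enters both
  the noise model and the Fisher weight matrix.
* **Monte-Carlo sizes**: the package's benchmark runs use 2500
  repetitions for the variance-reduction comparison (the full study
  condition; at 500 repetitions a one-sided F-test at α = 0.01 has under
  50% power for the ~9% SD reduction present at dT1 = 300 ms /
  dT2 = 15 ms, so a scaled-down ensemble cannot resolve the effect),
  400 repetitions for CRLB agreement at low noise, and 150–400 for
  smoke-level properties.
* **Phantom SNR**: region `s0` values are chosen so the *observed*
  b = 0, shortest-TE signal is ≈ 1, keeping "SNR at S0" consistent with
  σ despite the absolute T2 decay in the voxel-wise forward model.
* **Known limitations**: two compartments only (no ballistic-flow b–M1
  regime, no exchange, no three-compartment kidney model); no T1 fitting
  in the joint model (choose TR ≥ 3000 ms to keep T1 bias small); the
  CRLB is a local, Gaussian-noise bound and is conservative for the
  bounded estimator at low SNR; DICOM ingestion and registration are out
  of scope.
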