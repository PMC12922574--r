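# t2ivim — relaxation-compensated T2-IVIM modelling, fitting and protocol design

Intravoxel incoherent motion (IVIM) imaging estimates tissue perfusion
from multi-b-value diffusion-weighted MRI via the biexponential model

    S(b)/S0 = (1 − f)·exp(−b·D) + f·exp(−b·D*)

with pseudo-diffusion volume fraction `f`, diffusion coefficient `D`
(mm²/s) and pseudo-diffusion coefficient `D*`. The model assumes both
compartments relax identically — but fluids have longer T2 than
parenchyma, so the apparent `f` grows with echo time: in the liver a
fluid–tissue T2 difference of only 5 ms inflates `f` by ~31% at
TE = 52 ms and ~45% at TE = 72 ms. This package implements the
relaxation-compensated T2-IVIM framework around that problem, for
quantitative-MRI researchers working in abdominal organs:

* forward models: conventional IVIM, the relaxation-compensated signal
  with compartmental T1/T2 weighting, and the T2-compensated 2D fitting
  model `S(b,TE) = S0·[(1−f)·e^(−TE/T2t)·e^(−bD) + f·e^(−TE/T2f)·e^(−bD*)]`,
  plus the closed-form apparent fraction
  `f_app = f·w_f / ((1−f)·w_t + f·w_f)`, `w_x = (1 − e^(−TR/T1x))·e^(−TE/T2x)`;
* a Rician Monte-Carlo simulator reproducing the liver/kidney numerical
  phantoms (3T presets, 16-b and consensus b-sets, TE 47–100 ms,
  SNR = 1/σ);
* single-TE (1D) and joint b-TE (2D) bounded nonlinear least-squares
  fitting returning classic model objects (`coef`, `summary`, `predict`,
  `residuals`, `plot`, `simulate` methods);
* voxel-wise parameter mapping via the IDEAL multiresolution scheme
  (1×1 → … → full resolution, interpolated priors, ±20%/±50% bounds);
* Cramér–Rao lower-bound machinery and exhaustive / genetic-algorithm
  echo-time subset optimization minimizing the nRMSE of `f`,
  `Σ_i sqrt(β_i² + σ_f,i²)/f` over a grid of fluid-T2 scenarios.

## Worked example

```r
library(t2ivim)

liver <- tissue_preset("liver", dT2 = 5)   # fluid T2 32 ms vs tissue 27 ms
grid  <- acq_grid(b_set("invivo16"), te_set("te1"), tr_values = 4000)
ds    <- generate_dataset(liver, grid)     # noiseless, anchor-normalized

# conventional single-TE fit at TE = 52 ms: f is biased upward
ser  <- extract_te_series(ds, te = 52)
fit1 <- fit_ivim(ser$signals, ser$b_values)
fit1
#> Conventional IVIM fit (single TE)
#>      f      D D_star     S0
#> 0.1242 0.0010 0.0670 0.8339
#> residual sum of squares: 7.704e-32 over 16 points
percent_bias(coef(fit1)[["f"]], 0.095)     # +30.7 %
apparent_f(liver, 52, 4000)                # 0.1242 — closed-form check

# joint 2D T2-IVIM fit over all 16 b x 6 TE: unbiased, T2s recovered
fit_t2ivim(ds)
#> Joint 2D T2-IVIM fit
#>         f         D    D_star T2_tissue  T2_fluid
#>     0.095     0.001     0.067    27.000    32.000

# optimal 3-TE protocol for the six consensus liver b-values
space <- design_space(te_set("te2"), b_set("liver_consensus"), k = 3)
optimize_tes_exhaustive(space)
#> Optimal TE subset (exhaustive search, 165 evaluations):
#>   TEs (ms):  50, 95, 100
#>   nRMSE objective: 6.2654
```

The single-TE fit lands exactly on the closed-form apparent fraction
(0.1242, a +31% bias from the true 0.095), while the joint fit over the
(b, TE) plane recovers all five generative parameters. The protocol
search says a 3-echo liver protocol should span the full 50–100 ms
candidate range.

A command-line interface wrapping these functions ships at
`inst/cli/t2ivim.R` (subcommands `simulate`, `fit`, `fit-image`,
`optimize-protocol`, `validate-protocol`); acquisition schemes are YAML
files (`load_scheme("liver_consensus")`), signal tables are long-format
TSV, and image stacks are 4D NIfTI with b varying fastest across
volumes.

See the methods vignette (`vignettes/t2ivim-methods.Rmd`) for the model
assumptions, normalization conventions, fitting and optimizer details,
and what the synthetic benchmarks do and do not demonstrate.

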