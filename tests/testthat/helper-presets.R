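# Shared fixtures: presets and grids used across the test files.

liver_state <- function(dT1 = 0, dT2 = 0) tissue_preset("liver", dT1, dT2)
kidney_state <- function(dT1 = 0, dT2 = 0) tissue_preset("kidney", dT1, dT2)

grid_invivo <- function(tr = 4000) acq_grid(b_set("invivo16"), te_set("te1"), tr)
grid_consensus <- function(tes = te_set("te2"), tr = 4000)
  acq_grid(b_set("liver_consensus"), tes, tr)

# scale s0 so the observed (b = 0, shortest TE) signal is 1: keeps the
# phantom's SNR-at-S0 definition consistent with the noise sigma
s0_unit_observed <- function(state, te_min) {
  state$s0 <- 1 / t2ivim_signal(state$ivim, state$relax$T2_tissue,
                                state$relax$T2_fluid, 1, 0, te_min)
  state
}

# disc-in-background region layout
disc_layout <- function(n, label = "liver", radius = n * 0.38) {
  lay <- matrix("background", n, n)
  c0 <- (n + 1) / 2
  for (y in seq_len(n)) for (x in seq_len(n))
    if ((y - c0)^2 + (x - c0)^2 <= radius^2) lay[y, x] <- label
  lay
}
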