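# emtswitch

Hysteresis and bistability in TGF-β-induced epithelial–mesenchymal
transition (EMT), modelled through the miR-200/ZEB double-negative feedback
loop with autocrine TGF-β production and an E-cadherin readout.

The package is for systems biologists who want a tested, end-to-end
implementation of the switch analysis: the single-cell ODE circuit,
saddle-node (bistable window) detection with a scalar hysteresis-extent
measure, stochastic cell-population ensembles under continuous / pulsed /
withdrawal dosing, RS-HDMR global sensitivity analysis of what controls the
hysteresis, and a reaction–diffusion lattice for paracrine EMT spreading. A
synthetic flow-cytometry generator provides ground-truth mixtures for the
population-modality analysis, so everything is testable without any
experimental download.

## Model

Each cell carries four species — TGF-β `T`, miR-200 `M`, ZEB `Z`,
E-cadherin `E`:

    dT/dt = dose + k_T / (1 + (M/K_MT)^h_T) − d_T·T
    dM/dt = b_M + k_M / (1 + (Z/K_Z′)^h_M) − d_M·M
    dZ/dt = b_Z + k_Z·T / (K_T + T) − k_MZ·M·Z − d_Z·Z
    dE/dt = b_E + k_E / (1 + (Z/K_Z″)^h_E) − d_E·E

ZEB represses the miR-200 promoter (constant `K_Z′`); miR-200 removes ZEB
(coefficient `k_MZ`) and shuts down autocrine TGF-β production (constant
`K_MT`). The calibrated wildtype preset is bistable over exogenous doses of
about 2.5–12 a.u.: cells keep a memory of whether they were undergoing EMT
or its reverse. Raising `K_Z′` alone — weakened ZEB repression of the
miR-200 promoter, as caused by deleting a ZEB binding site — shrinks the
bistable window monotonically and abolishes it at ~2.2×, which is how the
`"mutant"` preset is built.

## Worked example

```r
library(emtswitch)

wt  <- default_parameters("wildtype")
mut <- default_parameters("mutant")

bistable_window(wt, method = "sweep")
#> <bistable_window> [2.477, 11.992] extent 9.516 (E gap 0.762, sweep)
hysteresis_extent(mut, method = "reduced")
#> [1] 0

# transient versus continuous TGF-beta: only the hysteretic circuit commits
pulse_memory_experiment(wt, dose = 20, pulse_duration = 12,
                        followup_time = 24, n_cells = 500,
                        noise = noise_spec(seed = 41))[1:2]
#> $fraction_pulse
#> [1] 0.946
#> $fraction_continuous
#> [1] 1

# what controls hysteresis: RS-HDMR over a factor-of-10 box
design  <- sample_hypercube(n_samples = 5000, seed = 101)
extents <- evaluate_extent_map(design)
fit     <- fit_hdmr(design, extents)
round(sort(fit$S_i, decreasing = TRUE), 3)
#>    K_Z_prime          k_Z         k_MZ K_Z_dblprime
#>        0.138        0.074        0.018        0.001
```

The window `[2.477, 11.992]` is the bistable dose range bracketed by the
forward (epithelial-history) and backward (mesenchymal-history) sweeps; its
width is the hysteresis extent, exactly 0 for the monostable mutant. The
pulse experiment shows memory: 94.6% of wildtype cells scored mesenchymal
after a transient pulse versus 100% under continuous treatment (the mutant
drops from 100% to 0%). The sensitivity indices identify `K_Z_prime` — the
strength of ZEB's grip on the miR-200 promoter — as the dominant controller
of hysteresis.

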