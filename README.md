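# mompsim

Particle-based stochastic simulation of mitochondrial outer membrane
permeabilization (MOMP) regulation, for systems biologists studying why
individual mitochondria within one cell respond differently to apoptotic
stress.

During apoptosis, pore-forming BAK — activated by the BH3-only protein tBID
and restrained by the guard MCL-1 — permeabilizes the mitochondrial outer
membrane. Usually all mitochondria permeabilize together, but under
sublethal stress only a minority may do so (*minority MOMP*), and during
widespread permeabilization a few mitochondria can escape. `mompsim` tests
how much of that heterogeneity is explained by stochasticity alone: finite
numbers of molecules diffusing through a 3D model cell, translocating on and
off mitochondrial membranes, and reacting at single-mitochondrion
resolution.

The package provides:

- a periodic 3D model cell with static rectangular mitochondria in regular,
  random, polarized, surface-varied and fragmented arrangements (total
  mitochondrial volume conserved under fragmentation);
- fixed-step Brownian dynamics with collision-mediated membrane binding
  (probability `p_bind` per collision), lateral membrane diffusion with
  face transitions, and stochastic retrotranslocation (`1 − exp(−k_off·dt)`
  per step), exactly particle-conserving;
- a reduced membrane interactome — tBID + BAK → tBID + aBAK,
  tBID + MCL1 ⇌ tBID·MCL1, aBAK + MCL1 ⇌ aBAK·MCL1, and the dimer ladder
  aBAK → aBAK2 → aBAK4 → aBAK6 — simulated per mitochondrion with
  mesoscopic binding radii derived from mass-action constants rescaled by
  `k_f = k_est · V_m / V_c`, and the pore metric `aBAK4 + aBAK6`;
- a deterministic mass-action twin (deSolve) used as a correctness oracle;
- the study's statistical toolkit: Mann-Whitney, Kruskal-Wallis with Dunn's
  post-hoc, Levene, Brown-Forsythe, D'Agostino-Pearson K², one-phase decay
  fits, per-mitochondrion density tables and surface density maps;
- ImageJ-style mitochondrial size quantification (8-bit conversion, IsoData
  threshold, connected-component particle sizing) with synthetic
  microscopy-image generators carrying exact ground truth;
- a manifest-driven pipeline (`cmd_simulate_cell()`, `cmd_simulate_mito()`,
  `cmd_analyze()`, `cmd_quantify_images()`, `cmd_make_synthetic()`,
  `rerun_from_manifest()`) in which every stage is bit-reproducible from
  one master seed, plus a thin CLI at `inst/scripts/momp-pipeline.R`.

## Worked example

Ten percent of a regular mitochondrial population is fragmented at conserved
volume, MCL-1 is seeded at 101 nM, and the per-mitochondrion membrane
density is compared between fragments and intact mitochondria:

```r
library(mompsim)

cfg <- make_experiment_config("fig3_fragmentation", scale_factor = 0.108,
                              seed = 1)
res <- run_scenario(cfg)

ref <- res$per_concentration[["101"]]
ref$brown_forsythe$p          # variance comparison, fragmented vs intact
#> [1] 6.39e-06
tt  <- res$table[res$table$concentration_nM == 101, ]
tapply(tt$count_per_area, tt$group, median)
#>     fragmented non_fragmented
#>           24.0           24.3
kruskal.test(tt$count_per_area, factor(tt$group))$p.value
#> [1] 0.22
res$pooled_brown_forsythe$p   # pooled across the 10-400 nM sweep
#> [1] 1.23e-09
```

Fragmented and intact mitochondria carry the *same median* MCL-1 density per
membrane area (Kruskal-Wallis p ≫ 0.05), but the fragments' densities are
far more dispersed (Brown-Forsythe p < 0.0001): with ~3× less surface per
fragment, the same per-area expectation is realized with ~3× fewer
molecules, so counting noise creates sub-populations of fragments with high
or low guard coverage — the proposed stochastic route to heterogeneous MOMP
susceptibility. The same pipeline yields the 10–400 nM sweep
(`res$pooled_brown_forsythe`), the arrangement comparison
(`fig2_arrangements`), the surface-area sweep with its through-origin
collision fit and one-phase decay of the cytosol:membrane ratio
(`fig1_sweep`), and the tBID scenarios with the single-mitochondrion pore
endpoint (`fig4_strong_tBID`, `fig5_weak_tBID`, via `cmd_simulate_mito()`).

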