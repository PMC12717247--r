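---
title: "Particle-based modeling of stochastic MOMP regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-based modeling of stochastic MOMP regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mompsim)
```

## The scientific question

Mitochondrial outer membrane permeabilization (MOMP) commits a cell to
apoptosis. It is executed by pore-forming effectors (BAK) activated by
BH3-only proteins (tBID) and restrained by anti-apoptotic guards (MCL-1).
MOMP is usually all-or-none across a cell's mitochondria, but two deviant
phenotypes matter in cancer biology: *minority MOMP*, where only a small
subset of mitochondria permeabilize under sublethal stress, and escape from
*majority MOMP*, where a few mitochondria survive an otherwise global
permeabilization wave.

`mompsim` asks how far pure stochasticity — finite molecule numbers
diffusing, translocating and reacting in a spatially structured cell — can
explain which mitochondria respond. The package simulates a simplified 3D
cell at single-particle resolution and quantifies the resulting
inter-mitochondrial heterogeneity in protein load and pore formation, with a
deliberate focus on mitochondrial *fragmentation*: small fission products
have larger surface-to-volume ratios and carry fewer molecules, so
small-number fluctuations hit them hardest.

## The model

**Geometry.** The cell is a rectangular box with periodic boundary
conditions containing static, axis-aligned rectangular mitochondria
(default 1.5 × 0.5 × 0.5 µm). Mitochondria never move, rotate, fuse or
divide during a run; fragmentation is represented statically by replacing a
fraction of mitochondria with `k` length-wise fragments of equal total
volume (`apply_fragmentation()`, volume conserved exactly). Arrangements:
regular lattice, uniform random (non-overlapping, rejection-sampled),
polarized (confined to the two outer quarter-slabs of a chosen axis), and
surface-area-varied at conserved volume (length-wise splitting).

**Translocation stage.** Cytosolic particles perform fixed-step Brownian
dynamics (per-axis Gaussian steps of variance 2·D·dt, periodic wrap).
Collisions with mitochondria are resolved by segment/box intersection; a
collision binds the particle with probability `p_bind` (it becomes a
membrane particle at the hit point, in 2D face coordinates) or reflects it
specularly, with repeated reflections resolved recursively within the step.
Membrane particles diffuse laterally in face coordinates; steps crossing a
face edge are folded onto the adjacent face with path length preserved.
Membrane particles return to the cytosol with per-step probability
1 − exp(−k_off·dt), released 1 nm outside the membrane. Total particle
number is conserved exactly at every step.

**Reaction stage.** MOMP regulation is modeled by a reduced membrane
interactome: tBID catalytically activates BAK; MCL-1 reversibly sequesters
tBID and activated BAK (aBAK); aBAK assembles strictly through a dimer
ladder (aBAK2 → aBAK4 → aBAK6); tetramers plus hexamers (`aBAK4 + aBAK6`,
`pore_metric()`) are counted as membrane pores. Because simulating all
mitochondria and reactions concurrently at cell scale is infeasible at desk
scale, each mitochondrion is simulated separately: its molecular complement
is copied from the final time point of the whole-cell translocation run
(`seed_single_mito()`), positions are re-drawn uniformly over the box
surface, and retrotranslocation is disabled during the reaction stage (the
mitochondrial ensemble already samples the exchange heterogeneity).

**Rate rescaling.** Whole-cell second-order rate constants `k_est`
(nM⁻¹s⁻¹) are rescaled to a mitochondrion of volume `V_m` in cell volume
`V_c` as `k_f = k_est · V_m / V_c` (`scale_rate()`). With reaction
propensities referenced to the local compartment volume this makes the
per-particle-pair interaction rate identical in the whole-cell and
single-mitochondrion descriptions, so summed per-mitochondrion expectations
reproduce whole-cell mass-action kinetics (`eq1_consistency()`, verified to
2% in the tests, in practice exact to integrator precision). In the
particle pipeline the conversion is evaluated once, at the reference
(non-fragmented) mitochondrion area, and the resulting binding radii are
used on every mitochondrion: radii are molecular properties, so equal
surface densities react at equal per-molecule rates everywhere. The two
conventions coincide when molecules distribute proportionally to membrane
area and differ only in the fluctuations — which is deliberate, since a
fragment that stochastically received a high activator density should
react proportionally faster.

**Mesoscopic conversion.** Second-order rates become binding radii: a pair
within the radius after the diffusion substep reacts (conflicts are
resolved in randomized order, each particle reacting at most once per
step). In the regime used throughout — diffusive step σ much larger than
the radius — the realized 2D rate constant is `π r² / dt`, and
`kf_to_binding_radius()` starts from that closed form and verifies (and if
needed refines) it against well-mixed calibration simulations, accepting
the radius only when the measured rate is within tolerance or statistically
indistinguishable from it. The verification estimator uses the endpoint of
the integrated second-order law, which is exact under ideal mass action.
Same-species reactions (dimerization) double the radius-capture target
because the engine fires once per unordered pair while the mass-action
convention counts `k·N²`. Reverse rates become per-step unbinding
probabilities `1 − exp(−k_r·dt)`; dissociation products are placed one
unbinding radius (2× binding radius) apart to avoid immediate recapture.

**Deterministic twin.** `build_odes()`/`integrate_odes()` provide a
stiff-capable mass-action ODE mirror of the network (deSolve), used purely
as a correctness oracle: the particle engine is required to match it in the
well-mixed, reaction-limited, high-copy regime. Outside that regime the
particle model is the reference, not the ODE: catalytic activation, for
example, creates genuine spatial correlations (newly activated BAK appears
along the activator's path, locally depleted of MCL-1) that mean-field
kinetics cannot represent; the oracle comparison is therefore run at
reaction-limited rates (`k/(4πD)` ≪ 1).

## Parameters, units and defaults

All lengths are µm, times s, concentrations nM; counts follow
`N = conc · 0.602214076 · V[µm³]`.

| Parameter | Default | Why |
|---|---|---|
| cell volume | 2500 µm³ reference, scaled | typical carcinoma cell; `scale_factor` shrinks volume for desk-scale particle counts |
| mitochondria | 120 boxes of 1.5 × 0.5 × 0.5 µm | rod-like mitochondria; 16% volume fraction at the desk scale |
| fragmentation | 10% of mitochondria into k = 3 fragments | study condition; volume conserved |
| MCL-1 | 101 nM total | study reference concentration (sweep 10–400 nM) |
| tBID | 10 nM (strong) / 2 nM (weak) | study stimulus levels |
| BAK | 50 nM | plausible effector level; the experimentally derived value is not public |
| D_cyto | 10 µm²/s | cytosolic protein diffusion |
| D_mem | 0.25 µm²/s | lateral membrane diffusion |
| dt (translocation) | 1.9 × 10⁻⁴ s | largest step obeying the invariant `sqrt(2 D dt)` ≤ ¼ smallest half-dimension |
| p_bind (MCL-1) | 0.008 | calibrated once so the steady state is ≈65% membrane-bound at k_off = 1/s |
| k_off (MCL-1) | 1 /s | desk-scale exchange: time axis compressed so one residence time is ~1 s |
| sampling window | 1 s | fixed-endpoint sampling at ≈1 residence time (see below) |
| reaction dt / window | 2 × 10⁻³ s / 60 s | membrane step ≪ face size; window long enough for pore assembly on loaded mitochondria |

The translocation and kinetic constants of the source system are not
publicly tabulated, so these are the package's own desk-scale choices: the
(p_bind, k_off) pair is degenerate with respect to the steady-state
cytosol:membrane ratio, and the reaction rates are chosen so that the
qualitative regime of the study is reproduced (non-fragmented mitochondria
assemble pores robustly under a strong stimulus while fragments scatter;
under a weak stimulus pore formation is sparse and fragment-dominated).
They are *not* measured values.

**Fixed-endpoint sampling.** Per-mitochondrion tables are taken at a fixed
end time of about one retrotranslocation residence time, the desk-scale
analog of the study protocol of measuring at a fixed 30-minute endpoint.
This matters scientifically: at full exchange equilibrium, detailed balance
makes the membrane density per unit area uniform across mitochondria
regardless of crowding, so the arrangement-driven variance inflation is a
*pre-equilibrium* phenomenon carried by slowly equilibrating, densely
packed regions. Sampling at the fixed endpoint preserves it; letting every
run converge would wash it out.

## What the statistics measure

`densities()` tabulates per-mitochondrion membrane counts per volume and
per surface area. Group comparisons follow the study's conventions: medians
by Mann-Whitney (two groups) or Kruskal-Wallis with Dunn's post-hoc
(several; midranks with tie correction, no multiplicity adjustment by
default), variances by Levene (two groups, deviations from means) or
Brown-Forsythe (deviations from medians), normality by the
D'Agostino-Pearson K² omnibus (implemented from the standard skewness and
kurtosis z-approximations; no installed package provides it). The
cytosol:membrane partitioning versus surface area is summarized by a
bounded one-phase decay fit `y = (y0 − plateau)·exp(−k·x) + plateau` with
multi-start nonlinear least squares.

For the concentration sweep, the pooled fragmented-vs-non-fragmented
variance comparison normalizes each concentration's densities by that
concentration's overall median before the Brown-Forsythe test; without the
normalization the absolute deviations of the highest concentration dominate
the pooled statistic.

## Synthetic data

The generators produce every input the pipeline needs. Scenario configs
(`make_experiment_config()`) embed the study concentrations and
fragmentation fraction, with three replicate seeds derived from one master
seed by a counter scheme (`derive_seed()`); replicates re-randomize initial
particle placements, and stochastic arrangements also re-randomize
mitochondrial positions, mirroring the replicate protocol of the study.

`make_image()` emulates fluorescence microscopy images of mitochondrial
populations: non-overlapping ellipses with log-normal pixel areas
(right-skewed, as mitochondrial size distributions typically are) on a dark
background, Gaussian PSF blur and additive Gaussian read noise, with
ground-truth pre-blur pixel areas and a labeled subset (smallest fraction
or random fraction) standing in for mitochondria undergoing or escaping
MOMP. What these images do *not* emulate: realistic PSFs, uneven
illumination, touching/overlapping organelles, or depth effects — so
passing quantification tests shows the measurement chain is correct, not
that segmentation of real micrographs is solved.

The quantification chain mirrors the ImageJ workflow used for the
retrospective analyses: linear 8-bit conversion, IsoData iterative
intermeans auto-threshold (the ImageJ default variant), 8-connected
component labeling (ImageJ "Analyze Particles" default; 4-connectivity
available), minimum object size 2 px, border objects kept.

## Numerical choices

- Per-axis Gaussian steps are clamped at 4σ (probability 6×10⁻⁵ per draw)
  so the collision grid can guarantee no tunneling; the variance deficit is
  ≈0.04%.
- Tangential (zero-measure) box grazing counts as no hit; reflection
  recursion is capped at 8, after which the particle rests 1 nm outside the
  last face hit.
- Membrane edge crossings fold the remaining path onto the adjacent face;
  corner-exact ties route through the lower face index.
- The engines use a dedicated 64-bit Mersenne Twister with Marsaglia polar
  normal draws, so identical seeds give bit-identical trajectories on any
  platform; R-side placement helpers use R's RNG under `with_seed()`.
- Rejection sampling for random placements is capped at 10,000 attempts per
  box; arrangement feasibility (volume fraction ≤ 50%, lattice spacing)
  errors out before any simulation.
- ODE integration uses lsoda at rtol 10⁻⁸ with conservation checked to
  10⁻⁶ relative; trajectories must stay non-negative.

## Problem sizes

The shipped scenarios are desk-scale reductions: the fragmentation and
weak-stimulus scenarios run ≈16,000 MCL-1-equivalent particles in a 270 µm³
cell with 144 mitochondria (three replicate seeds pooled); the arrangement
comparison uses a 1250 µm³ cell with 540 mitochondria per arm at the same
packing density, sized so that a variance-equality comparison has
paper-like statistical power; the surface-area sweep uses 12 mitochondria
at four area factors; the oracle-equivalence check runs ≈5,100 reacting
particles on a 10 µm² patch, six replicates. A full scenario completes in
minutes on one core.

## Known limitations

- The cell is geometrically minimal: no nucleus, organelle crowding,
  cytoskeletal barriers, or membrane curvature; mitochondria are static
  boxes.
- Kinetic and translocation constants are desk-scale stand-ins with the
  correct qualitative regime, not measured values; absolute times and
  absolute pore counts are not interpretable, only comparisons between
  arrangements, size classes and stimulus levels.
- The mesoscopic conversion is valid in the reaction-limited, step-resampling
  regime (σ ≫ binding radius, k/(4πD) ≪ 1); strongly diffusion-limited 2D
  kinetics would need a different (Smoluchowski-corrected) conversion.
- MOMP itself is not modeled as membrane rupture; the aBAK4+6 pore metric
  is the endpoint, and no threshold pore number is asserted.
- The weak-stimulus reaction endpoint (a minority of fragments out-running
  the non-fragmented pool) is a tail-event property; at desk-scale
  mitochondrial counts it is qualitative, not a stable test statistic.
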