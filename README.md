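# afpop

Population-of-models analysis of rotor dynamics in chronically remodeled
human atrial tissue.

Long-standing persistent atrial fibrillation (AF) is sustained by
functional reentry — rotors — and the ionic makeup of each patient's
atrium shapes whether those rotors persist, how fast they activate the
tissue, and whether a drug terminates them. `afpop` is an R toolkit for
studying these questions *in silico*, aimed at cardiac-electrophysiology
modellers. It builds an experimentally calibrated *population of models*:
the eleven maximal conductances of a chronic-AF-remodeled human atrial
cell model (Courtemanche–Ramirez–Nattel kinetics with standard AF
remodeling) are scaled by Latin-hypercube multipliers in [0, 3], each
candidate is paced at 1–4 Hz, and only candidates whose action-potential
biomarkers (APD20/50/90, APA, RMP, V20 and the APD rate-adaptation ratios)
fall inside a physiologic envelope are accepted:

* monodomain reaction–diffusion tissue (∂V/∂t = −I_ion/C_m + D∇²V) on 2-D
  sheets, 1-D strips and icosphere surfaces, with a compiled
  Rush–Larsen / forward-Euler kernel;
* rotor analysis: Hilbert-transform phase maps, phase-singularity
  detection by topological charge (winding number ±2π around each mesh
  face), core tracking, dominant frequency (DF, Welch periodogram peak in
  1–20 Hz), rotor-meandering area (RM, convex hull of the core
  trajectory), and termination classification (core collision vs other);
* in-silico pharmacology: any conductance can be blocked at a chosen
  fraction and onset — the scripted experiment is 50% gCaL (L-type
  calcium) block of every model that sustains reentry;
* statistics: Mann–Whitney U comparisons (sustained vs unsustained;
  terminated vs persisting under block) and partial correlations (PCr) of
  each conductance with DF, RM and their block-induced changes,
  controlling for the other ten conductances.

Everything is seeded and deterministic: a configuration plus a seed
reproduces every table bit-for-bit.

## Worked example

A single cell, its biomarkers, and a small population:

```r
library(afpop)

p  <- af_cell_params()                      # chronic-AF remodeled baseline
tr <- simulate_cell(p, pacing_protocol(frequency = 1, beats = 3))
compute_ap_biomarkers(tr, beat_window = c(2000, 3000))
#> # A tibble: 1 × 9
#>   apd20 apd50 apd90   apa   rmp   v20 t_takeoff excited repolarized
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>     <dbl> <lgl>   <lgl>
#> 1  4.65  63.0  138.  117. -84.1 -12.9     2002. TRUE    TRUE
```

An AF-remodeled atrial AP: short (APD90 ≈ 138 ms), triangular
(APD50 ≪ APD90), resting near −84 mV with a ~117 mV upstroke. The full
study pipeline is two calls:

```r
base <- run_maintenance_experiment(experiment_config(seed = 101))
base
glance(base)

blk <- run_ical_block_experiment(base)
glance(blk)
```

`base$population` is the calibrated-population tibble (one row per
candidate, with acceptance flags and rejection reasons), `tidy(base)` the
per-model reentry biomarkers, `base$comparison` the sustained-vs-
unsustained Mann–Whitney table, and `base$pcr_df` / `base$pcr_rm` the
partial correlations. `autoplot()` methods and `plot_pcr_heatmap()` give
the standard views. See the output shown in
`vignettes/rotor-population-methods.Rmd` for what the numbers mean; at
desk scale a few percent of candidates calibrate, about two-thirds of the
simulated models sustain reentry for the full basal window, and sustained
models sit at visibly higher sodium-conductance multipliers.

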