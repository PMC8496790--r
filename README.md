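# opmapr — cardiac optical mapping analysis in R

`opmapr` turns voltage-sensitive-dye fluorescence movies of cardiac tissue
into the three quantities electrophysiologists use to characterize
pro-arrhythmic substrate, and provides the clustered statistics needed to
compare groups of animals:

1. **Local activation times (LAT)** — per pixel, the instant of steepest
   fluorescence upstroke (max dV/dt, with parabolic sub-frame
   interpolation), after Gaussian spatial binning, zero-phase 0–100 Hz
   filtering, diastolic-baseline drift correction with normalization, and
   signal-to-noise masking.
2. **Conduction velocity (CV)** — a local polynomial surface T(x, y) is
   fit to the LAT map around every pixel and the inverse-gradient identity
   **v** = ∇T/|∇T|² converts its gradient into a velocity vector in m/s.
3. **Slow-conduction (SC) regions** — pixels with speed < 0.2 m/s form a
   binary image; connected components under 4-connectivity (no diagonals)
   are labeled, components of 2+ pixels counted and measured in mm²
   (one pixel = (17 mm / 100 px)² = 0.0289 mm²). Per recording the
   pipeline reports percent SC of the ROI, the component count, and the
   component areas.

For study-level analysis, `fit_mixed()` fits the REML linear mixed model

```
outcome ~ class + train + position + class:train + class:position + (1 | animal)
```

(9 predictor terms for the control/persistent-AF × S1/S2 × 4-pacing-site
design) with mean-centered marginal Wald contrasts, and
`design_effect()` / `effective_sample_size()` implement
D_eff = 1 + (m − 1)·ICC and n_eff = n/D_eff for clustered samples.

Because no recordings are distributed, the package includes a synthetic
scene generator (`scene_spec()`, `make_movie()`): an eikonal fast-sweeping
solver propagates a wavefront through a prescribed speed field (slow
patches, block lines, edge or point pacing sources) and emits a movie with
AP-shaped traces, drift and noise — plus the exact ground truth, so every
stage is testable.

## Worked example

Simulate a 100 × 100, 3000 fps recording in which a vertical strip
conducting at 0.1 m/s covers a quarter of the field (background 0.5 m/s),
with acquisition noise and drift, then run the full analysis:

```r
library(opmapr)

spec <- scene_spec(
  patches = list(list(shape = "rect", rows = c(1, 100),
                      cols = c(38, 62), speed_mps = 0.1)),
  noise_sd = 0.05, drift_per_s = 0.1, seed = 42)
sim <- make_movie(spec)
sim$truth
#> <ground_truth> 100 x 100 px, 25.0% slow (<0.2 m/s), 1 component(s) of 2+ px

res <- run_pipeline(sim$movie, default_config())
res$report
#> <region_report> 26.0% SC of 10000 ROI px; 1 component(s) of 2+ px, mean area 75.140 mm^2
```

The pipeline recovers the 25% slow strip as 26.0% of the ROI (the one
extra point comes from the transition band where the surface fit straddles
the patch boundary) and segments it as a single connected region.

Study-level statistics on a simulated 7-animal table (55 observations:
7 × 4 positions × 2 trains − 1 missing), with a class-specific premature-
pacing effect built in:

```r
tab <- make_study_table(study_design(seed = 42))
fit <- fit_mixed(tab, outcome = "outcome")
fit
#> <model_fit> 55 obs, 9 predictor terms; animal var 4.21, residual var 39.8, ICC 0.096
#>   class effect: 27.04 (SE 2.32, p = 2.87e-31)
#>   S2-S1 in control: -1.47 (SE 2.57, p = 0.567)
#>   S2-S1 in persistentAF: 12.74 (SE 2.27, p = 2.08e-08)

deff <- design_effect(7.9, fit$icc)
effective_sample_size(nrow(tab), deff)
#> [1] 33
```

The marginal contrasts read as: persistent-AF recordings differ from
control by ~27 outcome units; the premature (S2) beat shifts the outcome
by ~13 units in AF animals but not in controls — the class × train
interaction the model is built to expose. The ICC (here 0.096) measures
how much of the remaining variance is between-animal clustering, and the
effective sample size discounts the 55 clustered observations accordingly.

## Command line

A thin wrapper at `inst/cli/opmap` exposes the pipeline as
`simulate | analyze | stats | all` subcommands driven by a YAML config;
every output directory receives the exact config and seed needed to
regenerate it:

```sh
Rscript inst/cli/opmap all --out=run1 --seed=7
Rscript inst/cli/opmap stats --table=outcomes.csv --out=run1
```

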