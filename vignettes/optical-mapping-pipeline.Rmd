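---
title: "From fluorescence movies to slow-conduction statistics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fluorescence movies to slow-conduction statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmapr)
```

## The measurement problem

Voltage-sensitive-dye optical mapping films the spread of electrical
activation across cardiac tissue: a camera records a fluorescence movie
(here nominally 100 × 100 pixels over a 17 mm × 17 mm field of view at
3000 frames/s) in which each pixel's trace follows the local transmembrane
potential. Three quantities of clinical interest are derived per recording:

1. the **local activation time (LAT)** of each pixel — when the upstroke of
   the action potential passes through it;
2. the **conduction velocity (CV)** — how fast and in which direction the
   wavefront moves, obtained from the spatial gradient of the LAT surface;
3. **slow-conduction (SC) regions** — connected patches where the speed
   falls below 0.2 m/s, a widely used marker of pro-arrhythmic substrate.
   Per recording the pipeline reports the percentage of the region of
   interest that conducts slowly, the number of connected SC regions larger
   than one pixel, and their areas in mm² (one pixel = (17/100)² =
   0.0289 mm²).

Recordings come from S1/S2 pacing protocols (a drive train plus one
premature beat) delivered from four sites around the field of view, in
control animals and in animals with a history of persistent atrial
fibrillation. The per-recording outcomes then feed a clustered statistical
analysis (multiple recordings per animal).

Because raw animal recordings are not available, the package ships a
synthetic scene generator that produces movies with *known* activation
structure; every stage of the pipeline is validated against that ground
truth.

## Synthetic scenes

`scene_spec()` + `make_movie()` build a movie from a prescribed speed
field:

* **Front propagation.** The true LAT map solves the eikonal equation
  |∇T| = 1/v on the pixel grid with a first-order upwind fast-sweeping
  solver; travel cost per pixel is `pixel_size / speed`. We chose the
  axis-neighbor upwind scheme over an 8-neighbor graph distance because the
  latter's metric error (up to ~8% at 22.5°) exceeds a pixel over realistic
  distances, while the upwind scheme stays within one pixel of the exact
  travel time on a 50 × 50 grid (verified against the closed-form d/v
  solution). For point sources the solver seeds exact straight-line times
  in a 3-pixel disk ("source factorization"), which removes the scheme's
  characteristic accuracy loss around a point source. Edge sources
  stimulate the whole first tissue line, producing a plane wave, as a
  pacing wire along that edge would.
* **Block lines** are rasterized to pixels of effectively zero speed; the
  front must detour around them, and pixels the front never reaches are
  flagged in the ground truth rather than silently truncated.
* **Waveform.** Each activated pixel follows a logistic upstroke
  (`upstroke_ms`, default 2 ms, measured 2%–98%), a plateau (`apd_ms`,
  default 50 ms) and an exponential recovery. The steepest point of the
  upstroke is placed *at* the pixel's LAT: the field defines LAT as the
  moment of maximum dV/dt, so aligning the generator with that convention
  keeps ground truth and detector bias-free with respect to each other.
* **Recording model.** A 10 ms quiet pre-stimulus baseline precedes the
  first activation (`baseline_ms`) — without it the earliest-activating
  pixels' upstrokes would be cut off by the recording start, which no real
  protocol does. A linear baseline drift (`drift_per_s`, default
  0.1 amplitude-units/s) and white Gaussian pixel noise (`noise_sd`,
  default 0.05 of the AP amplitude, i.e. amplitude SNR ≈ 20) are added
  last. The camera system's actual noise and drift magnitudes are not
  published, so these defaults are deliberate, plausible choices and both
  are exposed in the configuration. An optional `inactive_margin_px`
  surrounds the tissue with signal-free pixels to exercise the
  signal-quality mask.
* The generator's noise is *white and additive* and its drift *linear*;
  real recordings add motion residue, dye bleaching curvature, and shot
  noise whose variance tracks intensity. Passing the round-trip tests
  therefore demonstrates correctness of the algorithms under the stated
  noise model, not performance on every pathology of real data.

`study_design()` + `make_study_table()` generate the clustered outcome
tables: animals nested in class (control vs persistent AF), crossed with 4
pacing positions and 2 train levels, with additive fixed effects, a
Gaussian per-animal random intercept, and declared missing cells. The
default layout is 7 animals (3 control, 4 AF) × 4 positions × 2 trains − 1
missing = 55 rows.

## Preprocessing

`preprocess_movie()` chains four steps, each exposed separately:

* **Gaussian binning** (`spatial_bin`): each frame is convolved with a
  normalized Gaussian kernel of size 3 or 5 (σ = size/4, truncated and
  renormalized). Borders are edge-replicated, so constant frames pass
  through unchanged.
* **Temporal filtering** (`temporal_filter`): a zero-phase (forward-
  backward) Butterworth filter, order 4 by default, low-pass at 100 Hz when
  the lower band edge is 0. Zero-phase application preserves upstroke
  timing exactly. Traces are mean-anchored and constant-padded by three
  filter time constants before the forward-backward pass; reflection
  padding was rejected because it mirrors an early upstroke into a
  fictitious pre-recording deflection that the activation detector would
  find.
* **Drift correction + normalization** (`drift_correct_normalize`): a
  polynomial baseline (order 2 by default) is estimated per pixel and
  subtracted, then the trace is mapped affinely onto [0, 1]. The baseline
  must pass through the *diastolic* samples, not the least-squares middle
  of the trace — a plain polynomial fit absorbs part of the action
  potential itself. The estimator therefore starts from the trace's 10th
  percentile as a constant baseline and iterates (4×): select samples in
  the lower 30% band of the current residual range, refit the polynomial
  on them. Starting from the full least-squares fit instead can select
  only one end of a trace whose AP comes early, and the refit then
  extrapolates without support; the quantile start anchors the selection
  at both quiet ends. The operation is idempotent, constant traces map to
  zeros, and on synthetic APs with linear drift the corrected trace
  correlates with the clean AP above 0.99.
* **SNR masking** (`snr_mask`): per pixel, the trace is detrended, the
  noise SD estimated robustly from frame-to-frame differences (median
  absolute successive difference, Gaussian-scaled), and the SNR defined as
  the detrended peak-to-peak amplitude over the *expected* peak-to-peak
  excursion of pure noise of that SD and trace length. A noise-only pixel
  scores ≈ 1 by construction, independent of the noise level; tissue
  pixels score an order of magnitude higher; the default threshold is 3.
  The mask is computed on the binned movie *before* the 100 Hz low-pass:
  once the noise has been band-limited, successive-difference estimators
  (and quiet-window statistics generally) collapse, because heavily
  correlated noise locally resembles signal. The reference acquisition
  software's masking algorithm is unpublished; this definition is the
  package's own and is recorded in every run's configuration.

## Activation detection

`local_activation_times()` marks each masked pixel's LAT as the time of
maximum temporal derivative of its normalized trace — the standard
optical-mapping criterion — within an optional analysis window (one paced
beat per call; the caller supplies the window, e.g. the last S1 and the
following S2). The derivative peak is refined by parabolic interpolation
over the three neighboring derivative samples: at 3000 frames/s a frame is
0.33 ms, and integer-frame LATs would visibly quantize downstream velocity
estimates. Pixels whose in-window amplitude stays below `amplitude_floor`
(default 0.3 on the normalized scale) are left undefined. A 50%-amplitude
crossing criterion is available behind `method = "half_amplitude"` since
the acquisition software's exact criterion is not documented; on clean
symmetric upstrokes the two agree to well under a millisecond.

## Conduction velocity

`cv_map()` fits, around every pixel, a polynomial surface T(x, y) (order 2
by default) to the defined LATs in a circular neighborhood (radius 3
pixels by default) by least squares, takes the fitted spatial gradient
g = ∇T at the center, and applies the inverse-gradient identity
**v** = g/|g|² — the wavefront moves normal to its isochrones at speed
1/|g|. With T in ms and coordinates in mm, speeds come out in m/s. The
quadratic-surface/radius-3 default follows the established practice of
polynomial LAT-surface fitting for velocity estimation; both knobs are
configuration keys because the exact window used for the original
recordings is unreported.

Degenerate pixels are *excluded, never classified*: undefined LAT,
underdetermined neighborhoods (fewer points than coefficients), flat
gradients below `gradient_floor` (quasi-simultaneous activation has no
meaningful direction), and speeds above the physiological cap
(`speed_cap_mps`, default 2 m/s). Each exclusion carries its reason, and
the counts are logged by the pipeline. On noise-free plane waves the
estimator is exact to floating precision; on a radial wave (the hardest
smooth case for a quadratic, since √(x²+y²) has unbounded curvature at the
source) interior errors stay below 5% in speed and 5° in direction.

## Slow-conduction regions

`classify_slow()` thresholds valid pixels at `threshold_mps` (default
0.2 m/s, strict `<`). `label_components()` groups slow pixels by
4-connectivity — horizontal and vertical neighbors only, diagonals
deliberately excluded — with a two-pass union-find; the tests verify it
pixel-for-pixel against an independent brute-force flood fill on hundreds
of random maps. `region_report()` then computes:

* `percent_sc` — slow pixels as a share of the region of interest, taken
  from the binary image *before* any component filtering, so single-pixel
  components count toward the percentage;
* `n_components` and `component_areas_mm2` — only components of 2+ pixels
  are counted and measured (pixel count × 0.0289 mm²); an empty count
  yields an undefined (NA) mean area, never 0.

The ROI denominator is the SNR mask intersected with the valid-velocity
pixels; whether the original analysis also excluded invalid-CV pixels from
the denominator is not stated, so the choice is recorded in the report.
`run_pipeline()` chains all stages deterministically and labels any stage
failure with the stage name.

## Study statistics

`fit_mixed()` fits, by REML (`lme4`), the model

    outcome ~ class + train + position + class:train + class:position + (1 | animal)

— 9 fixed-effect predictor terms for the 2 × 2 × 4 design, with the animal
random intercept absorbing the within-animal clustering. Main effects in
the presence of interactions are assessed the way clustered-study reports
do it: marginal (adjusted) means that average over the other factors
("mean centering"), compared by asymptotic Wald z tests (`emmeans` with
asymptotic degrees of freedom), two-sided. A singular fit returns ICC 0
with a note instead of an error. The intraclass correlation is
σ²_animal/(σ²_animal + σ²_resid); `design_effect()` implements
D_eff = 1 + (m − 1)·ICC and `effective_sample_size()` divides the
observation count by it, rounding half-up (this rounding reproduces the
published effective sample sizes n = 14 at ICC 0.420 and n = 27 at ICC
0.150 for m = 7.9 and 55 observations).

`summarize_s2()` produces the descriptive mean ± SD tables of
shortest-captured S2 intervals with the sample (n−1) standard deviation
and half-up rounding to whole milliseconds; groups with fewer than two
values keep their mean but are flagged with an undefined SD.

Two statistical caveats worth knowing:

* With only 7 animals, the REML ICC is noisy: under a *null* animal effect
  the estimate exceeds 0.05 in roughly a fifth of replicates, and with a
  true ICC of 0.42 the mean estimate over replicates sits slightly below
  the target. The tests assert what this design can support (mean recovery
  within 0.05; median ≈ 0 under the null).
* Wald (asymptotic) intervals with 7 clusters are mildly anti-conservative;
  simulated 95% CI coverage of the class-specific S2−S1 contrast lands in
  the low-to-mid 90s, which the acceptance suite checks against a
  90–99% band.

## Numerical and scale choices

Validation runs use grids from 20 × 20 (property sweeps, hundreds of
replicates) through 40–50 × 50 (oracle comparisons) up to the full
100 × 100 × ~570-frame geometry for the end-to-end recovery checks, and
500 replicates for the mixed-model recovery study; these sizes make the
whole validation suite run in about two minutes while still exercising the
full-scale geometry where it matters. Ties in the activation detector
resolve to the earliest frame before interpolation; the parabolic shift is
clamped to ±half a frame; the eikonal sweeps stop when an entire 4-sweep
cycle changes no pixel by more than 10⁻⁹ ms.

## Limitations

The generator produces kinematic wavefronts, not electrophysiology: no
wavefront curvature–velocity coupling, no restitution, no fractionation,
no re-entry. Repolarization is a fixed template, so the package measures
nothing about action-potential duration. Conduction-block *lines* are
visible in the LAT maps the pipeline writes, but no automatic line
detector is provided. Fiber orientation and anisotropy are outside scope.
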