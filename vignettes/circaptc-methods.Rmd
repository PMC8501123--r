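---
title: "Phase transition curves from single-cell traces: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase transition curves from single-cell traces: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaptc)
```

## The measurement model

The package analyzes hourly fluorescence traces of a circadian
transcriptional reporter in individually tracked nuclei over a nine-day
recording, with a single pharmacological or physiological cue applied
mid-recording (4.5 days in, by default). Clocks in cultured fibroblast-like
cells are cell-autonomous and desynchronize within a few days, so at the
moment of the cue the population covers all clock phases; each cell then
acts as one probe of the resetting map at its own phase. A full phase
transition curve (PTC) — new phase as a function of old phase — is thereby
obtained from a single culture.

The per-cell analysis assumes that within each fitting window the signal is
reasonably stationary: a single harmonic
$y(t) \approx m + A\cos\big(2\pi(t - t_\mathrm{peak})/\tau\big)$
plus noise, riding on a trend much slower than circadian. Cells whose
dynamics violate this (dividing, dying, transiently suppressed) are removed
by the R² and period filters rather than modelled. Dynamics *through* the
cue (transients, amplitude effects) are deliberately not modelled: the
method compares two stationary windows on either side.

## Pipeline and tunable parameters

1. **Full-span selection.** Only cells observed at every timepoint enter
   the analysis; per-stage counts are kept as a funnel report.
2. **Detrending** (`detrend_zscore()`): running-average trend, window
   `detrend_window_h = 48` h (samples, odd count, truncated at the edges),
   subtracted and scaled by the residual SD. 48 h passes circadian
   oscillation to the residual while absorbing baseline drift; the
   alternative `sd_mode = "raw"` divides by the raw-track SD instead — the
   two differ only by a per-cell constant and do not change any phase.
3. **Cosine scan** (`fit_cosine_scan()`): linear least squares per
   candidate period over `tau_min = 20` to `tau_max = 32` h in
   `tau_step = 0.1` h increments; best R² wins. The grid is exhaustive, so
   the estimate is the global grid optimum; a 10x-denser independent
   re-implementation (`brute_force_fit_oracle()`) bounds the grid error in
   the tests.
4. **Rhythmicity and quality gates:** R² > `r2_min = 0.5` in *both*
   windows (strict inequality), fitted periods within
   `tau_bounds = [22, 29]` h (bounds inclusive; the exclusion rule is
   "> 29 or < 22"). Both windows must pass because both phases enter every
   downstream quantity.
5. **Phases** (`tipa_old_phase()`, `new_phase_from_after_fit()`): both
   referenced to the cue time and normalized by the period. The pre-cue
   phase is extended through the cue at the *post*-cue period (the TIPA
   "null curve"), so the old/new comparison is period-independent; when the
   two periods agree this reduces exactly to the naive phase difference.
   Default windows are 24–96 h and 120–192 h; the post-cue window is
   configurable (e.g. 120–196 h) since reasonable variants exist and the
   PTC topology is insensitive to the choice.
6. **Resetting models and tests** (`fit_type1()`, `fit_type0()`,
   `bootstrap_*()`): described below; `bootstrap_B = 10000` by default,
   seeds mandatory in the API.

## Conventions

* Phases live in $[0,1)$ (fraction of a period), shifts in $[-0.5, 0.5)$.
* Wrap boundary: exactly $+0.5$ maps to $-0.5$ (half-open, deterministic).
* Sign: **advance is positive** — after an advancing cue the clock sits
  further along its cycle. The convention is arbitrary but is applied
  consistently across shifts, models and metrics.
* Period-scan ties (equal R²) resolve to the smaller period.
* The cosine model keeps a mesor term even on detrended (zero-mean) data;
  it is harmless and makes the fit a standard three-parameter harmonic
  regression.

## Fourier resetting models

Resetting topology is classified into the two canonical classes: a PTC of
mean slope one (type-1, "weak") versus mean slope zero (type-0, "strong").
Both are represented by one two-harmonic periodic curve
$f(x) = a_0 + a_1\cos 2\pi x + b_1 \sin 2\pi x + a_2\cos 4\pi x +
b_2\sin 4\pi x$, fitted by least squares:

* **type-1**: fitted to the PRC (shift vs. old phase); the implied PTC
  $\hat y = x + f(x)$ has mean slope exactly 1 by construction.
* **type-0**: fitted to the PTC directly; $\hat y = f(x)$ has mean slope 0.

Three numerical choices deserve note:

* **Fixed fundamental frequency.** The fundamental is pinned to one cycle
  per unit old phase. With period-normalized, duplicated data a free
  frequency is essentially unidentified and only destabilizes the fit.
* **x-duplication.** Data are duplicated one cycle to the right before
  fitting, for parity with the conventional double-plotted procedure. All
  five basis functions are 1-periodic, so this provably leaves the
  coefficients unchanged; the test suite asserts the identity to 1e-10.
* **y-unwrapping for type-0.** The PTC's y-axis is circular; a final-phase
  cluster straddling the 0/1 seam would otherwise read as a ±1 jump and
  inflate the RMSE to ~0.5. Each new phase is therefore shifted by an
  integer to lie within half a cycle of the circular mean before fitting.
  RMSEs of both models are computed on residuals wrapped to
  $[-0.5, 0.5)$, in the same (new-phase) units, so the two are directly
  comparable.

Derived metrics are read off a dense grid (step 0.001 cycles): maximal
advance/delay and the phase of maximal absolute shift (type-1 range), and
the circular-mean final phase with its range (type-0 range). A saturating
type-0 response attains the wrap bound $|\Delta\phi| = 0.5$ — half a cycle,
±12 h on a 24 h clock — by construction.

## Bootstrap inference

All tests resample cells i.i.d. with replacement and use add-one smoothed
p-values, $(1 + \#\{\text{exceedances}\})/(B+1)$.

* **Response test** (one-sided): the null distribution is the maximal
  absolute shift of type-1 fits to control resamples of the test group's
  size; significance at p < 0.05.
* **Model selection** (one-sided): resample the treated well, fit both
  models, collect $D = \mathrm{RMSE}_0 - \mathrm{RMSE}_1$; type-0 is
  accepted when $D < 0$ in more than 95 % of resamples.
* **Group difference** (two-sided): percentile 95 % CI of the difference in
  a chosen summary metric over paired resamples; rejection when 0 is
  outside.
* **Period change**: per-cell $\Delta\tau = \tau_\text{after} -
  \tau_\text{before}$, compared between groups by a pooled-variance
  two-sided t-test.

One operating characteristic matters in practice: the response test's null
distribution is generated from a *finite* control, so each resample carries
the control's own estimation noise on top of the sampling noise of a fresh
well. With a control of similar size to the test group the test is
conservative (empirical size well below 0.05); with a control much larger
than the test group it holds its nominal size. The package's calibration
study (`calibration_suite()`) therefore uses one large pooled null control
(2000 pairs) against 150-pair test wells — the regime in which the
bootstrap null approximates the statistic's sampling distribution — and
verifies the empirical size against exact binomial bounds, alongside
selection power (strong type-0 chosen, weak type-1 retained) and type-1
parameter recovery.

## The synthetic population

`simulate_population()` generates the study conditions the pipeline is
designed for: `n_cells = 400` cells, 216 h at 1 h sampling, cue at 108 h.
Initial phases are uniform on the cycle (the mixed-phase prerequisite;
checked by a Rayleigh test in the suite). Start periods are
$\mathcal N(26, 1^2)$ h truncated to $[20, 32]$, with a linear-in-time
instantaneous-period drift of $-1/9$ h per day so the population moves from
about 26 h early in the recording toward 25 h at its end — giving the
before and after windows genuinely different mean periods, which is what
makes TIPA necessary. Traces are
$\text{trend}(t) + g(t)\,A\cos(2\pi\Phi(t)) + \varepsilon$ with
$\Phi(t)$ the integrated instantaneous frequency (closed form), a slow
logistic baseline (timescale 72 h, safely below the 48 h detrending band),
a mild linear gain fade, and Gaussian measurement noise (SD 0.2 relative to
unit amplitude by default).

Resetting is an instantaneous phase jump at the cue drawn from a sinusoidal
circle-map family (`response_map()`): identity (none),
$x + A\sin 2\pi(x-\psi)$ with $2\pi A < 1$ (type-1, degree-1 circle map),
or $c + B\sin 2\pi(x-\psi)$ (type-0, degree-0), each plus Gaussian phase
noise. This family is the simplest one expressible exactly by the analysis
models, which is the point: recovery tests then have closed-form truth.
What the generator does *not* emulate: cell division and death, transient
amplitude suppression after strong cues, frame drift, or non-stationary
noise — so green tests certify the estimator chain, not robustness to every
artefact of real imaging. Statistical calibration studies
(`simulate_phase_pairs()`) sample at the phase-pair level directly, since
trace-to-pair fidelity is certified separately by the end-to-end recovery
tests.

## Imaging front end

The optional imaging module is an explicit simplification of a nuclei
segmentation/tracking pipeline, validated only against synthetic movies
with known ground truth: difference-of-Gaussians band-pass at the expected
feature width (25 px), Otsu threshold, connected components, an equivalent-
diameter gate of 9–35 px, border exclusion, mean background (outside
nuclei) subtraction from the reporter channel, and greedy global-nearest-
neighbour linking under a 50 px cap with a 24 h minimum lifetime. Ties
break by smaller displacement, then lower object index. The synthetic
renderer draws soft-edged disk nuclei so the measured equivalent diameter
matches the nominal one; a `min_separation` placement option provides
overlap-free fixtures where per-nucleus ground truth must be unambiguous.
On clean movies the recovered traces correlate with truth above 0.999 up to
an affine gain, and link accuracy exceeds 95 % at 10 px steps; neither
robust-background thresholding nor declumping of touching nuclei is
reproduced, and crowded fields are out of scope (the renderer warns above a
documented density).

## Degenerate inputs and edge cases

* Flat traces (residual SD below 1e-10 of the raw scale) raise degenerate-
  trace errors, or are dropped with a warning in table-level calls.
* Zero-variance fit windows and windows outside the trace error out.
* The running-average detrender is *not* a projection: re-detrending an
  already detrended trace changes it by a few percent (the truncated
  window leaves a periodic ripple). The suite asserts the true contraction
  behaviour rather than exact idempotence.
* Circular means of balanced antipodal data are undefined and flagged.
* Degenerate bootstrap resamples (no dispersion in old phase) are redrawn
  up to a cap and counted.
* Fewer than `min_pairs = 30` filtered pairs flags a PTC as under-powered
  (warning; soft-failure exit code 3 in the CLI).

## Problem sizes in the test suite

The suite runs everything at sizes chosen to exercise the asymptotics the
claims rely on while staying desk-scale: end-to-end recovery at 400 cells,
bootstrap calibration over 200 null wells of 150 pairs at B = 1000 against
a 2000-pair control, classification power at 100 repeats per scenario, and
imaging checks on 10–20 nuclei over ~40–50 frames at 400 px. Production
analyses should use the full `B = 10000` defaults.

## Known limitations

* Phase estimates are window-stationary summaries; rapid post-cue
  transients are invisible by design.
* The two-harmonic model cannot represent PTCs with more than two
  advance/delay lobes per cycle (none are expected biologically).
* The response test's conservativeness with small controls is inherent to
  resampling a finite control; use generous untreated wells.
* Classification near the type-1/type-0 transition (the singularity
  neighbourhood) is genuinely ambiguous; the dose-panel view
  (`bin_phase_plane()`) is the intended instrument there, not a single
  p-value.
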