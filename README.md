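# circaptc

Reconstruction and statistical characterization of circadian **phase
transition curves (PTCs)** from long-term single-cell reporter imaging.

## The problem

Circadian clocks in cultured cells are cell-autonomous: an unsynchronized
population spreads its clock phases over the whole cycle within a few days.
That makes a single culture a complete phase-scanning experiment — apply one
resetting cue (a drug, a serum, a signalling agonist) at one moment, and
every cell reports how a clock at *its* phase responds. Tracking individual
nuclei before and after the cue therefore yields a full, high-resolution PTC
(new phase vs. old phase) from one well, where the conventional protocol
needs a separate synchronized culture per treatment time.

`circaptc` implements the computational half of that assay for
chronobiologists and screeners: trace preprocessing, per-cell phase
estimation, PTC assembly, resetting-topology classification with bootstrap
inference, dose-panel summaries, plus a fully synthetic oscillator
population (and an optional simplified imaging front end) so that every
stage is testable without microscope data.

## The method in brief

Per cell, the detrended reporter trace is fitted with a cosine
`y ≈ m + a·cos(2πt/τ) + b·sin(2πt/τ)` independently in a pre-cue and a
post-cue window, scanning τ over 20–32 h in 0.1 h steps and keeping the fit
maximizing R². Fits with R² > 0.5 in both windows and both periods inside
22–29 h enter the PTC. Because τ usually differs between windows, the
pre-cue phase is propagated through the cue with the *post*-cue period
(tau-independent phase analysis, TIPA): with θ the pre-cue fit's relative
phase at the cue,

    old phase  φ_old = θ = ((t_cue − t_peak,before) mod τ_before) / τ_before
    new phase  φ_new = ((t_cue − t_peak,after) mod τ_after) / τ_after
    shift      Δφ   = wrap(φ_new − φ_old) ∈ [−0.5, 0.5),  advance > 0

All phases are period-normalized to `[0, 1)`. The PTC is summarized by a
two-harmonic Fourier model
`f(x) = a₀ + a₁cos2πx + b₁sin2πx + a₂cos4πx + b₂sin4πx` fitted twice:
in PRC form (shift vs. φ_old; implied PTC has mean slope 1 — **type-1**,
weak resetting) and in PTC form (φ_new vs. φ_old; mean slope 0 — **type-0**,
strong resetting). Three bootstrap tests characterize a treatment: a
one-sided response test (null distribution of maximal |shift| from control
resamples), model selection by the resampled RMSE difference
(type-0 accepted when RMSE₀ < RMSE₁ in > 95 % of resamples), and a
two-sided percentile-CI test for group differences in any summary metric.

## Worked example

Simulate a 300-cell well given a weak (type-1) resetting cue of PRC
amplitude 0.12 at reference phase 0.6, reconstruct its PTC, and classify it
against an untreated control:

```r
library(circaptc)

sim <- simulate_population(sim_config(
  n_cells = 300,
  response = response_map("type1", A = 0.12, psi = 0.6, phase_noise_sd = 0.03),
  seed = 42))
ptc <- assemble_ptc(sim$tracks)
funnel_report(ptc)
#>   stage             n
#> 1 tracked         300
#> 2 full_span       300
#> 3 detrended       300
#> 4 rhythmic_both   300
#> 5 filtered        300

ctrl <- assemble_ptc(simulate_population(sim_config(
  n_cells = 2000, response = response_map("none", phase_noise_sd = 0.03),
  seed = 43))$tracks)

res <- classify_response(ptc, ctrl, B = 2000, seed = 1)
res$decision
#> [1] "type-1"
res$metrics
#>   kind    rmse n_pairs max_advance max_delay max_abs_shift phase_of_max
#> 1 type1 0.0436     300       0.126    -0.115         0.126        0.857
```

The response test rejects its null (observed maximal |shift| 0.126,
p = 5e-4, control 95 % null interval [0.004, 0.018]); model selection then
retains type-1 (RMSE₀ − RMSE₁ = +0.088, p_type0 ≈ 1). The fitted maximal
advance 0.126 and its phase 0.857 recover the generating map: a
`0.12·sin` PRC peaks at ψ + ¼ cycle = 0.85 with amplitude 0.12. Phase units
are fractions of a period; 0.126 of a 24 h cycle ≈ 3 h.

`autoplot(ptc, "ptc")` / `autoplot(ptc, "prc")` draw the double-plotted
curves, `bin_phase_plane()` + `plot_phase_plane()` build the dose-by-phase
heat map, and `tidy()` / `glance()` give broom-style summaries of fitted
models and bootstrap results. A thin command-line wrapper with subcommands
`simulate`, `analyze`, `classify`, `dose-panel`, `compare` and `qc` is
installed at `inst/cli/circaptc.R`.

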