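# nbackerp

An R package implementing a complete working-memory EEG/ERP analysis
pipeline for two-group developmental cohorts: adaptive n-back task
logic, EEG preprocessing, ICA-based ocular-artifact removal, P300
measurement, and the associated statistics — together with a
synthetic-data generator with known ground truth, so that every stage
is testable by parameter recovery without access to raw clinical EEG.

## Who this is for

Researchers analysing P300 event-related potentials from n-back
working-memory paradigms (e.g. clinical vs control adolescent cohorts),
and anyone who needs a reproducible, scriptable reference
implementation of the standard analysis chain:

- **Task engine** — adaptive staircase (level up at ≥90% block
  accuracy, down at ≤70%, stop after two blocks at an unchanged level;
  `run_staircase()`), EEG sequence generation with exact design counts
  (100 trials, 25 targets per block) and cross-level target exclusion
  (`generate_sequence()`), block scoring (hits − false alarms) and
  Corsi span scoring.
- **Preprocessing** — mastoid re-referencing, zero-phase Butterworth
  filtering (0.1 Hz HP, 120 Hz LP, 48–52 Hz notch), resampling to
  200 Hz, epoching with baseline correction (`rereference()`,
  `filter_resample()`, `epoch_baseline()`).
- **Artifact removal** — 32-component ICA on the 64 EEG channels,
  blink detection and blink topography, component scoring by z-scored
  temporal (VEOG/HEOG) and spatial (blink map) correlations with |z| > 2
  suspects, robust bad-channel detection, and a single composed
  removal + interpolation cleaning matrix (`fit_ica()`,
  `detect_blinks()`, `score_components()`, `build_cleaning_montage()`).
- **P300 measurement** — ±120 µV rejection, temporally proximal
  non-target balancing, condition averages, window-mean amplitude
  (300–700 / 300–500 / 500–700 ms) at Pz and four 7-channel ROIs, and
  50% fractional-area latency (`select_valid_trials()`,
  `balance_nontargets()`, `window_amplitude()`,
  `fractional_area_latency()`).
- **Statistics** — mixed group × load ANCOVA with an age covariate and
  homogeneity-of-regression gate, partial eta squared
  (η²p = F·df1/(F·df1+df2)), Fisher r-to-z correlation comparison,
  Benjamini–Hochberg FDR, linear-vs-quadratic AICc comparison with
  p = exp(ΔAICc/2), and Kaplan–Meier / log-rank analysis of achieved
  mean n-back level (`mixed_ancova()`, `partial_eta_sq()`,
  `correlate_and_compare()`, `bh_fdr()`, `lin_vs_quad_aicc()`,
  `km_logrank()`).

## Worked example

Simulate a small cohort, play the adaptive staircase, and compare the
groups' achieved levels:

```r
library(nbackerp)

co <- simulate_cohort(n_per_group = 16, seed = 11)
tapply(co$subjects$mean_nback_visual, co$subjects$group, mean)
#>  control      nf1
#> 2.987273 2.349614

km_logrank(split(co$subjects$mean_nback_visual, co$subjects$group))
#> log-rank chi-square = 14.976, df = 1, p = 0.0001089
```

The control group reaches a higher mean n-back level, and the log-rank
test on the achieved-level distributions is strongly significant — the
generator's default group capacity difference (0.9 levels) propagated
through the staircase.

Measure the P300 from a simulated recording and recover its ground
truth:

```r
mont <- make_montage()
co   <- simulate_cohort(2, seed = 5)
seqs <- list(generate_sequence(1, "eeg",
             eeg_sequence_config(n_trials = 10, n_targets = 3), seed = 1))
rec  <- simulate_recording(co, "S01", seqs, mont,
                           noise_config(background_rms_uV = 0, alpha_uV = 0,
                                        include_artifacts = FALSE))
ep   <- epoch_baseline(rec, c(-100, 900), c(-100, 0))
ev   <- average_evoked(ep, ep$meta$is_target, "target")
window_amplitude(ev, "Pz", c(300, 700))
#> [1] 13.14256        # ground truth for this subject/load: 13.15485 uV
fractional_area_latency(ev, window = c(300, 700))
#> [1] 508.9494        # ground truth latency: 509.1115 ms
```

With noise and artifacts enabled, the same chain runs through
`fit_ica()`/`score_components()`/`apply_cleaning()`; the end-to-end
pipeline over all stages is `run_pipeline(run_config(...))`, and a thin
CLI wrapper lives at `inst/cli/nbackerp-pipeline.R`.

Classical identities are one-liners:

```r
partial_eta_sq(11.077, 1, 28)   #> 0.283466
two_sample_t(means = c(69.88, 49.31), sds = c(18.53, 8.90),
             ns = c(16, 16))$t  #> 4.002621
aicc_evidence_p(97.74, 103.82)  #> 0.04783489
```

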