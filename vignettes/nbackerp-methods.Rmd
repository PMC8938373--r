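---
title: "Methods: simulating and analysing n-back P300 data with nbackerp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing n-back P300 data with nbackerp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbackerp)
```

## The problem

Working-memory studies in developmental cohorts (for example comparing
adolescents with neurofibromatosis type 1 to matched controls) commonly
combine an adaptive behavioral n-back task with a fixed-load EEG n-back
task, and quantify the P300 — the large parietal-maximal positivity
between roughly 300 and 800 ms after the stimulus — in terms of
window-mean amplitude, latency, and scalp topography. `nbackerp`
implements that whole chain as reusable, testable components: task
logic, EEG preprocessing, ICA-based ocular-artifact removal, P300
measurement, and the statistical layer. Because raw clinical EEG of this
kind is typically not public, the package also contains a first-class
synthetic-data generator with known ground truth; every downstream stage
is validated by parameter recovery against that ground truth rather than
against irreproducible group-level results.

## Task engine

**Adaptive staircase.** A block's accuracy (hits/targets; no response is
required on non-targets) drives the next block's load level: at or above
90% the level increases by one, at or below 70% it decreases by one
(floor at 1), otherwise it stays. The session terminates once two
consecutive blocks have been played at an unchanged level — i.e. after
the third block at a stable level — or at a 20-block safety cap. We read
"two blocks with unchanged level" as a counter over consecutive
zero transitions that resets whenever the level moves, and we count a
floor-clamped decrease as "unchanged"; both choices are exercised by
worked-trace tests. The capacity score is the mean level over all
administered blocks. Behavioral blocks contain 20 critical screens plus
one lead-in screen per load level, with exactly 6 targets among the
critical screens.

**EEG sequences.** EEG blocks are fixed-load (levels 1 and 2, order
1,2,2,1), 100 trials with exactly 25 targets. Two placement constraints
matter. First, a stimulus that would be a target at the *other* load
level is never shown (no immediate repeats in 2-back blocks; no
two-back matches in 1-back blocks). Second, consecutive targets are
rare; we cap the number of adjacent target pairs (default 6, the count
reported for 2-back blocks). A consequence worth noting: under the
cross-level rule consecutive targets are *impossible* in 1-back blocks
(two adjacent 1-back targets would produce three identical letters in a
row, which is a 2-back match), so 1-back target placement uses a
non-adjacent sampling scheme (a standard bijection between k
non-adjacent picks from m slots and k unrestricted picks from m-k+1
slots). Letters come from an 8-consonant alphabet (c, g, h, k, p, q, t,
w); the exact letter set of the original visual task is not specified
anywhere, so we reuse the auditory set. Onset jitter is drawn uniformly
from the 17 ms display-refresh grid within ±100 ms.

**Corsi scoring.** An ordered list of (sequence length, correct)
outcomes is truncated at the second cumulative failure and scored as the
mean of the two longest correctly repeated lengths, with flags for the
degenerate zero- and one-success cases.

## Synthetic cohort and recordings

`simulate_cohort()` draws two groups (default 16 per group, ages 11–17,
age- and sex-matched in pairs, a 9:7 male:female ratio)
with behavioral scores drawn from per-group Gaussians whose default
means and SDs follow the reference cohort profile (Conners inattention /
hyperactivity, Vineland composite, digit spans, four TEA-Ch subtests).
Mean n-back scores are not drawn directly: each subject gets a
working-memory capacity parameter (group difference 0.9 levels, age
slope 0.15 levels/year — chosen so that group separation and an
age-performance correlation of the size seen in adolescent cohorts
emerge) and a capacity-limited observer actually plays the staircase.
Corsi span similarly comes from simulated block-tapping sessions.
`group_scale = 0` collapses all group differences for null calibration.

The ERP ground truth per subject and load is a P300 pulse at Pz:
Gaussian in time (default sigma 70 ms) and Gaussian in geodesic distance
on the unit-sphere montage (FWHM 0.9 rad, chosen so the simulated
topography is decisively parietal-maximal). Ground-truth amplitudes are
expressed as **window-mean amplitude over 300–700 ms** — the quantity
the measurement layer itself reports (defaults
14.0 µV at 1-back, 11.5 µV at 2-back for targets; non-targets scaled by
0.35) — and converted internally to the equivalent pulse peak.
Latencies default to 510/532 ms (controls, 1-/2-back) with the clinical
group shifted earlier by 20 ms at 1-back and 55 ms at 2-back, matching
the reported follow-up differences; between-subject SDs are 2.5 µV and
25 ms.

Recordings are synthesised at 512 Hz over a 64-channel 10-10 montage
plus VEOG, HEOG and two mastoids. The montage geometry is built from
the standard 10-10 construction itself (midline at 10% arc steps, outer
ring at 72° inclination, intermediate electrodes by great-circle
interpolation), so all distances used for interpolation and spatial
fields are self-consistent. Background noise has a 1/f spectrum (flat
below 0.5 Hz) at 12 µV RMS per channel, split into spatially smooth
shared components (70% of the variance, reflecting volume conduction)
plus independent per-channel sensor noise, with a waxing-and-waning
10 Hz posterior alpha component on top; blinks arrive as a Poisson
process (default 12/min) with a 55 ms-sigma pulse, 200 µV at VEOG and
an 80 µV frontal scalp field; saccades are HEOG steps; bad channels
(always including TP7, a persistently bad electrode in the reference
design) are replaced by high-variance noise. The 12 µV single-trial RMS
was fixed so that ~40 averaged trials — a typical per-condition
valid-trial count in this paradigm — give a stable window-mean
(SE ≈ 1.5 µV) whose implied load-effect F at study scale is of the same
order as the reference value; no single-trial SNR is available
anywhere, so only trial counts and printed summary statistics anchor
this calibration.

All randomness flows from one master seed through labelled sub-streams
(`derive_seed(seed, label)`), so any object regenerates bit-identically.

## Preprocessing

Deterministic conditioning follows: re-reference to averaged mastoids
(scalp channels only; EOG and reference channels untouched), zero-phase
(forward–backward) Butterworth filtering — 0.1 Hz high-pass, 120 Hz
low-pass, 48–52 Hz band-stop, order 4 applied as cascaded order-2
sections for numerical stability at the very low relative high-pass
cutoff — and polyphase resampling to 200 Hz. The filters run at the
native rate *before* resampling: a 120 Hz low-pass is undefined at a
200 Hz target rate, so the literal order "down-sample, then filter"
cannot be executed for these cutoffs; the stage order is configurable
for sensitivity analyses. Epochs are cut on the sample grid (half-open
windows, time 0 at the stimulus-onset sample), default −600..1400 ms,
with −100..0 ms baseline subtraction; the analysis crop to −100..900 ms
and the 30 Hz low-pass are applied after artifact cleaning. Events too
close to the recording edge are dropped and logged. All units are µV
and ms throughout.

## Ocular artifact removal

Thirty-two ICA components are extracted from the 64 EEG channels only
(PCA reduction, then symmetric fixed-point ICA with a tanh
nonlinearity; deterministic under a fixed seed; components ordered by
explained variance and sign-fixed). The pipeline fits ICA on the
continuous filtered recording rather than on concatenated epochs:
epoch-boundary discontinuities measurably degrade the unmixing (in our
validation the blink component's mixing column aligned with the true
blink field at r = 0.99 when fit on continuous data versus r = 0.93 on
concatenated epochs, and blink suppression improved from ~81% to ~95%);
an epoched mode remains available by passing an epoch set to
`fit_ica()`. Blinks are detected on VEOG
band-passed 1–15 Hz at median + 5·MAD with a 300 ms refractory period —
thresholds of the original detection routine are not published, so
these are the package's choices — and the blink topography is the
50–250 ms mean of the blink-locked average over all EEG channels.

Each component receives three correlations: temporal with VEOG,
temporal with HEOG (all signals band-passed 1–20 Hz first), and spatial
between its mixing column and the blink topography. Each correlation
set is z-scored *across components*, so a score measures how unusual a
component is relative to the other components rather than its absolute
magnitude; components with any |z| > 2 are suspects. The study
confirmed suspects by visual inspection; we replace that step with an
automatic gate — a suspect is removed only if its raw |correlation|
also exceeds 0.2 — which prevents removing components that merely stick
out of a tight, uniformly low correlation distribution. If all
correlations in a set are equal (zero spread) the z-scores are defined
as 0 and a warning is logged.

Removal is the channel-space projector I − A·W over the removed
components (idempotent because unmixing·mixing is the identity on the
retained subspace). Bad channels — detected by a robust log-MAD²
variance z-score across channels (threshold 4; MAD rather than variance
so that blink excursions do not inflate frontal channels), plus a
forced list — are rebuilt by inverse-geodesic-distance weights over
their 6 nearest good channels, normalised to sum to one. Both matrices
compose into a single cleaning matrix applied once to the epoched data.

## P300 measurement

Epochs with any |value| > 120 µV on an EEG channel, and incorrect
trials, are rejected. Because correct non-targets outnumber correct
targets, counts are balanced per block: each valid target, in temporal
order, claims the unclaimed valid non-target with the smallest
trial-index distance (ties to the earlier trial). Averages are plain
arithmetic means; difference waves subtract sample-wise; grand averages
average subject evokeds unweighted.

Window-mean amplitude is reported for the full (300–700 ms), early
(300–500 ms) and late (500–700 ms) windows — endpoints inclusive on the
sample grid — at Pz and at four 7-channel regions (left/right ×
frontal/parietal; centroids F3, F4, P3, P4 with their six nearest
neighbours, fixed to the published channel lists). Fractional-area
latency is the time at which 50% of the area under the waveform within
300–700 ms has accumulated, computed trapezoidally with linear
interpolation at the crossing. Negative values are rectified to zero
first: the P300 is a positivity, and signed area can make the crossing
non-monotone; a signed-area mode exists behind a flag. A zero rectified
area yields a flagged missing latency. Conditions with fewer than 10
valid trials are flagged low-trial.

## Statistical layer

The mixed factorial ANCOVA handles one between-subject factor, any
number of two-level within-subject factors and one covariate, by the
per-subject contrast-score decomposition: for each subset of within
factors the ±1-coded cell means collapse to one score per subject, the
within effect is the intercept test on that score and its interactions
with group/covariate are the slopes (Type III sums of squares,
sum-to-zero contrasts, covariate mean-centred). With 1-df within
factors this is exactly the classical univariate mixed model and no
sphericity correction arises; the implementation is cross-checked
against base R's `aov` error-stratum decomposition. A
homogeneity-of-regression pre-test (group × covariate on the subject
means) gates the covariate at α = 0.05: when violated, the model is
downgraded to ANOVA and flagged. Every effect carries partial eta
squared via the F-identity η²p = F·df1/(F·df1 + df2). Note that adding
a covariate whose slope is exactly zero still changes F slightly
through the lost error df — the adjusted sums of squares, not the F,
are invariant.

Between-group correlation comparison uses Fisher's r-to-z with
SE = sqrt(1/(n1−3) + 1/(n2−3)); the boundary |r| = 1 is flagged rather
than compared. Multiple correlations per behavioral measure are
screened by canonical step-up Benjamini–Hochberg FDR at q = 0.10 (via
`p.adjust`); we note that published per-table FDR stars are not always
reproducible from printed p-values by the canonical procedure, and this
package makes no attempt to match any particular star pattern.

Linear-vs-quadratic comparisons fit both least-squares models and use
AICc = n·ln(RSS/n) + 2k + 2k(k+1)/(n−k−1) (k counting coefficients plus
the error scale; shared Gaussian constants cancel in differences), with
the evidence p = exp((AICc_quadratic − AICc_linear)/2). Degenerate
zero-residual fits are floored at machine scale so that noiseless
linear data yield "linear preferred" through the penalty alone.

Achieved mean n-back levels are compared by the Kaplan–Meier
product-limit estimator with a two-group log-rank test (via the
`survival` package), treating a higher achieved level as longer
survival; no censoring arises because every staircase session reaches a
terminal level. Follow-up simple-effect t-tests are pooled-variance
between groups and paired within group, uncorrected for multiplicity
(a corrected mode exists behind a flag).

## Parameter recovery and problem sizes

`power_recovery()` is the package's study-scale validation: per
replicate it simulates a cohort, draws 40 single-trial Pz epochs per
subject and load from the ground truth (1/f noise at the default RMS),
averages, measures amplitude and fractional-area latency, and runs the
2×2 group × load ANCOVA with age covariate. With the default effects
(55/20 ms group latency shifts, 2.5 µV load amplitude effect, 16 per
group) the group latency effect, the load amplitude effect, and the
group × load latency interaction (in the injected direction) are each
detected in well over 80% of replicates. This fast path deliberately
skips the continuous-recording and ICA stages, which are validated
separately: a noiseless recording round-trips the injected pulse at Pz
to under 1e-9 µV, and on a noisy recording with blinks the flagged
ocular component's removal cuts blink-locked frontal amplitude by more
than 90% while moving the Pz P300 window mean by less than 5%.

Test and demonstration problem sizes are deliberately small (2–4
subjects per group, 20–40 trial blocks, 256–512 Hz) — they exercise
every code path while keeping the suite quick to run; the study-scale
settings (16 per group, 100-trial blocks, 50 replicates) are used where
the claim being checked is about power at study scale.

## What the generator does and does not emulate

It emulates: the two-group, age-matched cohort structure with the
published score distributions; load- and group-dependent P300 amplitude
and latency with realistic between-subject spread; parietal-maximal
topography; 1/f + alpha background; frontal-topography blinks mirrored
in VEOG; HEOG saccades; persistently and sporadically bad channels; and
the full task logic generating the events. It does not emulate:
realistic head-geometry lead fields (the spatial model is a Gaussian on
a sphere), non-ocular artifacts (EMG bursts, line-noise transients
beyond a steady notch-testable sinusoid), trial-to-trial latency
jitter within a condition, or any dependence of P300 parameters on the
behavioral covariates. Passing tests therefore demonstrate that the
pipeline measures and detects what it claims under a controlled,
plausible signal model — not that the effect sizes themselves would
replicate in new clinical data.

## Known limitations

- BDF import/export is not implemented; recordings enter either through
  the simulator or the internal container format (BDF support is future
  work).
- The ANCOVA layer is restricted to two-level within factors (all the
  designs used here); general multi-level within factors would need
  sphericity handling.
- The blink detector assumes upward VEOG deflections; montages with
  inverted VEOG polarity need a sign flip at ingest.
- Fractional-area latency is rectified by default; for components that
  are genuinely biphasic the signed-area flag should be used and
  interpreted with care.
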