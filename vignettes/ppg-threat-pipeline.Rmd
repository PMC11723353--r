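---
title: "Detecting threat states from short smartwatch PPG windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting threat states from short smartwatch PPG windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A wrist-worn smartwatch samples a photoplethysmogram (PPG) — an optical
measure of blood-volume change — at 25 Hz. The goal is to decide, from a
single 12 s window (300 samples), whether the wearer is experiencing an
acute threat (fear/arousal) response. Two things make this hard:

1. **Signal quality.** Consumer wrist PPG is low-rate, noisy, and riddled
   with motion artifacts and baseline drift.
2. **Label integrity.** Training labels come from stimulus conditions
   (calm vs. threatening stimuli), not from the wearer's actual state.
   Some participants simply do not respond to the threatening stimulus
   ("non-responders"), so a substantial fraction of windows labeled
   *threat* contain perfectly calm physiology. Naive supervised training on
   such data learns from contradictions.

`ppgthreat` implements a complete pipeline for this setting: pulse-level
preprocessing, mixture-model label cleaning, a small 1D convolutional
pulse classifier, vote-based window decisions, evaluation metrics, and a
paired McNemar comparison — plus a seeded synthetic wrist-PPG generator so
the whole pipeline is testable and benchmarkable without access to any
participant recording.

## Preprocessing: from windows to single pulses

Each raw window passes through four deterministic stages
(`preprocess_window()`):

1. **Bandpass filter** (`bandpass_filter()`): order-3 Butterworth,
   0.5–8 Hz, applied forward–backward (`signal::filtfilt`) so the phase is
   zero and systolic peak positions are preserved. Content below 0.5 Hz is
   baseline wander; above 8 Hz, sensor noise.
2. **Valid-peak detection** (`detect_valid_peaks()`): candidate peaks are
   maxima of regions above an adaptive threshold (a 0.75 s moving average
   plus 0.1 signal SD); candidates must be strict local maxima, and
   candidates within 0.2 s of a window edge are ignored because zero-phase
   filtering leaves transients there. A validity screen then drops peaks
   whose every adjacent inter-beat interval deviates more than 30% from
   the median interval — the usual defense against motion-induced false
   peaks.
3. **Segmentation** (`segment_pulses()`): each surviving peak anchors one
   *single pulse* of 27 samples (≈1.1 s at 25 Hz) with the peak at
   position 14 — 13 samples strictly before and 13 strictly after.
   R indexing is 1-based, so `peak_offset` is 14.
4. **Amplitude screen** (`amplitude_filter()`): a pulse whose maximum
   absolute filtered value exceeds 25,000 ADC counts is discarded as an
   outlier (motion spikes that survived peak validation fail here).

## Mixture-model label cleaning

The core idea: within each labeled class, pulses are a mixture of
*normal* (label-consistent) and *anomalous* (ambiguous) signals. One
2-component Gaussian mixture is fitted per class over the 27-dimensional
pulses (`fit_class_gmm()`), and the component with the larger weight is
designated *normal* — the method presumes correctly-responding wearers are
the majority. Assignment is hard: a pulse is normal when the posterior
responsibility of the normal component is at least 0.5.

Two rules use these models (`filter_training()`, `filter_test()`):

* **Training** (default `"own_normal"`): a class-*c* training pulse is
  kept iff it is normal under class *c*'s own model, so only each class's
  normal group enters classifier training.
* **Test** (default `"both_abnormal"`): a pulse is removed only when
  *both* models call it anomalous — neither class claims it, so it is
  indiscernible. Both rules are available for either phase via
  configuration.

Two design choices deserve explanation, because both were forced by
observable failure modes of the obvious alternatives:

* **Fitting space.** Mixtures are fitted on *peak-normalized shapes*:
  each pulse is divided by its maximum absolute value, then standardized
  per dimension with pooled statistics. Raw wrist-PPG amplitude is
  dominated by contact pressure and skin optics — a per-subject gain that
  says nothing about affective state. Fitted on raw standardized pulses,
  the mixture reliably splits on subject gain (isolating one loud subject
  wholesale) instead of on label consistency. The classifier, by
  contrast, keeps plain per-dimension standardization; amplitude may
  legitimately inform it. Set `gmm_settings(shape_normalize = FALSE)` to
  fit on the shared standardized space instead.
* **Covariance structure.** The default is a *tied* full covariance
  (both components share one pooled 27×27 covariance; the EEE model in
  mclust's taxonomy). With per-component covariances, EM on few-subject
  pulse data maximizes likelihood by shrinking one component onto a
  single subject's tight pulse cluster — the classic near-singular
  collapse, which a small diagonal floor does not prevent. Tying the
  covariance removes that collapse direction entirely, and the split then
  lands on the normal-versus-anomalous axis.
  `gmm_settings(covariance_type = "full")` restores per-component
  covariances with diagonal regularization.

EM uses k-means initialization, 10 restarts, at most 200 iterations, a
1e-4 tolerance on the per-observation mean log-likelihood, and a fixed
seed; the winning restart's log-likelihood trace is stored in the model
(`fit_meta$loglik_trace`) and is non-decreasing by construction.

## The pulse classifier

`build_model()` constructs a compact 1D CNN over a 27-sample pulse:

| stage | output length × channels |
|---|---|
| conv 32 @ k3, valid | 25 × 32 |
| conv 32 @ k3, same | 25 × 32 |
| max-pool 4, stride 2 | 11 × 32 |
| conv 32 @ k3, valid | 9 × 32 |
| conv 32 @ k3, valid | 7 × 32 |
| max-pool 2, stride 2 | 3 × 32 |
| conv 64 @ k3, valid | 1 × 64 |
| flatten | 64 |
| dense 8 → dropout → dense 4 → dropout → dense 1 (sigmoid) | 1 |

Hidden activations are rectified-linear; training
(`train_classifier()`) minimizes binary cross-entropy with Adam
(learning rate 1e-3, batch 128), a stratified 20% validation split, an
epoch cap of 30, and validation-loss early stopping (patience 5) with
best-weight restoration. Inputs are standardized per dimension with
statistics stored in the model.

The network is implemented directly in vectorized R: convolutions are
im2col gathers followed by BLAS matrix products, max-pooling records
argmax offsets for its backward pass, and the whole forward/backward pair
is verified against finite differences in the test suite. At this network
size (≈4,700 parameters) that implementation trains a full benchmark model
in well under a minute, and it keeps every arithmetic step seeded, so
training is bit-reproducible.

## Window decisions and evaluation

A 12 s window is declared a **threat** when at least τ = 1/3 of its
surviving pulse predictions are positive (`decide_window()`); the
comparison is inclusive, so 1 positive among 3 pulses is already a threat.
The low threshold buys sensitivity: a threat response does not have to
dominate every beat of a window. A window whose pulses were all filtered
away is reported as **indeterminate** and excluded from metrics rather
than silently defaulted — forcing a class there would bias evaluation.

`evaluate_decisions()` reports the confusion counts with accuracy,
precision, recall and F1 (class 1 = threat as positive); empty
denominators produce 0 with an explicit degenerate flag.
`mcnemar_test()` compares two classifiers over their common decided
windows: with ≥25 discordant pairs the continuity-corrected chi-square
`max(|b − c| − 1, 0)² / (b + c)` on 1 df, otherwise the exact two-sided
binomial test.

## The synthetic generator

Real recordings of this kind are privacy-restricted, so
`generate_dataset()` fabricates them. Each beat is a systolic Gaussian
bump plus a delayed, wider diastolic bump; windows add a DC offset,
sinusoidal baseline wander (0.25 Hz, 2,000 counts), white noise
(300 counts), and Poisson-placed motion bumps (30,000 counts, above the
amplitude screen). Class 0 draws subject heart rates from N(70, 5) bpm
with a fuller diastolic wave; class 1 from N(95, 8) bpm with a flatter,
narrower pulse — arousal elevates heart rate and alters pulse shape.
These are invented, desk-scale defaults: no quantitative description of
the original signals exists to calibrate against.

Three variability layers make the data realistically hard:

* **Subjects** differ in morphology and gain (`subject_var`): systolic
  width, diastolic ratio/delay jitter and a log-normal amplitude factor —
  inter-individual PPG variability is large and stable.
* **Beats** differ within a window (`beat_amp_sd`, `beat_var`):
  respiratory-scale amplitude modulation and per-beat morphology jitter.
  This gives the two classes genuinely overlapping single-pulse
  distributions, which is the regime the vote rule and the
  indiscernible-pulse removal exist for.
* **Non-responders** (`nonresponder_rho`, default 0.3): with this
  probability a subject's class-1 windows are generated from class-0
  physiology while keeping label 1 — subject-level label noise, the
  ambiguity the mixture filter targets. The manifest records the ground
  truth flag so tests can measure filter targeting directly.

Randomness is fully hierarchical: one root seed deterministically derives
per-subject and per-window sub-streams, so any window can be regenerated
in isolation and the full dataset is byte-reproducible.

What the generator does **not** emulate: real sensor transfer functions,
dicrotic-notch detail, arrhythmias, gradual motion (only spikes),
bidirectional label noise (calm windows with aroused physiology), partial
or time-varying responses within a subject, and distribution shift
between acquisition sessions. Passing benchmarks on these data therefore
demonstrates pipeline correctness and the filter's targeting behavior —
not field performance on real wrists.

### A note on what label cleaning can and cannot buy here

On this generator's benchmark (8 subjects, 25 windows per class per
subject, `nonresponder_rho = 0.3`), the mixture filter demonstrably
targets the right pulses: the class-1 anomalous group is strongly
enriched in non-responder provenance when the subject draws leave the two
physiologies separable. Yet filtered and unfiltered pipelines reach
similar window accuracy. That is not an implementation accident but a
property of this noise model: with purely subject-level label noise at
rate ρ, the mislabel mass in the calm-pulse region stays below one half,
so a classifier trained with a validation split and early stopping
already converges to the thresholded posterior and makes the same window
decisions a label-cleaned training set would — while the windows that are
truly unknowable (a non-responder's calm physiology labeled threat) are
lost to both pipelines equally. Larger gains from filtering require
ambiguity structure beyond this mechanism — bidirectional mislabeling,
partial responses, heavier noise, or train/test distribution shift —
which this generator deliberately does not model. The package reports the
benchmark's actual numbers rather than a flattering subset.

## Numerical and procedural choices

* Pulse window arithmetic: 13 before + peak + 13 after = 27 samples; the
  alternative 13/14 split totals 28 and is rejected in favor of the
  stated total length. Both margins are configurable.
* "Exceeds the threshold" is read as maximum absolute filtered value.
* EM degeneracy (all-identical pulses) is an error; covariance
  regularization is 1e-6 on the standardized scale.
* Ties in max-pooling resolve to the earliest window offset;
  deterministic.
* The amplitude screen is applied after filtering, matching the stage
  order of the pipeline description it follows.
* Test problem sizes (4-subject pipelines in unit tests, the 8-subject
  benchmark in the acceptance suite, 15-epoch classifier runs for
  property checks) are chosen so the entire suite runs in minutes on one
  CPU while still exercising every code path at realistic shapes.

## Reproducible experiments

`run_experiment()` wires everything together: one stratified
subject-by-class split, two pipeline configurations trained on the same
windows, evaluated on the same held-out windows, compared by McNemar's
test over the intersection of decided windows. All stage seeds derive
from the pipeline seed. `scripts/acceptance.R` (repository root) re-runs
the main computations from scratch and writes their headline numbers to
JSON.
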