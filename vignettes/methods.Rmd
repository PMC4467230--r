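---
title: "Time-resolved decoding of conscious and unconscious location codes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved decoding of conscious and unconscious location codes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tgmvpa)
```

## The scientific question

In masked spatial-localization experiments, observers localize a briefly
flashed target at one of eight circularly arranged positions and report
whether they saw it. With mask contrast calibrated to a 50% detection
threshold, roughly half the trials are reported *unseen*, yet forced-choice
localization on those trials remains far above the 1/8 guessing level —
blindsight. Trials with identical stimuli and identical correct responses
that differ only in the visibility report ("seen–correct" vs
"unseen–correct") are then a minimal contrast for conscious access, and
multivariate decoding of MEG/EEG sensor patterns, sample by sample, can
track *where* and *for how long* the location information lives in each
case.

`tgmvpa` implements that analysis as a reusable pipeline: per-timepoint
calibrated decoding, cross-condition generalization (the asymmetry test),
temporal generalization matrices, the Classification Endurance (CE)
decoder half-life and its repeated-measures ANOVA, evoked-response
cluster statistics, the adaptive mask-contrast staircase, and a synthetic
epoch generator that realizes the assumed neural structure so every stage
is testable without access to recordings.

## Preprocessing

Continuous recordings are assumed low-pass filtered at 30 Hz, epoched
−500…+2000 ms around stimulus onset, and downsampled to 64 Hz;
`resample_lowpass()` reproduces this for higher-rate input with a
Hamming-window FIR (transition bandwidth 25% of the cutoff — no filter
family is canonical here, and a linear-phase FIR keeps latencies honest),
applied zero-phase via FFT convolution with the group delay compensated
and reflection padding at the epoch edges.

To mix magnetometers, gradiometers and EEG in one feature vector,
`baseline_zscore()` estimates, per channel, the standard deviation of the
baseline samples pooled across **all** trials and divides every sample of
that channel by this one scalar. Two points deserve emphasis:

* Division only, no mean subtraction: the normalization's job is to
  equate units across channel types, and the baseline division
  accomplishes that by itself; a `demean` flag exists but defaults off.
* Pooled, not per-trial, baseline SD: a per-trial z-score would let
  trial-specific baseline noise leak into every post-stimulus sample of
  that trial. Pooling across trials makes the divisor a per-channel
  constant, so the operation is a fixed rescaling (and hence idempotent,
  which the tests exploit).

Trial selection and class balancing (`select_subset()`) subsample without
replacement, seeded, down to the minimum cell count of the requested
factor cells (e.g. hemifield × visibility) — matching trial counts before
any decoder whose conditions are defined by the subject's own responses.

## Per-timepoint calibrated decoding

`decode_timecourse()` trains an independent linear support vector machine
(cost C = 1, libsvm via `e1071`) at every time sample, on the z-scored
channel vector at that single sample (no temporal window; a wider feature
window is deliberately not offered, keeping the decoder's temporal
resolution equal to the sampling grid). Trials are split into k = 15
non-overlapping random folds (10 for the visibility decoder, where the
original analysis used a coarser split); each fold is scored by a machine
trained on the other k − 1, so every posterior is out-of-sample.

Class *probabilities*, not hard labels, are the output of record: each
one-vs-one margin is passed through a Platt sigmoid and the pairwise
probabilities are coupled into a posterior over classes by the
Wu–Lin–Weng iterative scheme (the libsvm procedure). Two numerical
choices matter:

* **Sigmoid fitting set.** The sigmoids are fitted on the training-set
  decision values of the already-trained machine (with Platt's
  conservative targets), not by an inner cross-validated refit. The inner
  refit multiplies the cost of every fit several-fold while changing
  posteriors in roughly the third decimal; the outer cross-validation
  already guarantees that no reported posterior comes from a model that
  saw the scored trial. The package's engine is checked against
  `e1071::svm(probability = TRUE)` (the inner-CV route) as an independent
  oracle in the test suite.
* **SMO tolerance.** The optimizer's convergence tolerance defaults to
  0.01 (libsvm ships 0.001). At these trial counts the induced posterior
  differences are far below the Monte-Carlo noise of any curve the
  pipeline reports, and the looser tolerance roughly halves run time. It
  is exposed as `tolerance =` everywhere.

Argmax readouts (used only in tests and summaries) break ties toward the
lowest class index, via R's `which.max`.

A caution on error bars: the `sem` columns the curve functions report are
plain trial-wise standard errors. On cross-validated scores these
*undercover* — trials in a fold share their model, and models across
folds share most of their training data, so per-sample means carry a
model-level random component that no within-sample resampling sees (the
classic result that cross-validation admits no unbiased variance
estimator). On label-shuffled data the grand mean is calibrated at
chance essentially exactly, but nominal per-sample 95% intervals cover
chance at roughly 85–90% of samples at the default study geometry.
Replicate-level (subject-level) statistics, as in `window_stats()` and
`ce_anova()`, are the inferentially sound route; the per-curve `sem` is
descriptive.

Derived views: `correct_class_series()` (the decoding curve, split by
condition masks), `distance_profile()` (posterior mass by circular
distance 0–4 from the true location, the two symmetric neighbors pooled
at distances 1–3, so a flat posterior reads 0.125/0.25/0.25/0.25/0.125),
and `window_stats()` (per-stage means with one-sample and paired t tests;
the stage segmentation 0–115 / 115–162 / 162–271 / 271–800 ms, half-open,
is the package-wide default, with boundary samples assigned to the
earlier window).

### Blindsight chance correction

Among unseen-*correct* trials, some correct responses are lucky guesses.
Assuming guesses are uniform over the 8 responses, the observed incorrect
count implies `g = n_incorrect × 8/7` guess trials, of which `g/8`
contaminate the correct set; assuming those carry only incorrect-trial
level information, `chance_corrected_mean()` subtracts their expected
contribution:

```
corrected = (n_correct · s_correct − (g/8) · s_incorrect) / (n_correct − g/8)
```

The source analysis cites this style of correction without printing a
formula; the mixture-subtraction estimator above is this package's
explicit choice, and the test suite validates it by parameter recovery on
simulated informed/guess mixtures.

## Cross-condition generalization

`cross_condition_curves()` trains per time sample on the k − 1 training
folds of one perceptual condition and evaluates both the held-out fold
(*within*) and the full other condition (*transfer*, averaged over fold
models). Conditions must be disjoint; the degenerate self-transfer case
is permitted and collapses onto the within curve, a useful identity
check. Because seen/unseen categories are defined by responses, the
8-class location decoder would inherit class imbalance; the asymmetry
analysis therefore uses the binary left/right-hemifield decoder (chance
50%) on counts balanced over hemifield × visibility.

The theoretically loaded outcome is asymmetry: trained on unseen-correct
trials the decoder transfers *fully* to seen-correct trials, while
trained on seen-correct it *drops* on unseen-correct late in the trial —
the signature of conscious trials containing the unconscious codes plus
amplified, late, re-encoded ones.

## Temporal generalization and Classification Endurance

`temporal_generalization_matrix()` trains at every sample t and tests at
every sample t′ on the held-out fold — the same held-out fold as at the
training time, so fold structure (and hence leakage protection) is
constant across the row. The diagonal reproduces `decode_timecourse()`
exactly when the same folds are supplied, and the suite asserts this
identity bitwise.

Classification Endurance quantifies a decoder's half-life: for training
time t with diagonal excess `e(t) = values[t,t] − chance`, the forward CE
is the largest n such that every off-diagonal value `values[t, t+i]`,
1 ≤ i ≤ n, stays above `chance + e(t)/2`; backward analogously. Three
design points:

* **Excess, not raw probability.** Half of a raw 8-class probability
  (e.g. 0.5 × 0.157 ≈ 0.079) is *below* the 0.125 chance level, so a
  raw-level criterion would never be crossed and the half-life would be
  infinite. The above-chance excess is the only self-consistent reading
  of a "50% of its level at the training time" criterion.
* **Contiguity.** The run must be contiguous from lag 1; an isolated
  sub-threshold dip terminates it. Allowing gaps would make the measure
  depend on the epoch length in uninterpretable ways.
* **Undefined, not zero.** Training times whose diagonal is at or below
  chance have no meaningful half-life; they are flagged (`defined =
  FALSE`) and excluded from averages rather than scored 0.

`ce_timeframes()` averages CE within five equal half-open bins of
272–800 ms, and `ce_anova()` runs the within-subject Visibility ×
Direction × Timeframe ANOVA (base R `aov` with an
`Error(replicate/…)` stratum) plus the two planned paired contrasts
(forward and backward, seen vs unseen). CE is computed per replicate and
then aggregated; computing it on a replicate-averaged matrix is possible
by averaging `values` before calling `classification_endurance()`, but
per-replicate-then-average is the default analysis path because it feeds
the ANOVA. A fully degenerate (zero-variance) CE table is reported as "no
effect" rather than as 0/0 F ratios.

## Evoked contrasts

`global_field_power()` uses the population SD across channels (divide by
the channel count, the classical definition — two channels at ±a give
GFP exactly |a|). `gfp_peak_windows()` ranks post-150 ms GFP lobes and
wraps the top two in windows of user-set widths (defaults 36 and 300 ms,
the N2-like and P3-like windows). `cluster_permutation_test()` then runs
the standard paired sign-flip cluster test per channel type: paired t per
(channel, sample), two-tailed forming threshold at p < 0.05 by default,
clusters connected through channel adjacency plus temporal contiguity
within one sign, cluster mass = summed t, and
`p = (1 + #{null ≥ observed}) / (1 + n_perm)` against the max-mass
null. For synthetic data the adjacency is a seeded 4-nearest-neighbor
graph on random 2-D sensor positions; real layouts can be supplied as a
logical adjacency matrix. Channel types are tested separately (the
original supplementary analyses report magnetometers and EEG separately);
pooling across types is deliberately not offered.

## The staircase

The calibration procedure is a modified Levitt block staircase on mask
contrast (0–255 pixel intensity): initial intensity 230; after each block
the contrast moves by `max_step_current × (p_seen − 0.5)/0.5` (so a fully
seen or fully unseen block moves it by the full current maximum, 80 at the
start); block sizes run 4, 4, 6, 8, then 10s; stopping when the applied
step magnitude falls below 1.5 or 80 trials are done. A calibration
"seen" trial is one reported seen and localized correctly, or reported
seen, mislocalized, with the error detected. The printed procedure fixes
the boundary conditions but not the step *law* or the decay of the
maximum step; this package uses a step linear in (p_seen − 0.5) and a
geometric per-block decay of the maximum (factor 0.7), both exposed in
`staircase_config()`, chosen as the simplest rules reproducing every
printed boundary condition. Simulated steep observers recover their true
threshold within ±10 intensity units in well over 90% of runs, and an
observer sitting exactly at threshold shows zero expected drift.

## The synthetic generator

`signal_recipe()`/`generate_epochs()` realize the neural model the
analysis presumes, on top of i.i.d. Gaussian channel noise:

* **Stage 1** (0–115 ms): noise only.
* **Stage 2** (115–162 ms): a location-specific spatial code ramps to a
  sharp peak at 147 ms, then relaxes.
* **Stage 3** (162–271 ms): the same code at half the peak amplitude.
* **Stage 4** (from 271 ms): on all trials the stage-3 code lingers,
  decaying exponentially (τ = 600 ms); on seen trials a chain of 4
  distinct metastable codes, 160 ms each, is superposed at twice the
  sustained amplitude. Unseen codes are thus a strict subset of seen
  codes — which is precisely what makes train-on-unseen transfer fully
  while train-on-seen drops late. The τ = 600 ms default makes the
  lingering code's half-life a few hundred milliseconds, the order of
  magnitude the unseen forward endurance is reported at. The 4 × 160 ms
  chain is allowed to run from the stage-4 onset to 911 ms (it must fit
  inside the epoch, not inside the stage-4 analysis window, whose 529 ms
  span could not hold four full 160 ms states).

Spatial codes are *circularly tuned*: each code stage owns a pair of
random orthonormal axis maps (A1, A2), and the location at polar angle θ
gets the unit-norm pattern `cos θ·A1 + sin θ·A2 + κ·V_loc` with a
location-unique component weighted κ = 0.5. This has three consequences
that purely random per-location patterns would miss: neighboring
locations are more confusable than opposite ones (the distance-graded
confusion profile of real recordings), the two hemifields have linearly
separable class means (without which a binary hemifield decoder would be
near chance no matter the SNR), and the axis pairs can be orthogonalized
across code stages so successive metastable codes are decodably
distinct. Amplitudes are expressed in units of the noise SD
(`pattern_snr`, default 1 at the stage-2 peak).

EOG channels (optional) carry a weak, visibility-blind location signal in
a late window — enough for low, seen/unseen-indistinguishable EOG-only
decoding, as the eye-movement control requires. ROI variants
(`generate_roi_epochs()`) zero the information before a per-ROI onset
latency (pericalcarine and superior parietal 115 ms, superior frontal
194 ms, rostral medial frontal 365 ms) and apply the seen-trial chain
amplification only in the "workspace" ROIs (superior parietal, superior
frontal). Whether unseen-*incorrect* trials carry weaker stimulus-locked
signal is not constrained by the behavioral data, so the generator
exposes `unseen_incorrect_snr` (default 1) instead of assuming.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: no 1/f or autocorrelated noise (white
noise keeps the chance-calibration oracles exact), no inter-channel noise
covariance, no realistic sensor geometry or forward model, no eye/cardiac
artifacts, no trial-to-trial latency jitter, and amplitudes chosen for
desk-scale trial counts rather than fitted to recordings. Calibration
properties (chance levels, type-I rates) transfer to real data; effect
sizes and latencies do not.

## Problem sizes and runtime posture

The packaged checks run the null-calibration decoders at the full study
geometry (400 trials × 40 channels × 160 samples, 15 folds); the
structured-signal experiments (asymmetry, generalization geometry) use
12–24 channels, roughly 150–250 trials per replicate, and time windows
cropped to the informative part of the epoch — sizes at which every
qualitative signature is recovered with comfortable margins while a full
suite run stays in the minutes range on one core. All randomness flows
from explicit integer seeds; identical seeds give bitwise-identical
epochs, folds, balancing, permutations and reports.

## Known limitations

* The calibration sigmoids are fitted on training decision values (see
  above); posteriors can differ from an inner-CV calibration at the
  third decimal.
* `ce_anova()` requires a complete balanced factorial and refuses to
  impute; undefined CE values must be resolved (or replicates dropped)
  upstream.
* The cluster test assumes exchangeable paired replicates under the
  null; it is not a fixed-effects test across trials.
* The text epoch container is exact but verbose (~25 bytes per value);
  it is a fixture format, not an archival one.
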