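---
title: "Methods: ERP and pupillary-response biometrics with pupilgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERP and pupillary-response biometrics with pupilgate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A biometric authentication system can exploit the fact that the brain
responds differently to a *familiar* face than to a stranger's face. When
face photographs are flashed in rapid serial visual presentation (RSVP) and
one of them is personally familiar to the wearer, the familiar face evokes a
cascade of positive event-related potential (ERP) components — here
operationalized as three fixed post-stimulus windows, P3a (200–350 ms), P3b
(400–490 ms) and LPP (530–750 ms) — whose amplitudes are reliably larger
than for stranger faces. The same event structure is visible in the pupil:
the frame-to-frame change of pupil diameter (pupil size change, PSC),
epoched and averaged exactly like the EEG, yields an event-related pupillary
response (ErPR) whose window amplitudes correlate with the ERP ones. An
eye-tracker is much cheaper and less obtrusive than an EEG cap, so the
practical question is whether ErPR features can stand in for ERP features in
an authentication decision. `pupilgate` implements the full pipeline —
stimulus scheduling, preprocessing, feature extraction, statistics and
classifier evaluation — together with a synthetic cohort generator with
known ground truth, so every stage is testable end to end.

## Task structure

The default paradigm (`paradigm_config()`) presents 10 blocks of 5 trials.
A trial is a stream of 10 face photographs, each shown for 100 ms and
followed by a 100 ms blank, so consecutive onsets are 200 ms apart and one
trial spans 2 s. Exactly one photograph per trial is the familiar (target)
face, its position drawn uniformly; the other nine are strangers
(nontargets), each shown only once in the whole task so that repeated
exposure cannot familiarize them. Every trial — including the last of a
block — is followed by a 2 s inter-trial interval, so a block spans 20 s;
consecutive blocks are separated by 5 s. The core task therefore lasts
10 × 20 s + 9 × 5 s = 245 s and contains 500 stimuli, 50 of them targets.
Thirty-second preparation and relaxation periods pad the recording on both
sides; the initial fixation cross is modeled as part of the preparation
period rather than per-trial, because the 245 s core admits no per-trial
cross. A schedule is fully reproducible from its configuration and seed.

## Synthetic cohort generator

`simulate_subject()` is not a fixture: it is the package's testbed, with
recoverable ground truth. Its design:

* **EEG.** Each stimulus adds one Gaussian-in-time bump per component to
  every channel, peaking near the window centre (defaults 275, 445 and
  640 ms) with a per-channel topographic gain (Fz 1.0, Cz 1.05, Pz 0.9,
  Oz 0.55). The per-event peak amplitude is the condition mean (target >
  nontarget) plus a per-subject offset plus trial-to-trial jitter. The
  background is 1/f^β Gaussian noise (β = 1 by default) synthesized by
  random-phase spectral shaping; the default amplitude and noise scales are
  chosen so that a 30-subject cohort reproduces familiar-face effect sizes
  of the magnitude reported for this protocol (amplitude Cohen's *d*
  roughly 1–3 for the EEG, 3–4 for the pupil) rather than an
  unrealistically clean separation. Trial-to-trial variability matters as
  much as sensor noise: single-trial P3-family responses vary by some 40%
  of their mean amplitude with tens of milliseconds of latency jitter, and
  the default `trial_sd` and `latency_jitter_sd` are set accordingly —
  without that variability, few-trial averages would be unrealistically
  stable and the accuracy-versus-trial-count sweep would lose the
  behaviour it exists to study.
* **Pupil.** The same per-event component bumps form a dilation *drive*
  that is low-pass filtered by a first-order kernel (time constant 500 ms)
  before being added to a 4 mm baseline with slow drift, measurement noise
  and Poisson-placed blink gaps (marked invalid, never zero-filled).
  Because the analysis differences the diameter trace, the slow response is
  returned to bump-like PSC deflections — nontrivially related to, but
  correlated with, the EEG components, which is exactly the relationship the
  agreement analysis probes.
* **Shared subject factors.** The per-subject amplitude offset of each
  component is drawn once (a standard-normal factor scaled by each
  modality's `subject_sd`), making ERP and ErPR features correlated across
  subjects with realistic correlation coefficients (roughly 0.5–0.8).
* **Ground truth.** Per-event true amplitudes and latencies are stored in
  the recording, so parameter-recovery tests are first-class: with noise
  switched off, the averaged epoch must equal the template bump and the
  extracted amplitude must match ground truth to discretization error.

What the generator does **not** emulate: realistic scalp topographies and
volume conduction, ocular artifacts in the EEG, gaze-dependent pupil
foreshortening, and illumination effects on pupil size. Passing tests
therefore demonstrate that the pipeline recovers what the generator planted
under RSVP timing and plausible noise, not that any particular accuracy
will be attained on human data. The ErPR feature scale also depends on the
pupil response kernel and sampling rate, so pupil amplitudes are
scale-dependent quantities; all statistics that compare modalities z-score
them first.

## Preprocessing

The ERP path downsamples each EEG channel from the acquisition rate
(default 2048 Hz) to 200 Hz, band-pass filters at 0.1–50 Hz with a
fourth-order Butterworth design, epochs −200…+800 ms around every onset,
subtracts the mean of the −200…0 ms baseline per epoch and channel, and
averages per condition. Numerical choices worth stating:

* **Epoch span.** The three feature windows end at 750 ms, so epochs must
  extend at least that far; with the 200 ms pre-stimulus baseline, the
  epoch is 1 s long (200 samples at 200 Hz). Overlap between epochs of
  neighbouring stimuli (200 ms apart) is intrinsic to RSVP and is permitted.
* **Zero-phase filtering.** The band-pass is applied forward and backward
  so that the filter's phase response cannot shift peak latencies, which
  are features. Plain forward–backward filtering has start-up transients,
  so both the anti-aliasing low-pass and the band-pass use odd
  (anti-symmetric) edge extension — a few time constants of the lowest band
  edge — before filtering, and the resampler interpolates the filtered
  series at exactly the target sample grid (multiples of 1/200 s) so that
  event-to-sample alignment stays exact after rate conversion.
* **Alignment.** Event onsets map to the nearest sample; exact midpoints
  go to the earlier sample. Tie-breaking for equal window maxima also takes
  the earliest sample. Both conventions are arbitrary but fixed and tested.
* **Artifact handling.** Manual independent-component screening cannot be
  automated reproducibly, so the package offers absolute-amplitude epoch
  rejection (`epoch_reject_threshold`, off by default) as its documented
  automated stand-in.
* **Pupil path.** Blink gaps are bridged by linear interpolation before
  differencing (an optional cap on bridgeable gap length exists); the PSC
  series is epoched and baselined exactly like the EEG — the two modalities
  share one implementation — and the PSC sample inherits the timestamp of
  the *later* frame of each difference.

## Features and statistics

Within each window the amplitude feature is the peak-to-peak value
(max − min) of the averaged epoch, and the latency feature is the time of
the window maximum. "Highest point" is the window maximum, not a local-peak
detector, so the value is well-defined on monotone segments. The ERP
amplitude table has 12 features (4 channels × 3 windows), the ErPR table 3;
with 30 subjects and two conditions each table has 60 rows.

Condition contrasts use a paired t-test per feature with Cohen's
*d* = mean(diff)/sd(diff); the family-wise threshold is Bonferroni-divided
(α = 0.05 over the 30 amplitude-plus-latency hypotheses gives 0.0017). A
Shapiro–Wilk p-value is reported as a diagnostic alongside each contrast
but does not gate the test. ERP–ErPR agreement is quantified by Pearson
correlations per channel × window and Bland–Altman limits
(mean ± 1.96 SD) on z-scored values pooled over the three windows per
channel (n = 180 for a 30-subject cohort); z-scoring is necessary because
microvolts and millimetre-differences are not commensurable, and the
categorical reading of the plot (good / fairly good / poor) uses explicit,
configurable cutoffs on the within-limits proportion (1.0 / 0.95 by
default), since the qualitative categories have no canonical thresholds.

## Classification

Five classifiers are supported: linear SVM, QDA, naive Bayes, logistic
regression and RBF SVM, evaluated with stratified 5-fold cross-validation
under a fixed seed. Features are z-scored inside each training fold only,
so no information leaks from test folds. The headline accuracy is the mean
of the fold accuracies; FAR = FP/(FP+TN) and FRR = FN/(FN+TP) are computed
from counts pooled over folds, with the *target* (familiar-face) class as
the positive class — FAR is impostor acceptance. AUC comes from the pooled
decision scores (SVM decision values oriented by training-class means, QDA
and NB posteriors, LR probabilities). QDA estimates one covariance matrix
per class and therefore needs more training samples per class than feature
dimensions; with the default 60-row tables that holds, but smaller cohorts
should restrict the classifier set. Classifier significance uses a
permutation test, p = (1 + #{permuted ≥ observed})/(1 + N); N = 10 000 for
publication-scale runs, with smaller N (≥ 100) for desk-scale checks. The
trial sweep re-averages each subject's epochs from the first *n* trials
(preserving the 1:9 target:nontarget ratio trial structure) and re-runs
the evaluation, tracing accuracy as a function of authentication time.

## A known property of peak-to-peak features

The amplitude feature is max − min of an *averaged* epoch, and the expected
peak-to-peak value of residual noise grows with noise level and shrinks
with the number of averaged epochs. Because the oddball design averages 50
target but 450 nontarget epochs, target averages carry a systematically
higher noise floor than nontarget averages — a class-dependent bias that
exists in any analysis using this feature with unequal epoch counts, not
just in simulation. Two consequences are worth knowing. First, amplitude
contrasts between conditions are partly inflated by the floor difference
(the generator's ground truth lets you quantify this: compare extracted
amplitudes against truth at several noise levels). Second, in the trial
sweep the floor difference *grows* as trials are removed, so a classifier
can exploit it precisely when the signal itself becomes unreliable; on the
synthetic cohort this keeps pupil-feature accuracy saturated across the
sweep and can even make EEG-feature accuracy non-monotone in the trial
count. Interpretation of sweep curves should therefore always be made
relative to a null simulation (equal target and nontarget templates), which
isolates the floor effect.

## Problem sizes and open choices

The packaged analyses use the paradigm-default cohort: 30 subjects,
2048 Hz EEG and 200 Hz pupil simulation, downsampled to 200 Hz — about two
minutes of computation for the full pipeline on one CPU. Unit tests use
reduced schedules (2 blocks × 2 trials) and 200–256 Hz simulation so that
the suite completes in seconds. The generator's defaults were fixed once to
emulate the magnitudes reported for this protocol (effect sizes,
correlation range, high-90s ErPR accuracy) and are not tuned per analysis;
exact accuracies remain data-dependent. Where the underlying protocol was
ambiguous, this package chose: an inter-trial interval after *every* trial
(the only reading consistent with both the 20 s block and the 245 s total);
baseline correction applied to the PSC series itself (not the raw
diameter); and threshold-style Bonferroni control (dividing α rather than
inflating p-values).
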