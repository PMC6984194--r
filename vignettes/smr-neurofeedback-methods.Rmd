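---
title: "Methods: simulating and analyzing self-paced SMR neurofeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing self-paced SMR neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrbci)
```

## The problem this package addresses

Neurofeedback-guided motor-imagery training for upper-limb rehabilitation
couples a participant's EEG to an effector — here an anthropomorphic
robotic hand — so that every decoded imagination of a hand flexion or
extension is answered by the corresponding hand movement. The paradigm is
*self-paced*: there is no trial grid during feedback, the decoder runs
continuously and must distinguish intentional motor imagery (MI) from
non-control periods. `smrbci` implements the complete computational
pipeline of such a study — a synthetic-EEG generator that stands in for
the (undeposited) recordings, the calibration of the decoder, the online
six-state controller, and the offline electrophysiological, behavioral
and statistical evaluation — as tested, reusable R functions.

## The signal model behind the generator

Sensorimotor-rhythm (SMR) activity is modelled as two oscillatory sources,
one per MI class, projected through fixed spatial topographies over
central/centro-parietal channels (flexion laterally, over C3/CP1/CP5/FC1;
extension medially, over CZ/CPz/CP2/FC2), on top of per-channel white and
1/f background noise. Each source is a superposition of four
constant-amplitude sinusoids spaced ~5 Hz apart across 9–26 Hz with a slow
(~4 s time constant, 5% SD) multiplicative amplitude drift.

Two properties of this model are deliberate:

* **ERD is exact by construction.** Event-related desynchronization (ERD)
  is a multiplicative amplitude envelope $\sqrt{1-d}$ applied to the
  class's own source from (MI onset + latency) until 0.5 s past MI offset,
  so the injected fractional band-power drop is exactly $d$. This gives
  every downstream estimator a sharp ground truth.
* **Band power is stable on the sub-second scale.** Widely spaced
  constant-amplitude sinusoids keep single-trial band-power traces quiet
  enough that a per-trial ERD-onset analysis is meaningful. A Gaussian
  narrow-band source would make instantaneous power exponentially
  distributed and single-trial onset detection mostly noise.

Defaults are the study conditions: 24 channels of a 10–20 subset at
500 Hz; ~50 runs of 13.6 s (5 s rest, LED, 1.5 s flexion MI — beginning
0.3 s after LED onset — 5 s rest, LED, 1.5 s extension MI); ERD depth 0.30
(the 26–34% group-mean power decreases); ERD latency 0.51 s for the
control preset and 0.63 s for the stroke preset (the group-mean onset
latencies); source RMS four times the in-band background so the planted
topographies dominate the sensorimotor band. Flexion-vs-extension
discriminability is created purely by the mediolateral topography shift —
the literature offers no generative account of the difference, so this is
a stand-in, not a claim.

What the generator does *not* emulate: eye/muscle artifacts beyond
amplitude outliers, volume-conduction correlation structure, non-
stationary electrode drift, or any coupling between ERD depth and
latency. Tests passing on this generator therefore validate the
*estimators and bookkeeping*, not the field performance of the decoder on
real EEG.

## Decoder calibration

Training data are band-pass filtered 8–28 Hz (4th-order Butterworth;
causal single-pass on the online path, forward-backward offline) and cut
into 1.5 s epochs: one per MI onset, plus two rest epochs per run (placed
1.75 s into each 5 s rest period, labelled `rest_open` before flexion and
`rest_closed` before extension), giving the 2:1 rest:MI ratio. Amplitude/
variance outliers beyond 5 robust z-scores are dropped automatically —
a deterministic stand-in for visual artifact screening.

Common spatial patterns (CSP) are fit per class pair from trace-normalized,
trial-averaged covariances by whitening + eigendecomposition; all 24
filters are computed and the first four plus last four are candidates.
An automatic plausibility proxy keeps candidates whose patterns
concentrate ≥ 50% of their squared weight over sensorimotor channels
(visual filter vetting replaced by a quantitative rule; at least one
component is always retained). Features are per-epoch log-variances of
the projected signals; a pairwise L2-penalized logistic regression
(unpenalized intercept, λ = 1 on standardized features, Newton iterations
to gradient norm < 1e-8) yields calibrated class probabilities for the
three classifiers: flexion-vs-extension, flexion-vs-rest-open,
extension-vs-rest-closed.

Two numerical choices deserve comment:

* **Covariance shrinkage (default 0.2 in the cohort pipeline, 0 in
  `fit_csp()` itself).** With 24 channels and tens of trials, sample CSP
  eigenvectors overfit: noise components acquire spurious in-sample
  eigenvalue contrast comparable to a 30% ERD. Shrinking the class
  covariances toward the scaled identity tempers this; it is the standard
  remedy and is exposed everywhere as a parameter.
* **Block-wise cross-validation.** Training accuracies come from
  five-fold cross-validation whose folds are contiguous blocks of runs;
  CSP, component selection and the classifier are refit inside every
  fold, so no information leaks across folds. Chance level uses the
  binomial criterion (smallest accuracy whose upper-tail probability
  under Binomial(n, 1/2) is below 0.05, capped at a perfect score for
  tiny n); feedback accuracies use the Wilson interval.

## The six-state controller

The online controller is a deterministic state machine over
`REMAINING_OPENED`, `CURRENTLY_FLEXING`, `JUST_CLOSED`,
`REMAINING_CLOSED`, `CURRENTLY_EXTENDING`, `JUST_OPENED`, updated every
50 ms on the most recent 1.5 s window. Each state activates a subset of
the three classifiers; a movement starts when the active classifier(s)
reach their thresholds (default 0.7), takes 2 s during which no
classifier is active, and the `JUST_*` states offer a 2 s window in which
a double-threshold shortcut (including the flexion-vs-extension
classifier, whose extension probability is the complement of its flexion
output) can reverse the movement before falling back to the resting
state. Decisions happen only on the tick grid; elapsed times are counted
in whole ticks; threshold comparisons are inclusive; and a threshold
crossing beats a simultaneous timeout — all chosen so traces are exactly
reproducible. Although the ensemble is described as weighting classifier
estimates, the transition narrative specifies pure state-gating with
AND-ed thresholds, which is what is implemented.

`calibrate_thresholds()` reproduces the acquaintance-phase threshold
adjustment automatically: each threshold is set just above the 99th
percentile of that classifier's output during known rest, clamped to
[0.55, 0.92], so spontaneous rest activity rarely triggers movements.

The simulated participant (`user_model()`) reacts to a command after
0.5 s, performs 3 s MI bouts, and — because the simulation is open-loop —
repeats an attempt every 4.5 s (up to 3) within a command's slot, the way
an instructed participant keeps imagining until the hand finally moves.
A grasp is extension followed, after the 2 s movement, by flexion.

## Offline ERD analysis

For time-frequency analysis a single spatial component is extracted per
contrast and segmented −2 to 3 s around MI onsets. A continuous Morlet
transform (fixed 6 cycles; 5–50 Hz in 1 Hz steps) is computed over −0.8
to 2.3 s on a 10 ms grid, and only −0.5 to 2 s is analyzed to avoid edge
effects. Percent power change referenced to the −0.5–0 s baseline is
computed per trial as the dB difference from the *mean baseline power*
mapped back to a linear percent, `100 (10^{\Delta dB/10} - 1)`; using the
arithmetic-mean baseline (rather than the mean of dB values) makes the
baseline mean of the percent map exactly zero and keeps single-trial maps
unbiased. The headline statistic is the mean percent change over 10–25 Hz
and 0.5–1.5 s after MI onset, averaged within and then across trials.

ERD latency is estimated per trial as the first analyzed time point at
which the band trace stays at or below −30% for at least 0.1 s (the
sustained-crossing requirement rejects isolated noise dips), and per
participant as the 20th percentile of the crossing trials' onsets —
robust against late outliers; if no trial crosses, the latency is an
explicit missing value. Band traces are band-averaged and smoothed with a
0.2 s moving average before thresholding, which cancels the residual
beating between source sinusoids. `estimate_erd_parameters()` combines
the two estimators into a (depth, latency) recovery: the depth estimate
divides the raw percent statistic by the fraction of the 0.5–1.5 s window
after the *estimated* onset, since no desynchronization can exist before
it. In the package's own calibration (20 seeded datasets, 20 runs each,
depths 0.3/0.4 × latencies 0.4/0.6 s, topography-matched component) the
recovery is within ±3 percentage points and ±30 ms; the matched component
is used so estimator bias is not confounded with filter-estimation error.
With data-estimated filters, the pattern-matched spatial filter (the
estimated source topography normalized by its power) is used instead of
the CSP filter weights, which are much noisier.

CSP filter quality is scored on a 6-criteria × 2-filter rubric (maximum
12, plausible at ≥ 10): pattern and filter sensorimotor concentration
(≥ 0.5 squared-weight fraction), class discriminability of the
log-variance distributions (|Cohen's d| ≥ 0.5), single-trial
discriminability (AUC ≥ 0.65), contralateral ERD (pattern-weighted band
power change ≤ −20%), and per-class normality (Shapiro-Wilk p > 0.05).
The original criteria involve visual judgment; these quantitative proxies
are configurable and non-canonical by design.

## Feedback evaluation

For the command tasks, 5 s trials are reconstructed relative to each
command: intended-movement trials run from the command until the
commanded movement occurs (the trial containing it is the series' last);
intended-rest trials then run until the next command; partial segments
are dropped, a new command truncates the running series, and movements
before the first command count against an implicit initial rest series.
TP/FN/TN/FP outcomes follow from whether a movement fell inside the
trial, and feedback accuracy is `100 (TP + TN) / total`. A
wrong-direction movement cannot satisfy a command; since the confusion
scheme has no wrong-direction cell, such trials stay FN and the event is
logged separately. The rest-vs-move task segments its eight 30 s phases
(left-closed intervals) into the same 5 s trials, and movement counts per
phase feed the phase-effect ANOVA.

Questionnaire constructs — ownership (SoO), agency (SoA), experiential
realness (ER) and MI-action binding (MIAB), three 7-point items each
(−3..+3) plus three control items — are averaged per construct, with
induction declared at a mean ≥ 1 (inclusive); control constructs are
scored but never count as induction evidence. The cohort simulator draws
item ratings from latent construct levels around the induction region
(agency and binding reduced in the control group); these are synthetic
stand-ins, not modelled phenomenology.

## Bootstrap statistics

The mixed two-way ANOVA (2 groups × 2 within-conditions) is implemented
from classical sums of squares, all three effects with (1, N−2) degrees
of freedom. Its bootstrap null centers the within factor (subtracting the
condition grand means, so the condition effect is nulled while each
subject's condition deviations survive), resamples the N subjects with
replacement as whole cases, and randomly reassigns group labels with
group sizes preserved — nulling group and interaction effects; 3000
replicates by default. The two-sided t-test resamples from the pooled
sample; the correlation null shuffles one variable. All p-values use the
`(1 + #exceed)/(B + 1)` convention to avoid exact zeros, inputs are
canonicalized (sorted) before resampling so p is invariant to row order,
and every routine is seed-deterministic. Family-wise correction is
step-down Holm via `stats::p.adjust`.

The package's calibration check (200 simulated null datasets per test,
B = 1000, scaled down from 3000 for runtime) verifies type-I rates in
[0.02, 0.08] at α = 0.05 for all three procedures.

## The simulated cohort study

`run_study()` ties everything together: 9 + 9 simulated participants
(stroke preset: ERD onset 0.63 s; control: 0.51 s; per-subject depth
N(0.30, 0.05), latency SD 0.06 s), per-subject training, decoding,
threshold calibration, feedback tasks, ERD statistics, CSP quality,
questionnaires, and the group-level bootstrap tests with Holm correction.
Default problem sizes (24 runs per subject, 120 s command task, B = 1000)
keep a full cohort under a few minutes while leaving every estimator
enough data to be stable; all sizes are parameters.

## Known limitations

* At the study-conditions depth of 0.30, single-trial decodability of the
  synthetic data is conservative: the generator ties the decoder's
  eigenvalue contrast directly to the ERD depth, whereas real SMR data
  offer additional discriminative structure (multiple rhythms,
  lateralization dynamics). Training accuracies of the simulated cohort
  are therefore lower than those typically reported on real recordings.
* The two class topographies are spatially disjoint; a single component
  cannot exhibit both classes' ERD, so each class is analyzed on its own
  contrast component.
* The EDF writer targets plain 16-bit EDF with 1 s records at the
  recording rate; it is not a general EDF+ implementation.
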