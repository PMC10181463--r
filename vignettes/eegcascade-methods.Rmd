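---
title: "Classifying real and imagined movements from EEG with a hierarchical random-forest cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying real and imagined movements from EEG with a hierarchical random-forest cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegcascade)
```

## The problem

A subject alternately performs and imagines opening/closing each hand
and flexing each ankle, following an eight-task protocol (each task
30 s, no interval, order: imagery right hand, real right hand, imagery
left hand, real left hand, imagery right ankle, real right ankle,
imagery left ankle, real left ankle).  EEG is recorded at 512 Hz,
either with a 16-channel research montage or with a single dry frontal
electrode (FP1) of a consumer headset, together with a light-sensor
trigger channel that sees a 0.5 s white square displayed at the
beginning and end of every task.  The goal is to recover, window by
window, which of the eight activities the subject was doing.

## Pipeline

1. **Trigger synchronization.**  Pulses are maximal runs of the
   trigger at or above a threshold expressed as a fraction of its
   dynamic range (default 0.5) lasting at least 0.25 s (half the
   nominal square duration, robust to a two-fold amplitude droop).
   Because the threshold is relative, detection is invariant to affine
   rescaling of the light-sensor gain.  Back-to-back tasks share
   boundary pulses (`shared` mode, 9 pulses for 8 tasks); a `paired`
   mode supports protocols with inter-task gaps.  All sample indices
   are 0-based with half-open intervals.

2. **Band-pass filtering.**  A 3rd-order Butterworth band-pass,
   0.5--59 Hz, applied forward--backward (zero phase) to the
   *continuous* recording before segmentation, so filter transients
   fall outside the epochs.  The 0.5 Hz edge is the drift remover;
   no separate detrending stage exists.  Zero-phase application
   squares the magnitude response (the package's own
   `filter_response()` is the oracle for all gain checks) and
   introduces no group delay.  Signal ends are odd-extended by one
   second before filtering to suppress edge transients.

3. **Epoching and windowing.**  Each 30 s epoch loses its first and
   last 5 s (task transitions), leaving 20 s.  Windows of 2 s with 50%
   overlap (19 windows per task) become the classification examples.
   The window length is a package choice: the split fractions of the
   evaluation frameworks need many examples per task, and 2 s at
   512 Hz balances moment-estimation stability against example count.

4. **Features.**  Statistical moments of orders 1..10 per channel per
   window: 160 features for the 16-channel montage, 10 for FP1.
   Central moments are the default (`raw` and `standardized` kinds are
   also implemented).  Channels are z-scored once over the whole
   filtered recording (`normalize = "recording"`), not per window: a
   per-window standardization would force orders 1 and 2 to the
   constants 0 and 1, discarding the dispersion differences between
   tasks that make order 2 the single most informative feature family;
   recording-level scaling keeps the numeric range sane for tree
   splits while preserving that information.

5. **Model selection.**  Each of the seven machines runs greedy
   forward feature selection (validation-accuracy driven, default
   `max_k = 10`, `tol = 0.001`, every candidate fit under the same
   seed so reported accuracies reproduce exactly), then an exhaustive
   grid search over trees {50, 100, 200} x depth {unlimited, 8, 16} x
   features-per-split {sqrt, log2} on the selected features.  Ties go
   to the first lattice point.

6. **The cascade.**  Level A classifies body region (hand/ankle);
   Level B (B0 for hand, B1 for ankle) classifies side (left/right);
   Level C (C0 left hand, C1 right hand, C2 left ankle, C3 right
   ankle) classifies mode (real/imagery).  Machines train on
   ground-truth-filtered subsets but are routed by *predicted*
   upstream outputs at inference, standard hierarchical-classifier
   practice.  The final label is the exact composition of the three
   stage outputs, so a Level A error always costs the window.  The
   base learner is a bootstrap ensemble of classification trees
   (backed by `ranger`); per-tree votes are aggregated by the
   package's own majority vote with a deterministic lexicographic
   tie-break.

7. **Evaluation.**  The metric is the macro average of per-activity
   accuracies (row-normalized diagonal of the 8x8 confusion matrix).
   Framework 1 splits one recording 60/20/20 (train/validation/test),
   stratified by class with a fixed seed; Framework 2 trains and
   validates (80/20) on one recording and tests on the other recording
   of the same subject (40/10/50 overall for equal-sized recordings);
   Framework 3 trains and validates (82/18) on the pooled best and
   worst Framework-1 subjects and tests on all rows of the remaining
   subjects (about 18/4/78 with nine equal subjects).  Cross-subject
   results are reported per test subject plus an averaged
   (row-normalized) confusion matrix.

Splits operate on windows; in Framework 1, overlapping windows of a
task may fall on both sides of the train/test boundary, as a
within-recording split implies.  A stricter task-level grouping
(`group_by_task` semantics) is intentionally not the default: with one
recording there is exactly one task per class, so task-level splitting
cannot produce three stratified subsets at all.

## The synthetic generator

The study's recordings are not publicly deposited, so the package
ships a generator whose output exercises every stage of the pipeline.
It emulates the acquisition protocol exactly (8 x 30 s tasks, 512 Hz,
0.5 s boundary pulses, both montages, two sessions for each of nine
subjects) and injects class information into the statistics the
classifier actually consumes, a deliberate simplification of real
sensorimotor rhythms (no mu/beta event-related desynchronization, no
dipole geometry):

* **mode** (real vs imagery) multiplies the task's EEG amplitude
  (default gain 2.4 for imagery);
* **region** (hand vs ankle) multiplies amplitude as well (default
  1.55 for ankle) and raises tail weight through sparse symmetric
  shot noise (amplitudes 0.2 vs 1.2 background SD at 10 events/s);
* **side** (left vs right) sets the *sign* of the skewness through
  one-sided shot noise (amplitude 2.2 background SD, 25 events/s;
  positive for right, negative for left).

Shot components use Gaussian kernels (6 ms for the skew component,
4 ms for the tail component) whose spectra lie mostly inside the
0.5--59 Hz analysis band, so the injected statistics survive
preprocessing; the narrow tail kernel concentrates kurtosis per unit
variance.  `class_statistics_oracle()` returns the implied variance,
skewness and excess kurtosis in closed form via Campbell's theorem,
giving parameter-recovery tests an exact target.  Nuisance structure
is label-independent: 1/f Gaussian background (10 uV SD), random-walk
baseline drift (20 uV), 60 Hz line hum (2 uV) and frontal-only blink
artifacts (30 uV, 0.5 per minute — a deliberately artifact-light rate
emulating a compliant, screened subject pool; blink-heavy recordings
were excluded from the study population this generator mirrors).

Effect sizes were calibrated once so that the no-variability regime
puts Framework 1 near-perfect (macro accuracy at or above 0.95 on both
montages) and then frozen; they are exposed in `class_effects()`.

**Inter-subject and inter-session variability** are log-normal random
effects.  The dominant effect displaces each (region, mode)
condition's amplitude gain independently per subject (log-SD
`subject_sd`, default 0.8) and per session (log-SD `session_sd`,
default 0.25): each person has their own layout of the four gain
levels, which a within-subject classifier learns easily but which
transfers poorly across subjects — the displacement, rather than
shrinkage, keeps within-recording separability high for most subjects
while breaking cross-subject transfer, matching the qualitative
pattern the frameworks are designed to expose.  Shot amplitudes and
the global gain receive milder perturbations (half the log-SD) so the
sign-based side coding stays readable within a subject; side
consequently transfers across subjects better than region or mode do,
a known asymmetry of this generator.

## What passing tests do and do not show

The test-suite properties demonstrated on synthetic data are:
equivalence of the moment fast path with definitional sums; the
filter's gain contract against its own frequency response; exactness
of split fractions, stage composition and vote tie-breaks; chance-level
behaviour (inside the 99% binomial interval around 1/8) when all class
effects are zeroed; near-perfect Framework 1 without variability; and
the ordering Framework 1 >= Framework 2 >= Framework 3 with a
cross-subject penalty of at least 0.1 under default variability.
Because the class structure is injected directly into moment space,
these results validate the *pipeline*, not the physiological claim
that real motor-imagery EEG carries this much moment-space
information; absolute accuracies on real recordings depend on the
brain, not on this code.

The chance-level control uses non-overlapping windows so that the
binomial reference distribution is valid; with overlapping windows
neighbouring examples share samples and the effective test size would
be smaller than the row count.

## Numerical choices and degenerate inputs

* Ties in the majority vote go to the lexicographically smallest label
  (C locale); ties in selection go to column order, in the grid to the
  first lattice point; best/worst-subject ties resolve by subject id.
* A flat trigger (zero dynamic range) yields no pulses rather than an
  error; an epoch deviating more than 10% from the protocol duration,
  a pulse-count mismatch, a starved cascade machine (a training subset
  missing one of its two classes), an empty feature table and a
  zero-variance window under standardized moments are all hard errors
  naming the offender.
* EDF output quantizes to 16 bits over each signal's observed range
  (round-trip error well below 0.01 uV at EEG scale); the CSV dialect
  round-trips losslessly.  EDF writing requires whole seconds of data
  (one record per second).
* All randomness flows from explicit integer seeds; simulation streams
  derive from (seed, subject, recording) so any single recording can
  be regenerated bit-identically in isolation.

## Problem sizes used in the shipped studies

The multi-seed framework comparison in the tests and the acceptance
script uses the single-channel FP1 montage (nine subjects, two
sessions, five dataset seeds in the tests, one seed per invocation in
the script), the defaults above for the generator, and a reduced
hyperparameter lattice only where a full grid would not change the
qualitative comparison.  The no-variability and chance-level studies
use single recordings per seed.  These sizes are the package's choice
of a desk-scale experiment; all of them are configurable upward.

## Known limitations

* The generator codes class information in marginal moments only; any
  classifier using spectral features would see nothing.
* Recording-level z-scoring assumes stationary channel gain within a
  recording; slow electrode degradation is not modelled.
* Framework 3's best/worst training pair is determined from Framework
  1 runs on each subject's first recording.
* The cascade never abstains: every window receives one of the eight
  labels.
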