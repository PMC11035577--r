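---
title: "Hybrid decoding of error-related responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid decoding of error-related responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`errpfusion` implements an end-to-end analysis for multimodal decoding of
error processing in immersive human-computer interaction: a participant
steers a virtual glider through target rings; occasionally the target
jumps (*target* errors), or the vehicle rotates unexpectedly while the
participant is passively gliding (*passive*) or actively steering
(*active*). Errors elicit an error-related potential (ErrP) in the EEG —
a P1/ERN/Pe/N400 component sequence over frontocentral and centroparietal
cortex — alongside an autonomic orienting response: a pupil dilation
peaking roughly half a second later and a transient heart-rate
deceleration. The package decodes the three error types against correct
trials from single epochs, asynchronously (an output every 31.25 ms), and
fuses the EEG and pupil classifiers.

No public recording of this paradigm exists, so the package is organised
around a synthetic-data generator that emulates the paradigm's event
structure and the reported physiological responses. Every processing
stage is exercised and validated against that generator.

# The synthetic session

`simulate_paradigm()` schedules 70 targets per run, roughly 4 s apart;
30% of the targets (randomised) trigger an error, seven per error type
per run (21 error trials per run), leaving 49 correct targets. Target
jumps occur 1.6 s before the projected target pass; passive/active
rotations are drawn uniformly 1.1–1.8 s before it. Nine runs form one
session on a single clock (t = 0 at recording start; event times in
seconds, converted to sample indices by each consumer, which keeps the
512 Hz EEG, 120 Hz gaze/pupil and beat-timed RR streams decoupled).

**EEG** (`synth_eeg()`). The signal is a strict sum of three terms:

* *Components.* Each error event adds four Gaussian bumps whose peak
  latency and amplitude encode the reported grand-average waveform at
  FCz — P1 at 188 ms (1.33/1.03/0.748 µV for target/passive/active), ERN
  at 234/250/266 ms (−0.401/−0.274/−0.331 µV), Pe at 313/344/391 ms
  (4.16/1.30/1.08 µV), N400 at 469/484/500 ms (amplitudes unreported;
  defaults −1.5/−1.2/−1.2 µV). Kernel widths (SD 18/16/28/45 ms) were
  chosen once so that the *composite* waveform, after the full filtering
  chain, still peaks at the component latencies — with strongly
  overlapping kernels the superposition would shift the extrema. Scalp
  topographies are Gaussians in great-circle distance from a centre
  electrode (FCz for P1/ERN, Cz for Pe/N400), on idealized 10-5
  positions constructed geometrically from the label system. Correct
  trials carry no event-locked component.
* *Background.* Twenty spatially mixed 1/f sources (per-channel SD
  10 µV) plus 1 µV white sensor noise. Real EEG background is what makes
  single-trial ERN decoding hard; 10 µV against sub-microvolt ERN keeps
  single-trial EEG accuracies in a realistic range.
* *Ocular sources.* Horizontal/vertical gaze angle and a 200 ms blink
  pulse, mixed linearly with frontally weighted gains (laterally
  antisymmetric for horizontal gaze, emulating the corneo-retinal
  dipole). Linear mixing makes the regression-based removal exactly
  verifiable.

Single-trial variability multiplies each event's component amplitudes by
a log-normal factor (SD 0.3 on the log scale) and jitters latencies
(SD 10 ms); both are zero-mean so grand averages stay centred on the
defaults. Cohorts add participant-level amplitude scaling (log SD 0.15)
and latency shifts (SD 5 ms EEG, 20 ms pupil).

**Gaze and pupil** (`synth_pupil()`). Gaze follows the target layout
with sigmoidal saccades at each pass (±20° horizontal, ±6° vertical)
plus fixational noise. Pupil diameter is a 3.5 mm baseline plus
error-evoked dilation kernels peaking at 625/656/734 ms
(0.08/0.06/0.05 mm; log-amplitude SD 0.5, latency jitter SD 50 ms),
a per-eye cubic function of the horizontal gaze angle (the pupil
foreshortening error, PFE), spontaneous slow fluctuations (SD 0.12 mm,
~1 s autocorrelation — in real pupillometry arousal-related activity is
comparable to or larger than evoked dilations, and this term is what
keeps pupil-only decoding in the reported moderate-accuracy regime), and
blinks as flagged dropout intervals at 0.2 Hz.

**RR series** (`synth_rr()`). `RR(t) = 0.8 s + 0.03 sin(2π·0.25 t)`
(respiratory sinus arrhythmia) plus a post-error lengthening kernel
equivalent to a 2 bpm deceleration peaking 1.1 s after error onset
(condition scales 0.8/1.2/1.0), plus 5 ms jitter, integrated into
strictly increasing beat times with the modulation evaluated at the peak
that ends each interval.

**Eye runs** (`synth_eye_calibration()`). A ~5-minute recording with
labelled horizontal-saccade, vertical-saccade and blink segments, the
same ocular mixing in the EEG and the same PFE distortion in the pupil.
Two eye runs per session mirror the two recording blocks.

# Preprocessing

**EEG.** Zero-phase Butterworth 0.4–30 Hz (order-4 sections, applied
forward-backward) with 50/100 Hz notches; ocular artifact subtraction;
a second zero-phase band-pass at 1–10 Hz; resampling to 64 Hz; removal
of the frontopolar/anterior-frontal channels (58 remain); epoching into
1.5 s trials ([−0.5, 1] s around error onset; correct trials [1.5, 3] s
after the previous target pass); artifact rejection; bad-channel
interpolation. The stage order is fixed as listed.

Ocular correction is a multi-reference least-squares subtraction: each
channel is regressed onto horizontal gaze, vertical gaze and the blink
indicator convolved with a canonical 200 ms pulse, fitted on the
labelled artifact segments of the eye runs only; the block-1 model
corrects runs 1–4 and the block-2 model runs 5–9. On the generator's
linear mixing the weights are identified exactly, which is the design
reason for this substitute over subspace methods whose behaviour could
not be verified against ground truth here.

Trial rejection marks a trial when any sample exceeds ±35 µV, when any
channel's excess kurtosis (z-scored across trials per channel) exceeds
5, or when the trial's joint-probability statistic — the mean negative
log-likelihood of its samples under per-channel kernel-density
estimates pooled over all trials, z-scored across trials — exceeds 5.
The per-channel reading of the kurtosis rule is the conservative
interpretation of a 5 SD threshold. Channels whose pooled variance
exceeds Q3 + 1.5 IQR are replaced by spherical-spline interpolation
(Perrin-type, m = 4, truncated Legendre expansion, light ridge
regularisation); more than 25% flagged channels aborts. There is no
separate EEG baseline subtraction: the 1 Hz high-pass serves that role.
Visual-inspection steps that cannot be reproduced automatically are
replaced by these rules alone.

**Pupil.** Blink gaps are linearly interpolated per eye (before any
resampling); streams are resampled to 128 Hz and the pupil band-passed
0.1–10 Hz (zero-phase, order 4). The PFE is removed by fitting a
per-eye cubic of pupil size on horizontal gaze angle over the
horizontal-saccade calibration segments and subtracting the fitted
dependency — only the degree-≥1 part, centred at the calibration mean
angle, so the absolute pupil level survives (baselining later removes
level anyway; whether the original procedure subtracted the intercept
is unknowable from the description, and this convention is the one that
leaves gaze-independent signal exactly untouched). Vertical gaze does
not enter the fit (the dependency is reported as horizontal). Eyes are
then averaged, epoched as for the EEG, trials with variance above
Q3 + 1.5 IQR are dropped — computed separately for the error and
correct pools so that one pool's outliers cannot mask the other's —
and trials are baseline-corrected (error: mean of [−0.5, 0] s; correct:
mean of the whole trial).

**Heart rate.** Heart rate is 60/RR at each R peak, linearly
interpolated to a uniform 4 Hz grid (heart rate carries no information
above ~1 Hz; the rate is a documented default, not a reported value).
Epochs span [−0.5, 3] s, baseline-corrected on [−0.5, 0] s; the peak
deceleration is the minimum of the per-condition average within
[0.7, 1.7] s. Because heart rate is only observed at beat times
(~1.25 Hz here), narrow deceleration kernels are attenuated by up to
about 25% in the epoch averages — a sampling limitation, not a bug, and
the reason the generator's default kernel width is 0.45 s.

# Decoding

Epochs are subsampled to 32 Hz (they are band-limited to 10 Hz, far
below the 16 Hz Nyquist rate of the decoding grid, so plain subsampling
is exact). Classes are balanced by keeping all error trials and
subsampling correct trials to the rounded mean of the three error-class
counts (round-half-to-even for determinism). Cross-validation is 10
repetitions of stratified 5-fold splits (stratification is a
stabilising choice for the small per-class counts; the folds are seeded
and reproducible).

A window of 1, 4, 8 or 16 samples (31.25–500 ms) slides through each
epoch in steps of one sample. The output at time *t* uses the window
*ending* at *t* — causal labelling, so accuracy rises only after the
discriminative response has entered the window. Features are the raw
amplitudes of the layout channels in the window (layouts: FCz; FCz, Cz,
Pz; all 58 channels), z-scored with training-fold statistics, projected
onto the minimal PCA basis explaining ≥ 99% of training variance, and
classified with a four-class shrinkage LDA: pooled within-class
covariance shrunk toward the scaled identity with the analytic
Ledoit–Wolf intensity (the standard parameter-free choice for
high-dimensional ERP features; the specific estimator behind "shrinkage
LDA" is under-determined in the literature this follows). All
standardisation, projection and discriminant statistics come from the
training folds only; the label-permutation test (accuracy ≈ 25%) guards
against leakage. Ties in the discriminant argmax break to the lowest
class index.

Pupil-only decoding uses the identical machinery on the single pupil
channel, either personalised (within-participant CV) or generic
(leave-one-participant-out with per-participant balancing before
pooling).

# Fusion

*Simple fusion* appends the 32 Hz pupil epoch as one extra channel
before standardisation/PCA; the per-feature z-scoring is what puts both
modalities on the zero-mean/unit-variance footing the method requires.
Trials are matched across modalities by event identity (the two
rejection stages drop different trials; the intersection is used).

*Bayesian fusion* combines the two classifiers' hard predictions
through their confusion matrices. With `n_ij` the number of training
trials of true class *i* predicted as *j*, the belief for class *i*
given predictions `e_1, e_2` is the prior times the product over
classifiers of the prediction-column-normalised counts
`n_ij / Σ_i n_ij`; the fused output is the belief argmax. Priors are
uniform (classes are balanced by construction). Counts are
Laplace-smoothed (+1) before normalisation: training-fold confusions of
weak classifiers can contain empty columns, and smoothing keeps every
belief strictly positive. Confusions are estimated from the training
folds with the model trained on those same folds — the literal reading
of the procedure this implements — which is optimistically biased for
weak classifiers; `bayes_fuse_results()` exposes smoothing and priors
so an inner-CV estimate can be substituted upstream.

# Statistics

The chance-level threshold for *n* balanced test trials over *c* = 4
classes is the smallest *k/n* with upper-tail cumulative binomial
probability ≤ α = 0.05. The tail uses the standard exponent *n − i*;
a commonly printed *n − 1* variant does not form a probability
distribution and cannot reproduce the ~30% threshold regime that
realistic trial counts give (≈180 error trials, ~12% rejected, correct
matched to the mean error-class count → cohort-average threshold
≈ 30%). Exhaustive enumeration of all 4^n outcome sequences for n ≤ 12
is the test oracle.

Peak responses (pupil maxima in [0.5, 0.8] s, heart-rate minima in
[0.7, 1.7] s) are compared against the correct-condition extremum in
the same window with paired Wilcoxon signed-rank tests (exact null up
to n = 25, normal approximation beyond), FDR-corrected
(Benjamini–Hochberg — the default reading of an unqualified "FDR
procedure"). Decoder comparisons use sample-wise paired signed-rank
tests with FDR across evaluation times, and Friedman omnibus tests
across methods per window length with Nemenyi post-hocs (mean-rank
differences against the studentized range) gated on omnibus
significance.

# Numerical choices

* Zero-phase filtering is implemented as forward–backward IIR with
  odd-symmetric reflection padding and steady-state initial conditions,
  so constant inputs are annihilated by high-pass sections to numerical
  precision and symmetric pulses keep their centre sample. Band-passes
  are cascades of order-4 low- and high-pass Butterworth sections,
  which stay numerically stable for corners far below Nyquist (0.1 Hz
  at 512 Hz) where a single transfer-function band-pass would be
  ill-conditioned.
* All resampling is linear interpolation applied after a 10 Hz (or
  lower) low-pass, where it is accurate to rounding; it is never applied
  to broadband data.
* Epoch windows treat boundaries with a 1 ns tolerance so that window
  edges landing exactly on a sample are included regardless of
  floating-point representation.
* Degenerate inputs: rejection requires ≥ 10 trials for stable
  z-scoring; the PFE fit requires ≥ 4 distinct horizontal angles and a
  full-rank cubic design; fold construction requires ≥ k trials per
  class; an epoch extending beyond its stream is skipped and logged,
  never silently truncated.

# What the generator does and does not show

Passing tests on this generator demonstrate that the pipeline recovers
what was injected — component latencies to within one sample through
the full chains, ocular and foreshortening coefficients exactly in the
noise-free case, fusion gains when information is placed in one
modality — and that the statistics behave under their nulls. The
generator's linear ocular mixing, Gaussian components, stationary 1/f
background and blink dropouts are idealisations: real EEG contains
non-stationary muscle and movement artifacts, real ocular propagation
is not exactly linear, and real inter-subject variability is richer
than amplitude/latency scaling. Results on this generator therefore
validate the *implementation*, not the real-data effect sizes; the
real-data accuracy levels it emulates are qualitative regimes only.

# Problem sizes

The shipped analyses use cohorts of 10 synthetic participants × 9 runs
for the grand-average latency reproductions (the acceptance script),
4 × 9 for the in-suite EEG latency check, two-run sessions per seed for
the fusion-gain property, and single runs or constructed epoch sets for
unit tests; decoding tests use 1–2 CV repetitions rather than 10. These
sizes are chosen so the full suite runs comfortably on one CPU while
keeping grand-average noise well below the latency tolerances. One
consequence of finite cohorts is worth noting: the generator draws a
per-participant latency shift (SD 5 ms for ERPs, 20 ms for the pupil),
so the *cohort-mean* latency is itself random with SD
`sd/sqrt(n_participants)`; cohort-level latency checks therefore carry
a 3-sigma allowance for that term on top of the one-sample resolution
limit.
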