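---
title: "Decoding sensory conditions from cortical population state spaces"
author: "popdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sensory conditions from cortical population state spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdecode)
```

# The analysis

This package analyses the *momentary activity distribution* across a
population of simultaneously recorded cortical neurons. Rather than the
temporal response profile of each neuron, the object of study is the
population vector: the instantaneous activity of all neurons at one time
point, viewed as a point in an N-dimensional state space.

The pipeline is:

1. **Preprocessing.** Spike trains are quality-controlled (units below
   0.8 Hz, or with more than 1% of inter-spike intervals under 2 ms, are
   excluded; responsiveness requires the trial-averaged 2 ms PSTH to
   exceed baseline by 2 SDs in two consecutive poststimulus bins). Spikes
   in prestimulus windows (300 ms) and poststimulus windows (300 ms, or
   1000 ms for pattern-identity analyses) are binned at 1 ms (5--300 ms
   for down-sampling controls), groups of sequential responses are
   averaged per pattern, and the result is convolved with a 10 ms
   Gaussian kernel.
2. **State space.** PCA is fitted to the pooled per-time-point population
   vectors of the prestimulus (spontaneous) windows, centering by the
   spontaneous mean with no per-neuron rescaling. The number of
   components explaining 95% of spontaneous variance, n(0.95), is the
   dimensionality measure, and evoked activity is projected onto those
   components.
3. **Decoding.** Points in PC space are classified by k-nearest
   neighbours (k = 5, Euclidean), over 50 repeated stratified 50/50
   train/test splits, scored by macro F1 from the one-vs-rest precision
   and recall of the confusion matrix. Every decode has a shuffled-label
   twin (50 shuffles) whose mean is the empirical chance level (0.25 for
   the four-pattern task, 0.5 for binary tasks). Variants: decoding in
   sliding 10 ms windows (30 windows for 0--300 ms, 120 for
   -200--1000 ms, smoothed for display with a 3-bin rolling mean),
   neuron-subsampling curves, and a single-neuron control in which each
   neuron's own temporal profile (5 ms kernel) is decoded with PCA
   refitted on the training half only.
4. **Control classifier.** A small convolutional network (two 1x5 conv
   layers of 5 and 10 filters, the first padded by 4 and max-pooled with
   window 3 / padding 1; a dense ReLU layer of 160 units per neuron; a
   2-unit softmax) separates spontaneous from evoked windows under
   categorical cross-entropy, full-batch gradient descent, and a
   learning rate starting at 0.01, halved every 50 epochs, floored at
   1e-5. Training restarts 24 times with fresh 70/30 splits; the
   reported F1 comes from the elementwise-mean confusion matrix.
5. **Statistics.** Pooled per-repetition F1 scores from window spans are
   compared with two-sided paired t tests and Cohen's d =
   (M1 - M2)/SD_pooled, SD_pooled = sqrt((SD1^2 + SD2^2)/2).

# The synthetic generator

Recorded sessions are large and not redistributable, so the package
ships a generator (`simConfig()`, `generateSession()`) that emulates the
experimental design the analysis assumes: 36--70 neurons; four tactile
patterns (F5, F10, F20, Finf; pulse trains of 200--340 ms) repeated 200
times each at ~1.8 s intervals (so 800 tactile stimuli per session);
four visual patterns (vA--vD; 215 ms, eight 5 ms colour pulses at 25 ms
spacing); and visuo-tactile sessions pairing each tactile pattern with a
simultaneous non-patterned visual train (+V) or nothing (-V).

The generative model, and what each choice is for:

* **Spontaneous activity** is a log-linear latent-factor
  inhomogeneous-Poisson process: each neuron's log rate is its log
  baseline (uniform 4--12 Hz) plus a loading-weighted sum of
  Ornstein-Uhlenbeck latent factors (default 12 factors, 15 ms
  correlation time, total log-rate SD 1.8). The large shared
  fluctuations emulate the synchronised cortical states of anaesthetised
  recordings and give the spontaneous distribution a genuinely
  high-dimensional fine-timescale structure: at 1 ms resolution the
  smoothed Poisson variability spreads variance across all population
  directions, while 300 ms binning averages the fast latents away and
  concentrates variance in the few loading directions. This is what
  makes n(0.95) fall as the resolution coarsens; with time-constant
  rates the curve is flat, and both behaviours are tested.
* **Evoked responses** are per-neuron gamma-shaped transients (shape 2,
  scale 5 ms, per-neuron latency 3--15 ms) at pattern-specific pulse
  times, scaled by `evokedGain` (default 3) times the mean baseline.
  About 80% of neurons respond to tactile input; visual responses are
  colour-tuned. No claim of biophysical fidelity is made -- the profiles
  merely resemble real PSTH transients and differ across patterns.
* **Visual modulation of tactile responses** (`visualModulation()`)
  redistributes each neuron's evoked rate *within* the first 300 ms of
  the window using a smooth periodic weight with a neuron-specific
  phase, then rescales so the window-integrated rate is conserved
  exactly. By construction a single 300 ms bin cannot distinguish +V
  from -V trials, while fine binning can -- the down-sampling control is
  therefore a designed property of the generator, not an empirical
  accident.
* **Persistence** adds, after stimulus offset, a rate perturbation
  `amplitude * exp(-t/tau)` along a fixed random non-negative unit
  direction per pattern label (default tau = 150 ms, amplitude 10 times
  the mean baseline at t = 0). This is the minimal mechanism that makes
  pattern identity decodable after the stimulus has ended and collapse
  when the amplitude is zero.
* **Spike emission** draws Poisson counts on a 1 ms piecewise-constant
  rate grid, jitters spike times uniformly within the bin, reports them
  at 0.1 ms resolution, and enforces a 2 ms absolute refractory period
  (so generated units pass the ISI criterion that curated recordings
  pass by construction; set `refractoryMs = 0` for a pure Poisson
  process). Stimulus onsets are jittered uniformly by +/-0.2 s around
  the 1.8 s interval; the distribution of the "random intervals" is not
  otherwise constrained.

What the generator does **not** emulate: refractory-driven ISI structure
beyond the dead time, adaptation, true laminar or cell-type diversity,
stimulus-locked oscillations, slow drift, or electrode artefacts.
Passing tests on this generator show that the *pipeline* recovers the
statistical structure it is designed to detect; they are not evidence
about any particular recorded dataset.

# Design decisions in ambiguous corners

* **"10 ms Gaussian kernel"** is interpreted as SD = 10 ms (5 ms for the
  single-neuron analysis), exposed as `kernelWidth`. Convolution uses
  reflect padding so short windows have no edge dip; mass away from the
  boundaries is preserved exactly.
* **Windows are half-open**: the onset bin belongs to the poststimulus
  window, so pre and post partition time without double counting.
* **Sequential averaging** groups the 1st--50th, 51st--100th, ...
  presentations *within* each pattern label (and condition); partial
  final groups are dropped. With 200 repetitions and groups of 50 this
  yields 4 averaged responses per pattern, hence 40 data points per
  pattern per 10 ms window at 1 ms binning.
* **PSTH baseline SD** for the responsiveness test is taken across the
  prestimulus bins of the trial-averaged PSTH (the alternative -- across
  trials -- is noted but not implemented). A zero-mean, zero-SD baseline
  makes a neuron responsive iff any poststimulus bin is positive.
* **PCA input**: the decoding pipeline fits the spontaneous PCA on the
  averaged, smoothed representation; `dimensionalityVsResolution()`
  defaults to the raw (un-averaged) prestimulus time points, both
  because the dimensionality question concerns the raw spontaneous
  distribution and because coarse bins leave too few averaged points to
  fit a covariance at desk scale. Both routes are available in
  `fitSpontaneous()`.
* **Numerical rank**: eigenvalues below 1e-12 of the largest are treated
  as zero; explained-variance ratios then sum to one over the retained
  spectrum.
* **Multi-class F1** is the macro average (unweighted mean of per-class
  F1); classes with empty precision or recall denominators contribute 0.
* **kNN ties** (possible with k = 5 and more than two classes) are
  broken by summed inverse distance among the tied classes, then by
  lowest class index -- deterministic and standard. Splits are
  stratified so both halves contain every class.
* **Split unit.** Averaged responses are temporally smooth, so the 10
  one-millisecond points of one averaged group inside a 10 ms window are
  nearly identical. A point-level random split would place near-copies
  of each test point in the training set and the decoder would recover
  *group identity* (hence, trivially, its label) rather than the
  pattern. All decodes therefore split at the level of whole trials or
  averaged groups (`groups` argument of `knnDecode()`), and shuffled
  nulls reassign labels between groups, the same unit. This is the one
  place the implementation deliberately differs from a literal
  point-level reading of "data points were split 50/50": with leakage,
  the zero-persistence control could never collapse to chance.
* **Shuffled nulls** run one split per shuffle by default
  (`nRepsPerShuffle`), since the null mean -- the empirical chance level
  -- is the quantity of interest and 50 shuffles x 50 splits is
  quadratic cost for no extra information about it.
* **CNN readings.** Pooling type is unstated: max pooling, stride 1
  (window 3 with padding 1 preserves length). The second conv layer is
  unpadded, which returns the time axis to its input length. The printed
  normalized-Xavier rule (bounds +/- sqrt(6)/(m+n), denominator m + n as
  printed, not sqrt(m+n)) initialises the conv layers it is stated for;
  dense layers use the standard Glorot bound sqrt(6/(m+n)), since the
  printed rule applied to a dense fan of tens of thousands collapses the
  weights to ~1e-5 and the fixed learning-rate schedule then cannot move
  them. Inputs are z-scored per (neuron, time) feature using
  training-split statistics -- a conditioning choice for fixed-schedule
  full-batch gradient descent, switchable off. The 70/30 split is
  re-drawn each restart. Gradients are batch means; the epoch budget
  defaults to 550 (the schedule reaches its floor at epoch 500, plus one
  final period).
* **Pairing for the pre-versus-post t tests** is by (session, window
  rank, repetition index); the effect sizes d, which need no pairing,
  are the primary quantities.
* **CI** on per-window F1 is the normal approximation
  mean +/- 1.96 SD/sqrt(n); the rolling average uses 3 centered bins
  with truncated edges, so series keep their length.

# Problem sizes used by the test suite

The packaged tests exercise the full design logic at reduced scale so
the whole suite runs on one CPU in minutes: synthetic sessions of 40
neurons with 80 trials per pattern (averaging groups of 10--20, giving
4--8 groups per label), 20 splits and 20 shuffles for windowed decoding,
and a 6-neuron, 60 ms-bin session with 25 repetitions, 24 restarts and
120 epochs for the convolutional control. The chance-level calibration
script uses 50 shuffles on the same 40-neuron sessions. Full-scale
defaults (200 repetitions, groups of 50, 50 splits, 550 epochs) remain
the package defaults.

Two scale-dependent choices deserve note. First, the +V/-V
down-sampling contrast is demonstrated on the quasi-continuous tactile
pattern (Finf), whose response covers the entire analysis window; sparse
pulse trains leave most 1 ms points uninformative and need more trials
than desk scale provides. Second, at 300 ms binning the averaged
representation leaves fewer points than neurons, so the coarse-bin
control decodes single-trial window counts (the conservation argument
applies per trial regardless).

# Known limitations

* The kNN implementation is O(n_train x n_test) per split and is meant
  for the point counts this design produces (thousands), not for
  general-purpose large-scale classification.
* The CNN is a faithful, minimal implementation of the stated
  architecture in base R; it trains in minutes at desk scale but is not
  a performance-oriented deep-learning tool, and no hyperparameter
  optimisation is attempted (by design).
* Nonlinear embeddings are intentionally out of scope; the state space
  is linear by construction.

# A short worked example

```{r example, eval = FALSE}
cfg <- simConfig(nNeurons = 40, repsPerPattern = 80, seed = 1)
sess <- generateSession(cfg)

qc <- qcFilter(sess)
tens <- extractTrials(sess, pre = 300, post = 1000, binWidth = 1,
                      neuronIds = qc$keep)
pre <- smoothGaussian(averageSequential(tens$pre, 10), 10)
post <- smoothGaussian(averageSequential(tens$post, 10), 10)

model <- fitSpontaneous(pre)
nComponentsFor(model, 0.95)

pts <- projectActivity(model, post)
curve <- windowedDecoding(pts, width = 10, span = c(0, 1000),
                          nReps = 20, nShuffles = 20, seed = 1)
plotWindowedCurve(curve)
```
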