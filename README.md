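# popdecode

Population state-space decoding of cortical spike trains.

## What this is for

Simultaneously recorded cortical neuron populations carry information in
the *distribution of momentary activity* across the population — the
population vector at each time point, viewed as a point in an
N-dimensional state space — and much of that information lives in high
dimensions that single neurons or coarse time bins cannot express.
`popdecode` implements a complete, tested pipeline for this kind of
analysis, for electrophysiologists and computational neuroscientists
working with spike tables and stimulus logs:

* spike-train preprocessing: firing-rate and ISI-violation quality
  control, PSTH responsiveness filtering, binning at 1–300 ms,
  averaging of sequential responses, Gaussian-kernel smoothing;
* a spontaneous-activity principal-component state space: PCA fitted to
  the pooled prestimulus population vectors, with n(0.95) — the number
  of components explaining 95% of spontaneous variance — as the
  dimensionality measure;
* k-nearest-neighbour decoding of sensory conditions in that space
  (k = 5, Euclidean, 50 repeated stratified 50/50 splits) scored by
  macro F1 with shuffled-label nulls, including sliding 10 ms window
  curves, neuron-subsampling curves, and a single-neuron control;
* a small convolutional-network control classifier (two 1×5 conv
  layers, dense 160·N, softmax; normalized Xavier initialisation,
  learning rate 0.01 halved every 50 epochs with floor 1e-5, 24
  restarts averaged into one confusion matrix);
* effect-size statistics: two-sided paired t tests and Cohen's
  d = (M₁ − M₂)/SD_pooled over pooled per-repetition F1 samples.

Because recorded sessions are large, a synthetic spike-data generator
reproduces the experimental design the analysis assumes (four tactile
pulse-train patterns × 200 repetitions at ~1.8 s intervals, four
visual patterns, visuo-tactile ±V conditions, high-dimensional shared
spontaneous dynamics, and an optional post-stimulus persistence term),
so the entire pipeline runs and is tested without any download. See the
vignette (`vignettes/population-state-space-decoding.Rmd`) for the
model, its assumptions, and every design decision.

## The core quantities

For each confusion matrix, per-class one-vs-rest scores

    precision = TP / (TP + FP)
    recall    = TP / (TP + FN)
    F1        = 2 · precision · recall / (precision + recall)

are macro-averaged over classes; the reported decoding accuracy is the
mean over repeated splits, and significance is judged against the
shuffled-label null distribution (empirical chance: 0.25 for the
four-pattern task, 0.5 for binary tasks). Effect sizes between pooled
F1 samples use d = (M₁ − M₂)/√((SD₁² + SD₂²)/2).

## A worked example

```r
library(popdecode)

cfg  <- simConfig(nNeurons = 40, repsPerPattern = 80, seed = 1)
sess <- generateSession(cfg)
sess
#> SpikeSession: 40 neurons, 208515 spikes, 320 stimulus events, 580.0 s

qc   <- qcFilter(sess)                      # all 40 units pass here
tens <- extractTrials(sess, pre = 300, post = 300, binWidth = 1,
                      neuronIds = qc$keep)
pre  <- smoothGaussian(averageSequential(tens$pre, 10), 10)
post <- smoothGaussian(averageSequential(tens$post, 10), 10)

model <- fitSpontaneous(pre)
model
#> PCModel: 40 neurons, 40 components fitted on 9600 points; 35 components reach 95% variance

pts <- projectActivity(model, post)
knnDecode(pts, nReps = 20, seed = 1, nShuffles = 20)
#> DecodingRun: 4 classes, k = 5 , 20 splits; mean F1 = 0.707 (null 0.257 +/- 0.043)

curve <- windowedDecoding(pts, width = 10, span = c(0, 300),
                          nReps = 10, nShuffles = 10, seed = 1)
head(windowSummary(curve))
dimensionalityVsResolution(sess, widths = c(1, 10, 100, 300))
#>   width nComponents nNeurons nPoints
#> 1     1          36       40   96000
#> 2    10          36       40    9600
#> 3   100          35       40     960
#> 4   300          34       40     320
```

The four tactile patterns decode at mean F1 0.707 against an empirical
chance of 0.257 ± 0.043; single 10 ms windows range from near-chance at
onset (F1 0.30 at 0 ms) to 0.97 at 50 ms, tracking when the patterns'
pulse trains differ; and the spontaneous dimensionality n(0.95) falls
from 36 components at 1 ms resolution to 34 at 300 ms, because coarse
binning averages away the fast shared dynamics.

A full run (simulate → preprocess → state space → decode → CNN →
stats), with every artifact and a digest manifest written to disk, is
one call:

```r
runPipeline("config.yaml", "out/")          # or a config list
```

(`inst/scripts/run_pipeline.R` wraps this for shell use.)

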