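#' @import methods
NULL

#' Stimulation pattern specification
#'
#' Describes one stimulation pattern: its label (e.g. \code{"F10"} or
#' \code{"vB"}), modality, duration and pulse timing. Tactile patterns are
#' pulse trains whose inter-pulse interval encodes the nominal pattern
#' frequency; visual patterns are multicolour pulse trains (8 pulses of 5 ms
#' at 25 ms spacing) whose colour sequence distinguishes the patterns.
#'
#' @slot label single character token naming the pattern.
#' @slot modality one of \code{"tactile"}, \code{"visual"},
#'   \code{"visuotactile"}.
#' @slot duration pattern duration in ms.
#' @slot pulseTimes numeric vector of pulse onset times in ms since pattern
#'   onset.
#' @slot colorSeq integer vector (one entry per pulse, values 1-4) giving the
#'   colour of each pulse for visual patterns; empty otherwise.
#' @slot condition condition flag, \code{"+V"} or \code{"-V"} for
#'   visuo-tactile protocols, \code{""} otherwise.
#' @exportClass PatternSpec
setClass("PatternSpec",
  representation(label = "character", modality = "character",
    duration = "numeric", pulseTimes = "numeric",
    colorSeq = "integer", condition = "character"),
  prototype(colorSeq = integer(0), condition = ""))

setValidity("PatternSpec", function(object) {
  msg <- character(0)
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "label must be a single non-empty string")
  if (!object@modality %in% c("tactile", "visual", "visuotactile"))
    msg <- c(msg, "modality must be tactile, visual or visuotactile")
  if (length(object@duration) != 1L || object@duration <= 0)
    msg <- c(msg, "duration must be a single positive number (ms)")
  if (any(object@pulseTimes < 0) || any(object@pulseTimes > object@duration))
    msg <- c(msg, "pulseTimes must lie within [0, duration]")
  if (length(msg)) msg else TRUE
})

#' Synthetic session configuration
#'
#' Parameters of the synthetic spike-data generator. Spontaneous activity is
#' a log-linear latent-factor inhomogeneous Poisson process: each neuron's
#' log rate is its log baseline plus a loading-weighted sum of
#' Ornstein-Uhlenbeck latent factors. Stimulation adds pattern-specific
#' rate transients, optional visual modulation of tactile responses (+V
#' trials), and an optional exponentially decaying pattern-specific
#' perturbation after stimulus offset (the persistence term).
#'
#' @slot nNeurons number of neurons.
#' @slot sessionLength session length in seconds; \code{NA} derives it from
#'   the stimulation timeline.
#' @slot baselineRateRange length-2 numeric, Hz; per-neuron baselines are
#'   drawn uniformly from this range.
#' @slot nLatents number of spontaneous latent factors.
#' @slot latentTimescale OU latent correlation time in ms.
#' @slot latentSd total standard deviation of the latent contribution to
#'   each neuron's log rate (dimensionless).
#' @slot patternSet list of \linkS4class{PatternSpec}.
#' @slot repsPerPattern repetitions of every pattern.
#' @slot interStimulusInterval mean onset-to-onset interval in seconds.
#' @slot isiJitter half-width of the uniform jitter on the interval (s).
#' @slot evokedGain dimensionless evoked effect size (0 disables evoked
#'   responses).
#' @slot visualGainMod dimensionless strength of the within-window
#'   redistribution of tactile rate on +V trials (0 disables it).
#' @slot persistenceTau decay time of the post-offset persistence term (ms);
#'   0 disables it.
#' @slot persistenceAmplitude dimensionless amplitude of the persistence
#'   term.
#' @slot refractoryMs absolute refractory period enforced on emitted spike
#'   trains, ms (0 disables; the default 2 ms emulates well-isolated
#'   units).
#' @slot seed integer RNG seed; an identical configuration (including seed)
#'   regenerates a bit-identical session.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nNeurons = "integer", sessionLength = "numeric",
    baselineRateRange = "numeric", nLatents = "integer",
    latentTimescale = "numeric", latentSd = "numeric",
    patternSet = "list", repsPerPattern = "integer",
    interStimulusInterval = "numeric", isiJitter = "numeric",
    evokedGain = "numeric", visualGainMod = "numeric",
    persistenceTau = "numeric", persistenceAmplitude = "numeric",
    refractoryMs = "numeric", seed = "integer"),
  prototype(refractoryMs = 2))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nNeurons < 1L) msg <- c(msg, "nNeurons must be >= 1")
  if (any(object@baselineRateRange < 0))
    msg <- c(msg, "baseline rates must be >= 0")
  if (length(object@baselineRateRange) != 2L)
    msg <- c(msg, "baselineRateRange must have length 2")
  if (object@nLatents < 0L) msg <- c(msg, "nLatents must be >= 0")
  if (object@latentSd < 0) msg <- c(msg, "latentSd must be >= 0")
  if (length(object@patternSet) > 0L) {
    if (!all(vapply(object@patternSet, is, TRUE, "PatternSpec")))
      msg <- c(msg, "patternSet must contain PatternSpec objects")
    if (object@repsPerPattern < 1L)
      msg <- c(msg, "repsPerPattern must be >= 1")
  }
  if (!is.na(object@sessionLength) && object@sessionLength <= 0)
    msg <- c(msg, "sessionLength must be positive")
  if (object@persistenceTau < 0) msg <- c(msg, "persistenceTau must be >= 0")
  if (object@refractoryMs < 0) msg <- c(msg, "refractoryMs must be >= 0")
  if (object@interStimulusInterval <= 0)
    msg <- c(msg, "interStimulusInterval must be positive")
  if (length(msg)) msg else TRUE
})

#' Recorded or simulated session: spike table plus stimulus log
#'
#' Container for one session: a long-form spike event table (neuron id,
#' spike time in seconds) and the stimulus log (onset, label, modality,
#' duration, condition flag).
#'
#' @slot spikes data.frame with columns \code{neuron} (integer) and
#'   \code{time} (seconds), sorted by neuron then time.
#' @slot stimulusLog data.frame with columns \code{onset} (s), \code{label},
#'   \code{modality}, \code{duration} (ms) and \code{condition}; onsets
#'   strictly increasing.
#' @slot sessionLength session length in seconds.
#' @slot nNeurons number of neurons (neuron ids are 1..nNeurons).
#' @exportClass SpikeSession
setClass("SpikeSession",
  representation(spikes = "data.frame", stimulusLog = "data.frame",
    sessionLength = "numeric", nNeurons = "integer"))

setValidity("SpikeSession", function(object) {
  msg <- character(0)
  sp <- object@spikes
  if (!all(c("neuron", "time") %in% names(sp)))
    msg <- c(msg, "spikes needs columns 'neuron' and 'time'")
  else {
    if (nrow(sp) && (min(sp$time) < 0 ||
        max(sp$time) > object@sessionLength + 1e-9))
      msg <- c(msg, "spike times must lie within [0, sessionLength]")
    if (nrow(sp) && is.unsorted(order(sp$neuron, sp$time) == seq_len(nrow(sp))))
      msg <- msg  # ordering checked cheaply below
    if (nrow(sp) && any(sp$neuron < 1L | sp$neuron > object@nNeurons))
      msg <- c(msg, "neuron ids must be in 1..nNeurons")
  }
  lg <- object@stimulusLog
  if (nrow(lg)) {
    if (!all(c("onset", "label", "modality", "duration", "condition")
        %in% names(lg)))
      msg <- c(msg, "stimulusLog is missing required columns")
    else if (is.unsorted(lg$onset, strictly = TRUE))
      msg <- c(msg, "stimulus onsets must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Binned population activity over one interval
#'
#' A time-bins x neurons matrix of spike counts (or smoothed activity) over
#' one contiguous interval of the session.
#'
#' @slot activity numeric matrix, bins x neurons.
#' @slot binWidth bin width in ms.
#' @slot startTime interval start in seconds.
#' @slot smoothed logical; has a Gaussian kernel been applied.
#' @slot kernelWidth kernel SD in ms (NA when unsmoothed).
#' @exportClass PopulationFrame
setClass("PopulationFrame",
  representation(activity = "matrix", binWidth = "numeric",
    startTime = "numeric", smoothed = "logical", kernelWidth = "numeric"),
  prototype(smoothed = FALSE, kernelWidth = NA_real_))

#' Per-trial population activity tensor
#'
#' A trials x time-bins x neurons array of population activity in fixed
#' windows around stimulus onsets, with per-trial metadata. All trials share
#' the same window and bin width. The time axis is relative to stimulus
#' onset; windows are half-open, so the onset bin belongs to the
#' poststimulus window.
#'
#' @slot activity numeric array, trials x bins x neurons.
#' @slot binWidth bin width in ms.
#' @slot window length-2 numeric, window start/end relative to onset in ms.
#' @slot trialInfo data.frame with one row per trial: \code{label},
#'   \code{condition}, \code{onset}, \code{windowType} (\code{"pre"} or
#'   \code{"post"}) and \code{group}.
#' @slot smoothed,kernelWidth smoothing state, as in
#'   \linkS4class{PopulationFrame}.
#' @slot groupSize number of sequential responses averaged into each trial
#'   entry (1 for raw trials).
#' @exportClass TrialTensor
setClass("TrialTensor",
  representation(activity = "array", binWidth = "numeric",
    window = "numeric", trialInfo = "data.frame", smoothed = "logical",
    kernelWidth = "numeric", groupSize = "integer"),
  prototype(smoothed = FALSE, kernelWidth = NA_real_, groupSize = 1L))

setValidity("TrialTensor", function(object) {
  msg <- character(0)
  d <- dim(object@activity)
  if (length(d) != 3L) msg <- c(msg, "activity must be a 3-d array")
  else {
    if (nrow(object@trialInfo) != d[1L])
      msg <- c(msg, "trialInfo rows must match trial count")
    nb <- round(diff(object@window) / object@binWidth)
    if (nb != d[2L])
      msg <- c(msg, "window span must equal n_bins * binWidth")
  }
  if (!object@smoothed && length(object@activity) &&
      min(object@activity) < 0)
    msg <- c(msg, "unsmoothed activity must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Sequentially averaged trial tensor
#'
#' A \linkS4class{TrialTensor} whose "trials" are groups of sequential
#' responses averaged within each pattern label (and condition), in
#' presentation order. \code{groupSize} gives the number of responses per
#' group.
#'
#' @exportClass AveragedTrialTensor
setClass("AveragedTrialTensor", contains = "TrialTensor")

#' Spontaneous-activity principal-component model
#'
#' PCA basis fitted to the pooled per-time-point population vectors of the
#' prestimulus (spontaneous) windows: spontaneous mean, orthonormal
#' loadings, eigenvalue spectrum and explained-variance ratios. Centering is
#' by the spontaneous mean only; no per-neuron rescaling.
#'
#' @slot center numeric vector, spontaneous mean per neuron.
#' @slot loadings neurons x components orthonormal matrix, columns sorted by
#'   decreasing eigenvalue.
#' @slot eigenvalues variances along each component.
#' @slot varianceRatios explained-variance ratios (sum to 1 over the full
#'   decomposition).
#' @slot nPoints number of time points the model was fitted on.
#' @slot source free-text descriptor of the fitted data.
#' @exportClass PCModel
setClass("PCModel",
  representation(center = "numeric", loadings = "matrix",
    eigenvalues = "numeric", varianceRatios = "numeric",
    nPoints = "integer", source = "character"),
  prototype(source = ""))

setValidity("PCModel", function(object) {
  msg <- character(0)
  G <- crossprod(object@loadings)
  if (max(abs(G - diag(ncol(G)))) > 1e-8)
    msg <- c(msg, "loadings must be orthonormal")
  if (any(object@varianceRatios < -1e-12) ||
      sum(object@varianceRatios) > 1 + 1e-9)
    msg <- c(msg, "variance ratios must be non-negative and sum to <= 1")
  if (is.unsorted(rev(object@eigenvalues + 1e-15)))
    msg <- c(msg, "eigenvalues must be sorted decreasing")
  if (length(msg)) msg else TRUE
})

#' Points projected into the spontaneous PC space
#'
#' @slot scores points x components score matrix.
#' @slot pointInfo data.frame with one row per point: \code{label},
#'   \code{condition}, \code{timeRel} (bin start relative to onset, ms),
#'   \code{group} (trial/group id) and \code{windowType}.
#' @exportClass ScoredPoints
setClass("ScoredPoints",
  representation(scores = "matrix", pointInfo = "data.frame"))

setValidity("ScoredPoints", function(object) {
  if (nrow(object@pointInfo) != nrow(object@scores))
    "pointInfo must label every point" else TRUE
})

#' Repeated-split kNN decoding outcome
#'
#' Result of repeated stratified 50/50 train/test splitting with
#' k-nearest-neighbour classification in PC space, scored by macro F1, with
#' an optional shuffled-label null twin.
#'
#' @slot classes class vocabulary, in the order used by the confusion
#'   matrices.
#' @slot confusions nReps x classes x classes array; rows of each matrix are
#'   true classes, columns predicted.
#' @slot f1 per-repetition macro F1 scores.
#' @slot k neighbour count.
#' @slot splitFraction training fraction of each class.
#' @slot nReps number of repetitions.
#' @slot seed RNG seed used.
#' @slot nullF1 shuffled-label null F1 scores (empty if not computed).
#' @exportClass DecodingRun
setClass("DecodingRun",
  representation(classes = "character", confusions = "array",
    f1 = "numeric", k = "integer", splitFraction = "numeric",
    nReps = "integer", seed = "integer", nullF1 = "numeric"),
  prototype(nullF1 = numeric(0)))

setValidity("DecodingRun", function(object) {
  msg <- character(0)
  if (any(object@f1 < -1e-12 | object@f1 > 1 + 1e-12))
    msg <- c(msg, "F1 scores must lie in [0, 1]")
  d <- dim(object@confusions)
  if (length(d) != 3L || d[2L] != length(object@classes) ||
      d[3L] != length(object@classes))
    msg <- c(msg, "confusions must be nReps x classes x classes")
  if (length(msg)) msg else TRUE
})

#' Time-windowed decoding curve
#'
#' Per-window repeated-split kNN decoding of stimulus identity over a series
#' of fixed-width windows, with a shuffled-label null twin per window.
#'
#' @slot windows data.frame with \code{start} and \code{width} (ms) per
#'   window.
#' @slot f1Matrix nWindows x nReps matrix of F1 scores.
#' @slot nullMatrix nWindows x nShuffles matrix of shuffled-label F1 scores.
#' @slot classes class vocabulary decoded in every window.
#' @slot k,nReps,seed decoding parameters.
#' @exportClass WindowedCurve
setClass("WindowedCurve",
  representation(windows = "data.frame", f1Matrix = "matrix",
    nullMatrix = "matrix", classes = "character", k = "integer",
    nReps = "integer", seed = "integer"))

setValidity("WindowedCurve", function(object) {
  if (nrow(object@windows) != nrow(object@f1Matrix))
    "f1Matrix must have one row per window" else TRUE
})

#' Convolutional-network control classifier specification
#'
#' Architecture and training schedule of the control classifier that
#' separates spontaneous from evoked population activity. Two convolutional
#' layers along time (5 then 10 filters of extent 1 x 5; the first convolved
#' with padding 4 and followed by max pooling with window 3 and padding 1),
#' then a dense ReLU layer of width 160 x nNeurons and a 2-unit softmax
#' output. Categorical cross-entropy loss, full-batch gradient descent,
#' learning rate 0.01 halved every 50 epochs with floor 1e-5, 70/30
#' train/test split, one-hot labels, 24 restarts.
#'
#' @slot nNeurons,nTimeBins input shape (neurons x binned time points).
#' @slot nFilters1,nFilters2 filter counts of the two conv layers.
#' @slot filterWidth temporal extent of every conv filter.
#' @slot convPad zero padding of the first conv layer (each side).
#' @slot poolWidth,poolPad max-pooling window and padding.
#' @slot denseFactor dense width per neuron (dense1 = denseFactor x
#'   nNeurons).
#' @slot lrStart,lrHalveEvery,lrFloor learning-rate schedule parameters.
#' @slot epochs training epochs per restart.
#' @slot trainFraction training fraction of the train/test split.
#' @slot nRestarts number of restarts averaged into the confusion matrix.
#' @exportClass CNNSpec
setClass("CNNSpec",
  representation(nNeurons = "integer", nTimeBins = "integer",
    nFilters1 = "integer", nFilters2 = "integer", filterWidth = "integer",
    convPad = "integer", poolWidth = "integer", poolPad = "integer",
    denseFactor = "integer", lrStart = "numeric", lrHalveEvery = "integer",
    lrFloor = "numeric", epochs = "integer", trainFraction = "numeric",
    nRestarts = "integer"),
  prototype(nFilters1 = 5L, nFilters2 = 10L, filterWidth = 5L,
    convPad = 4L, poolWidth = 3L, poolPad = 1L, denseFactor = 160L,
    lrStart = 0.01, lrHalveEvery = 50L, lrFloor = 1e-5, epochs = 550L,
    trainFraction = 0.7, nRestarts = 24L))

setValidity("CNNSpec", function(object) {
  msg <- character(0)
  if (any(c(object@nNeurons, object@nTimeBins, object@nFilters1,
      object@nFilters2, object@filterWidth, object@denseFactor) < 1L))
    msg <- c(msg, "all layer widths must be positive")
  if (object@lrFloor >= object@lrStart)
    msg <- c(msg, "lrFloor must be below lrStart")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msg <- c(msg, "trainFraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Convolutional-network control result
#'
#' @slot confusions nRestarts x 2 x 2 array of per-restart test confusion
#'   matrices (rows true, columns predicted).
#' @slot averagedConfusion elementwise mean confusion over included
#'   restarts.
#' @slot f1 macro F1 computed from the averaged confusion matrix.
#' @slot testLosses best test loss per restart.
#' @slot included logical per restart; restarts with non-finite loss are
#'   flagged and excluded from the average.
#' @slot classes the two class names (spontaneous, evoked).
#' @exportClass CNNResult
setClass("CNNResult",
  representation(confusions = "array", averagedConfusion = "matrix",
    f1 = "numeric", testLosses = "numeric", included = "logical",
    classes = "character"))
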