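#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: spike tables,
#' stimulus logs, activity arrays, PC-model components and decoding scores.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spikes", function(object) standardGeneric("spikes"))

#' @rdname accessors
#' @export
setGeneric("stimulusLog", function(object) standardGeneric("stimulusLog"))

#' @rdname accessors
#' @export
setGeneric("activity", function(object) standardGeneric("activity"))

#' @rdname accessors
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))

#' @rdname accessors
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))

#' @rdname accessors
#' @export
setGeneric("pcLoadings", function(object) standardGeneric("pcLoadings"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("varianceRatios",
  function(object) standardGeneric("varianceRatios"))

#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("pointInfo", function(object) standardGeneric("pointInfo"))

#' @rdname accessors
#' @export
setGeneric("f1Scores", function(object) standardGeneric("f1Scores"))

#' @rdname accessors
#' @export
setGeneric("nullScores", function(object) standardGeneric("nullScores"))

#' @rdname accessors
#' @export
setGeneric("confusionMatrices",
  function(object) standardGeneric("confusionMatrices"))

setMethod("spikes", "SpikeSession", function(object) object@spikes)
setMethod("stimulusLog", "SpikeSession", function(object) object@stimulusLog)
setMethod("activity", "PopulationFrame", function(object) object@activity)
setMethod("activity", "TrialTensor", function(object) object@activity)
setMethod("binWidth", "PopulationFrame", function(object) object@binWidth)
setMethod("binWidth", "TrialTensor", function(object) object@binWidth)
setMethod("trialInfo", "TrialTensor", function(object) object@trialInfo)
setMethod("pcLoadings", "PCModel", function(object) object@loadings)
setMethod("eigenvalues", "PCModel", function(object) object@eigenvalues)
setMethod("varianceRatios", "PCModel", function(object) object@varianceRatios)
setMethod("scores", "ScoredPoints", function(object) object@scores)
setMethod("pointInfo", "ScoredPoints", function(object) object@pointInfo)
setMethod("f1Scores", "DecodingRun", function(object) object@f1)
setMethod("nullScores", "DecodingRun", function(object) object@nullF1)
setMethod("confusionMatrices", "DecodingRun",
  function(object) object@confusions)
setMethod("f1Scores", "WindowedCurve", function(object) object@f1Matrix)
setMethod("nullScores", "WindowedCurve", function(object) object@nullMatrix)

setMethod("show", "SpikeSession", function(object) {
  cat("SpikeSession:", object@nNeurons, "neurons,",
      nrow(object@spikes), "spikes,",
      nrow(object@stimulusLog), "stimulus events,",
      sprintf("%.1f s\n", object@sessionLength))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nNeurons, "neurons,",
      length(object@patternSet), "patterns x", object@repsPerPattern,
      "reps,", object@nLatents, "latents (tau",
      object@latentTimescale, "ms), seed", object@seed, "\n")
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@activity)
  cat(class(object), ":", d[1L], "trials x", d[2L], "bins x", d[3L],
      "neurons; window [", object@window[1L], ",", object@window[2L],
      ") ms at", object@binWidth, "ms",
      if (object@smoothed) sprintf("(smoothed, SD %g ms)",
        object@kernelWidth) else "(unsmoothed)",
      if (object@groupSize > 1L) sprintf("; groups of %d",
        object@groupSize) else "", "\n")
})

setMethod("show", "PCModel", function(object) {
  cat("PCModel:", nrow(object@loadings), "neurons,",
      ncol(object@loadings), "components fitted on", object@nPoints,
      "points;", nComponentsFor(object, 0.95),
      "components reach 95% variance\n")
})

setMethod("show", "DecodingRun", function(object) {
  cat("DecodingRun:", length(object@classes), "classes, k =", object@k,
      ",", object@nReps, "splits; mean F1 =",
      sprintf("%.3f", mean(object@f1)),
      if (length(object@nullF1)) sprintf("(null %.3f +/- %.3f)",
        mean(object@nullF1), stats::sd(object@nullF1)) else "", "\n")
})

setMethod("show", "WindowedCurve", function(object) {
  cat("WindowedCurve:", nrow(object@windows), "windows of",
      object@windows$width[1L], "ms spanning [",
      min(object@windows$start), ",",
      max(object@windows$start + object@windows$width), ") ms\n")
})

setMethod("show", "CNNResult", function(object) {
  cat("CNNResult:", sum(object@included), "of",
      length(object@included), "restarts included; averaged-confusion",
      "F1 =", sprintf("%.3f", object@f1), "\n")
})
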