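#' Fit the spontaneous-activity principal-component state space
#'
#' Pools the per-time-point population activity vectors of all prestimulus
#' windows and fits a PCA: centering by the spontaneous mean only (no
#' per-neuron rescaling, since the object of interest is the covariance
#' pattern across the population), eigendecomposition of the sample
#' covariance, components sorted by decreasing eigenvalue. Eigenvalues
#' below \code{1e-12} times the largest are treated as numerically zero.
#'
#' @param x an (averaged) \linkS4class{TrialTensor} of prestimulus windows,
#'   or a points x neurons matrix.
#' @param source free-text descriptor stored in the model.
#' @return a \linkS4class{PCModel}.
#' @export
fitSpontaneous <- function(x, source = "spontaneous") {
  pts <- if (is(x, "TrialTensor")) {
    arr <- activity(x)
    d <- dim(arr)
    matrix(arr, d[1L] * d[2L], d[3L])
  } else as.matrix(x)
  if (nrow(pts) <= ncol(pts))
    stop("fewer spontaneous points (", nrow(pts),
         ") than neurons (", ncol(pts), "); cannot fit the state space")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2L, ctr)
  C <- crossprod(X) / (nrow(X) - 1L)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  ev[ev < 1e-12 * max(ev, .Machine$double.eps)] <- 0
  ratios <- if (sum(ev) > 0) ev / sum(ev) else ev
  new("PCModel", center = ctr, loadings = eg$vectors, eigenvalues = ev,
      varianceRatios = ratios, nPoints = nrow(pts), source = source)
}

#' Number of components for a variance fraction
#'
#' Smallest number of leading components whose cumulative explained
#' variance reaches \code{fraction}. \code{fraction = 1} returns the
#' numerical rank of the fitted data; the count is monotone in the
#' fraction.
#'
#' @param model a \linkS4class{PCModel}.
#' @param fraction target explained-variance fraction in (0, 1].
#' @return integer component count.
#' @export
nComponentsFor <- function(model, fraction = 0.95) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  r <- varianceRatios(model)
  if (fraction == 1) return(sum(eigenvalues(model) > 0))
  as.integer(which(cumsum(r) >= fraction - 1e-9)[1L])
}

#' Project activity into the spontaneous PC space
#'
#' Scores are \code{(point - spontaneous mean) \%*\% loadings}, truncated
#' to the first \code{nComponents} components. Each point keeps its label,
#' condition, time relative to stimulus onset (the start of its bin, ms)
#' and trial/group id.
#'
#' @param model a \linkS4class{PCModel}.
#' @param tensor a \linkS4class{TrialTensor} over the same neuron set.
#' @param nComponents components to retain; defaults to the number
#'   explaining 95\% of spontaneous variance.
#' @return a \linkS4class{ScoredPoints}.
#' @export
projectActivity <- function(model, tensor,
                            nComponents = nComponentsFor(model, 0.95)) {
  arr <- activity(tensor)
  d <- dim(arr)
  if (d[3L] != length(model@center))
    stop("tensor neuron set (", d[3L], ") does not match the model (",
         length(model@center), ")")
  pts <- matrix(arr, d[1L] * d[2L], d[3L])
  sc <- sweep(pts, 2L, model@center) %*%
    pcLoadings(model)[, seq_len(nComponents), drop = FALSE]
  info <- trialInfo(tensor)
  binStarts <- tensor@window[1L] + (seq_len(d[2L]) - 1L) * binWidth(tensor)
  # matrix(arr, ...) stacks trial-major within each bin: row = trial +
  # (bin - 1) * nTrials
  pointInfo <- data.frame(
    label = rep(info$label, times = d[2L]),
    condition = rep(info$condition, times = d[2L]),
    timeRel = rep(binStarts, each = d[1L]),
    group = rep(info$group, times = d[2L]),
    windowType = rep(info$windowType, times = d[2L]),
    stringsAsFactors = FALSE)
  new("ScoredPoints", scores = sc, pointInfo = pointInfo)
}

#' Combine scored point sets
#'
#' Concatenates \linkS4class{ScoredPoints} objects (e.g. the projected
#' prestimulus and poststimulus windows of the same trials, to decode a
#' span crossing stimulus onset). All sets must share the component count.
#'
#' @param ... \linkS4class{ScoredPoints} objects.
#' @return a single \linkS4class{ScoredPoints}.
#' @export
combineScoredPoints <- function(...) {
  xs <- list(...)
  nc <- vapply(xs, function(x) ncol(scores(x)), 0L)
  if (length(unique(nc)) != 1L)
    stop("point sets have different component counts")
  new("ScoredPoints",
      scores = do.call(rbind, lapply(xs, scores)),
      pointInfo = do.call(rbind, lapply(xs, pointInfo)))
}

#' Dimensionality of spontaneous activity versus temporal resolution
#'
#' Runs the preprocessing chain at each requested bin width (per-trial
#' binning of the prestimulus windows, optional sequential averaging,
#' Gaussian smoothing whenever the bin width does not exceed the kernel
#' width), fits the spontaneous PCA and reports the number of components
#' needed to reach the variance fraction. On data with fast shared latent
#' dynamics the count decreases as the resolution coarsens.
#'
#' @param session a \linkS4class{SpikeSession}.
#' @param widths bin widths in ms.
#' @param pre prestimulus window length, ms.
#' @param fraction explained-variance target.
#' @param average apply sequential averaging before the fit (default
#'   \code{FALSE}: the fit uses all raw prestimulus time points).
#' @param groupSize group size when \code{average} is \code{TRUE}.
#' @param kernelWidth smoothing kernel SD, ms.
#' @param neuronIds neurons to include.
#' @return data.frame with one row per width: \code{width},
#'   \code{nComponents}, \code{nNeurons}, \code{nPoints}.
#' @export
dimensionalityVsResolution <- function(session,
                                       widths = c(1, 5, 10, 50, 100, 300),
                                       pre = 300, fraction = 0.95,
                                       average = FALSE, groupSize = 50L,
                                       kernelWidth = 10,
                                       neuronIds = NULL) {
  rows <- lapply(widths, function(w) {
    tens <- extractTrials(session, pre = pre, post = w,
                          binWidth = w, neuronIds = neuronIds)$pre
    if (average) tens <- averageSequential(tens, groupSize)
    if (binWidth(tens) <= kernelWidth)
      tens <- smoothGaussian(tens, kernelWidth)
    m <- fitSpontaneous(tens, source = sprintf("pre %g ms bins", w))
    data.frame(width = w, nComponents = nComponentsFor(m, fraction),
               nNeurons = ncol(pcLoadings(m)), nPoints = m@nPoints)
  })
  do.call(rbind, rows)
}
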