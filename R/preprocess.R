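#' Quality-control filter on neurons
#'
#' Keeps neurons whose mean firing rate over the session is at least
#' \code{minRate} and whose fraction of inter-spike intervals shorter than
#' \code{isiLimit} is at most \code{maxViolation} (refractory-period
#' violations mark a unit as non-isolated). Both thresholds follow the
#' standard curated-unit criteria (0.8 Hz; 1\% of ISIs within 2 ms).
#'
#' @param x a \linkS4class{SpikeSession} or a spike data.frame with columns
#'   \code{neuron}, \code{time}.
#' @param sessionLength session length in seconds (taken from the session
#'   object when omitted).
#' @param minRate minimum mean rate, Hz.
#' @param isiLimit ISI violation threshold, ms.
#' @param maxViolation maximum tolerated violation fraction.
#' @param neuronIds ids to evaluate; defaults to all ids present (plus
#'   1..nNeurons for a session object, so silent neurons are reported too).
#' @return list with \code{keep} (integer ids) and \code{report} (one row
#'   per neuron: rate, ISI violation fraction, kept flag and exclusion
#'   reason, \code{"rate"}, \code{"isi"}, \code{"rate+isi"} or \code{""}).
#' @export
qcFilter <- function(x, sessionLength = NULL, minRate = 0.8, isiLimit = 2,
                     maxViolation = 0.01, neuronIds = NULL) {
  sp <- if (is(x, "SpikeSession")) spikes(x) else x
  if (is(x, "SpikeSession")) {
    if (is.null(sessionLength)) sessionLength <- x@sessionLength
    if (is.null(neuronIds)) neuronIds <- seq_len(x@nNeurons)
  }
  if (is.null(sessionLength) || sessionLength <= 0)
    stop("sessionLength must be positive")
  if (nrow(sp) == 0L) stop("empty spike table")
  if (is.null(neuronIds)) neuronIds <- sort(unique(sp$neuron))
  counts <- vapply(neuronIds, function(id) sum(sp$neuron == id), 0L)
  rate <- counts / sessionLength
  isiFrac <- vapply(neuronIds, function(id) {
    tt <- sort(sp$time[sp$neuron == id])
    if (length(tt) < 2L) return(0)
    isi <- diff(tt) * 1000
    mean(isi < isiLimit)
  }, 0)
  rateOk <- rate >= minRate
  isiOk <- isiFrac <= maxViolation
  reason <- rep("", length(neuronIds))
  reason[!rateOk & isiOk] <- "rate"
  reason[rateOk & !isiOk] <- "isi"
  reason[!rateOk & !isiOk] <- "rate+isi"
  report <- data.frame(neuron = neuronIds, rate = rate,
                       isiViolation = isiFrac, kept = rateOk & isiOk,
                       reason = reason, stringsAsFactors = FALSE)
  list(keep = neuronIds[rateOk & isiOk], report = report)
}

#' Responsiveness filter from trial-averaged PSTHs
#'
#' Marks a neuron as responsive when its trial-averaged PSTH (2 ms bins)
#' exceeds the prestimulus baseline mean by \code{z} baseline SDs in at
#' least \code{consecutive} consecutive poststimulus bins. Baseline mean
#' and SD are taken across the prestimulus bins of the trial-averaged
#' PSTH. A neuron with a zero-SD, zero-mean baseline is called responsive
#' iff any poststimulus bin is positive (documented convention).
#'
#' @inheritParams qcFilter
#' @param log stimulus log data.frame (or taken from the session).
#' @param pre,post window lengths around stimulus onset, ms.
#' @param psthBin PSTH bin width, ms.
#' @param z threshold in baseline SDs.
#' @param consecutive required run length of supra-threshold bins.
#' @return list with \code{responsive} (integer ids) and \code{report}.
#' @export
responsivenessFilter <- function(x, log = NULL, pre = 300, post = 300,
                                 psthBin = 2, z = 2, consecutive = 2,
                                 neuronIds = NULL) {
  sp <- if (is(x, "SpikeSession")) spikes(x) else x
  if (is(x, "SpikeSession")) {
    if (is.null(log)) log <- stimulusLog(x)
    if (is.null(neuronIds)) neuronIds <- seq_len(x@nNeurons)
  }
  if (is.null(neuronIds)) neuronIds <- sort(unique(sp$neuron))
  if (nrow(log) < 2L) stop("need at least 2 stimulus events")
  nPre <- as.integer(pre / psthBin)
  nPost <- as.integer(post / psthBin)
  nb <- nPre + nPost
  psth <- matrix(0, nb, length(neuronIds))
  idMap <- integer(max(neuronIds)); idMap[neuronIds] <- seq_along(neuronIds)
  ot <- sp$time[order(sp$time)]
  on <- sp$neuron[order(sp$time)]
  for (e in seq_len(nrow(log))) {
    lo <- log$onset[e] - pre / 1000
    hi <- log$onset[e] + post / 1000
    i1 <- findInterval(lo, ot, left.open = TRUE) + 1L
    i2 <- findInterval(hi, ot, left.open = TRUE)
    if (i2 < i1) next
    rel <- (ot[i1:i2] - lo) * 1000
    bin <- pmin(floor(rel / psthBin) + 1L, nb)
    j <- idMap[on[i1:i2]]
    ok <- j > 0L
    if (any(ok))
      psth <- psth + as.matrix(Matrix::sparseMatrix(i = bin[ok], j = j[ok],
        x = 1, dims = dim(psth)))
  }
  psth <- psth / nrow(log)
  baseM <- colMeans(psth[seq_len(nPre), , drop = FALSE])
  baseS <- apply(psth[seq_len(nPre), , drop = FALSE], 2L, stats::sd)
  postP <- psth[nPre + seq_len(nPost), , drop = FALSE]
  responsive <- vapply(seq_along(neuronIds), function(j) {
    if (baseS[j] == 0 && baseM[j] == 0) return(any(postP[, j] > 0))
    supra <- postP[, j] > baseM[j] + z * baseS[j]
    r <- rle(supra)
    any(r$values & r$lengths >= consecutive)
  }, TRUE)
  report <- data.frame(neuron = neuronIds, baselineMean = baseM,
                       baselineSd = baseS, responsive = responsive)
  list(responsive = neuronIds[responsive], report = report)
}

#' Bin a spike table into a population activity frame
#'
#' Counts spikes per (time bin, neuron) over one interval. The sum over all
#' bins equals the number of spikes inside the covered interval; a final
#' partial bin (when the bin width does not divide the interval) is dropped
#' with a message.
#'
#' @inheritParams qcFilter
#' @param binWidth bin width in ms (the analyses use 1, 5, 10, 50, 100 or
#'   300).
#' @param interval length-2 numeric, interval start/end in seconds.
#' @return a \linkS4class{PopulationFrame}.
#' @export
binSpikes <- function(x, binWidth, interval, neuronIds = NULL) {
  sp <- if (is(x, "SpikeSession")) spikes(x) else x
  if (is(x, "SpikeSession") && is.null(neuronIds))
    neuronIds <- seq_len(x@nNeurons)
  if (is.null(neuronIds)) neuronIds <- sort(unique(sp$neuron))
  span <- (interval[2L] - interval[1L]) * 1000
  nb <- floor(span / binWidth + 1e-9)
  if (abs(nb * binWidth - span) > 1e-6)
    message("binSpikes: dropping final partial bin (",
            format(span - nb * binWidth), " ms)")
  if (nb < 1L) stop("interval shorter than one bin")
  end <- interval[1L] + nb * binWidth / 1000
  keep <- sp$time >= interval[1L] & sp$time < end &
    sp$neuron %in% neuronIds
  idMap <- integer(max(neuronIds)); idMap[neuronIds] <- seq_along(neuronIds)
  bin <- floor((sp$time[keep] - interval[1L]) * 1000 / binWidth) + 1L
  bin <- pmin(bin, nb)  # guard times landing exactly on the boundary
  m <- as.matrix(Matrix::sparseMatrix(i = bin, j = idMap[sp$neuron[keep]],
    x = 1, dims = c(nb, length(neuronIds))))
  dimnames(m) <- NULL
  new("PopulationFrame", activity = m, binWidth = binWidth,
      startTime = interval[1L])
}

# bin one relative window [lo, hi) (seconds) for pre-sorted times;
# returns bins x neurons counts
.binWindow <- function(ot, onIdx, lo, hi, binWidth, nb, nNeur) {
  i1 <- findInterval(lo, ot, left.open = TRUE) + 1L
  i2 <- findInterval(hi, ot, left.open = TRUE)
  m <- matrix(0, nb, nNeur)
  if (i2 >= i1) {
    rel <- (ot[i1:i2] - lo) * 1000
    bin <- pmin(floor(rel / binWidth) + 1L, nb)
    j <- onIdx[i1:i2]
    ok <- j > 0L & bin >= 1L
    if (any(ok))
      m <- as.matrix(Matrix::sparseMatrix(i = bin[ok], j = j[ok], x = 1,
                                          dims = c(nb, nNeur)))
  }
  m
}

#' Extract per-trial pre- and poststimulus activity tensors
#'
#' Bins every stimulus event into a prestimulus window
#' \code{[onset - pre, onset)} and a poststimulus window
#' \code{[onset, onset + post)}, both half-open so the onset bin belongs to
#' the poststimulus window and the two windows partition time without
#' double counting. Binning is aligned to each onset, so any bin width that
#' divides the window length is exact; otherwise the final partial bin is
#' dropped with a message.
#'
#' @inheritParams qcFilter
#' @param log stimulus log (taken from the session when omitted).
#' @param pre prestimulus window length, ms.
#' @param post poststimulus window length, ms (300 for most analyses, 1000
#'   for the tactile-pattern analyses).
#' @param binWidth bin width in ms.
#' @return list with \code{pre} and \code{post}
#'   \linkS4class{TrialTensor}s.
#' @export
extractTrials <- function(x, log = NULL, pre = 300, post = 300,
                          binWidth = 1, neuronIds = NULL) {
  sp <- if (is(x, "SpikeSession")) spikes(x) else x
  if (is(x, "SpikeSession")) {
    if (is.null(log)) log <- stimulusLog(x)
    if (is.null(neuronIds)) neuronIds <- seq_len(x@nNeurons)
  }
  if (is.null(neuronIds)) neuronIds <- sort(unique(sp$neuron))
  nTr <- nrow(log)
  if (nTr == 0L) stop("stimulus log is empty")
  if (any(diff(log$onset) * 1000 < pre + post))
    stop("overlapping trial windows: events closer than pre + post")
  nbPre <- floor(pre / binWidth + 1e-9)
  nbPost <- floor(post / binWidth + 1e-9)
  if (abs(nbPre * binWidth - pre) > 1e-6 ||
      abs(nbPost * binWidth - post) > 1e-6)
    message("extractTrials: bin width does not divide the window; ",
            "dropping final partial bin")
  nNeur <- length(neuronIds)
  idMap <- integer(max(c(neuronIds, sp$neuron, 1L)))
  idMap[neuronIds] <- seq_along(neuronIds)
  tOrd <- order(sp$time)
  ot <- sp$time[tOrd]
  onIdx <- idMap[sp$neuron[tOrd]]
  preArr <- array(0, c(nTr, nbPre, nNeur))
  postArr <- array(0, c(nTr, nbPost, nNeur))
  for (e in seq_len(nTr)) {
    o <- log$onset[e]
    preArr[e, , ] <- .binWindow(ot, onIdx, o - nbPre * binWidth / 1000, o,
                                binWidth, nbPre, nNeur)
    postArr[e, , ] <- .binWindow(ot, onIdx, o, o + nbPost * binWidth / 1000,
                                 binWidth, nbPost, nNeur)
  }
  info <- data.frame(label = log$label, condition = log$condition,
                     onset = log$onset, group = seq_len(nTr),
                     stringsAsFactors = FALSE)
  preInfo <- info; preInfo$windowType <- "pre"
  postInfo <- info; postInfo$windowType <- "post"
  list(
    pre = new("TrialTensor", activity = preArr, binWidth = binWidth,
      window = c(-nbPre * binWidth, 0), trialInfo = preInfo),
    post = new("TrialTensor", activity = postArr, binWidth = binWidth,
      window = c(0, nbPost * binWidth), trialInfo = postInfo))
}

#' Average sequential responses within each pattern label
#'
#' Replaces the trials of each (label, condition) cell by the elementwise
#' means of consecutive groups of \code{groupSize} responses in
#' presentation order (1st-50th, 51st-100th, ... with the default 50),
#' the standard guard against classification errors caused by infrequently
#' spiking neurons. Partial final groups are dropped with a message; a
#' label with fewer trials than \code{groupSize} is an error.
#'
#' @param tensor a \linkS4class{TrialTensor}.
#' @param groupSize responses per group.
#' @return an \linkS4class{AveragedTrialTensor}.
#' @export
averageSequential <- function(tensor, groupSize = 50L) {
  groupSize <- as.integer(groupSize)
  if (groupSize < 1L) stop("groupSize must be >= 1")
  info <- trialInfo(tensor)
  arr <- activity(tensor)
  cell <- paste(info$label, info$condition, sep = "\r")
  cells <- unique(cell)
  outSlices <- list(); outInfo <- list()
  for (cl in cells) {
    idx <- which(cell == cl)
    idx <- idx[order(info$onset[idx])]
    if (length(idx) < groupSize)
      stop("label '", info$label[idx[1L]], "' has fewer trials (",
           length(idx), ") than groupSize (", groupSize, ")")
    ng <- length(idx) %/% groupSize
    if (ng * groupSize < length(idx))
      message("averageSequential: dropping ", length(idx) - ng * groupSize,
              " trailing trials of label '", info$label[idx[1L]], "'")
    for (g in seq_len(ng)) {
      take <- idx[(g - 1L) * groupSize + seq_len(groupSize)]
      sl <- arr[take, , , drop = FALSE]
      outSlices[[length(outSlices) + 1L]] <- colMeans(sl, dims = 1L)
      outInfo[[length(outInfo) + 1L]] <- data.frame(
        label = info$label[take[1L]], condition = info$condition[take[1L]],
        onset = info$onset[take[1L]],
        group = length(outSlices),  # unique across label cells
        windowType = info$windowType[take[1L]], stringsAsFactors = FALSE)
    }
  }
  nG <- length(outSlices)
  d <- dim(arr)
  out <- array(0, c(nG, d[2L], d[3L]))
  for (g in seq_len(nG)) out[g, , ] <- outSlices[[g]]
  new("AveragedTrialTensor", activity = out, binWidth = binWidth(tensor),
      window = tensor@window, trialInfo = do.call(rbind, outInfo),
      smoothed = tensor@smoothed, kernelWidth = tensor@kernelWidth,
      groupSize = groupSize)
}

# reflect an out-of-range index into 1..n (mirror about the end bins)
.reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j >= n, period - j, j)
  j + 1L
}

# Gaussian smoothing along the rows of a bins x K matrix, reflect padding
.gaussSmooth <- function(M, sigmaBins) {
  h <- max(1L, ceiling(4 * sigmaBins))
  w <- stats::dnorm(seq(-h, h), sd = sigmaBins)
  w <- w / sum(w)
  nb <- nrow(M)
  idx <- .reflectIndex(seq(1L - h, nb + h), nb)
  Mp <- M[idx, , drop = FALSE]
  res <- stats::filter(Mp, w, sides = 2)
  matrix(res[h + seq_len(nb), ], nb, ncol(M))
}

#' Convolve trial activity with a Gaussian kernel along time
#'
#' Per-neuron, per-trial 1-D convolution with a unit-mass Gaussian kernel
#' (its SD given in ms), applied after sequential averaging. Boundary bins
#' use reflect padding, which avoids edge dips inside short analysis
#' windows; total mass away from the edges is preserved.
#'
#' @param tensor a \linkS4class{TrialTensor} (or averaged tensor).
#' @param kernelWidth kernel SD in ms; 10 ms for population analyses, 5 ms
#'   for the single-neuron analysis. Must be at least the bin width.
#' @return the smoothed tensor (same class and dimensions).
#' @export
smoothGaussian <- function(tensor, kernelWidth = 10) {
  bw <- binWidth(tensor)
  if (bw > kernelWidth)
    stop("bin width exceeds kernel width; smoothing undefined")
  arr <- activity(tensor)
  d <- dim(arr)
  sigmaBins <- kernelWidth / bw
  M <- matrix(aperm(arr, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
  Ms <- .gaussSmooth(M, sigmaBins)
  out <- aperm(array(as.numeric(Ms), c(d[2L], d[1L], d[3L])),
               c(2L, 1L, 3L))
  initialize(tensor, activity = out, smoothed = TRUE,
             kernelWidth = kernelWidth)
}
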