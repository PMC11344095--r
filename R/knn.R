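#' Precision, recall and F1 from a confusion matrix
#'
#' One-vs-rest precision = TP/(TP+FP), recall = TP/(TP+FN) and
#' F1 = 2 * precision * recall / (precision + recall) per class, plus the
#' macro F1 (unweighted mean over classes). A class with TP+FP = 0 gets
#' precision 0, and TP+FN = 0 gets recall 0 (documented convention), so F1
#' stays defined.
#'
#' @param m non-negative confusion matrix; rows are true classes, columns
#'   predictions.
#' @return list with \code{perClass} (data.frame precision/recall/F1) and
#'   \code{macroF1}.
#' @export
f1FromConfusion <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("confusion matrix must be non-negative")
  if (sum(m) == 0) stop("all-zero confusion matrix")
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  cls <- rownames(m)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(m)))
  list(perClass = data.frame(class = cls, precision = precision,
                             recall = recall, f1 = f1, row.names = NULL,
                             stringsAsFactors = FALSE),
       macroF1 = mean(f1))
}

# k-nearest-neighbour prediction, Euclidean metric.
# Ties over the majority vote are broken by summed inverse distance, then
# by lowest class index. Returns an integer class index per test point.
.knnPredict <- function(train, clIdx, test, k, nClasses) {
  tr2 <- rowSums(train^2)
  te2 <- rowSums(test^2)
  D2 <- outer(te2, tr2, `+`) - 2 * tcrossprod(test, train)
  D2[D2 < 0] <- 0
  nTe <- nrow(test)
  pred <- integer(nTe)
  for (i in seq_len(nTe)) {
    d <- D2[i, ]
    nb <- integer(k)
    for (j in seq_len(k)) {
      nb[j] <- which.min(d)
      d[nb[j]] <- Inf
    }
    votes <- tabulate(clIdx[nb], nClasses)
    top <- which(votes == max(votes))
    if (length(top) == 1L) {
      pred[i] <- top
    } else {
      dd <- sqrt(pmax(D2[i, nb], 1e-300))
      invSum <- vapply(top, function(cl)
        sum(1 / dd[clIdx[nb] == cl]), 0)
      pred[i] <- top[which.max(invSum)]  # which.max takes the lowest index
    }
  }
  pred
}

# stratified split: per class, floor(n_c * split) training indices
.stratifiedSplit <- function(clIdx, split) {
  train <- integer(0)
  for (cl in unique(clIdx)) {
    idx <- which(clIdx == cl)
    nTr <- max(1L, floor(length(idx) * split))
    train <- c(train, sample(idx, nTr))
  }
  sort(train)
}

# group-aware stratified split: whole groups go to one side, stratified by
# the (single) class of each group; returns point indices
.groupSplit <- function(clIdx, groups, split) {
  gid <- unique(groups)
  gcl <- clIdx[match(gid, groups)]
  if (any(tapply(clIdx, groups, function(x) length(unique(x))) > 1L))
    stop("every group must carry a single label")
  trG <- gid[.stratifiedSplit(gcl, split)]
  which(groups %in% trG)
}

#' Repeated-split kNN decoding in PC space
#'
#' Classifies state-space points by the majority label of their k = 5
#' nearest neighbours (Euclidean), over repeated stratified 50/50
#' train/test splits (50 by default), scored by macro F1 per repetition.
#' Results are deterministic under the seed (per-repetition seeds are
#' derived from the master seed by fixed offsets).
#'
#' @param points a \linkS4class{ScoredPoints} or a numeric matrix of
#'   points x components.
#' @param labels class label per point; defaults to the pattern labels of
#'   the scored points.
#' @param groups grouping factor marking points that stem from the same
#'   trial or averaged response group: whole groups are assigned to one
#'   side of every split (and shuffled as units), so that within-group
#'   temporal correlation cannot leak group identity across the split.
#'   Defaults to the \code{group} column of scored points; pass \code{NA}
#'   to force plain point-level splits.
#' @param k neighbour count.
#' @param split training fraction.
#' @param nReps number of repetitions.
#' @param seed master RNG seed.
#' @param nShuffles when positive, also computes the shuffled-label null
#'   (see \code{\link{shuffledNull}}) and stores it in the result.
#' @return a \linkS4class{DecodingRun}.
#' @export
knnDecode <- function(points, labels = NULL, groups = NULL, k = 5L,
                      split = 0.5, nReps = 50L, seed = 1L,
                      nShuffles = 0L) {
  X <- if (is(points, "ScoredPoints")) scores(points) else as.matrix(points)
  if (is.null(labels)) {
    if (!is(points, "ScoredPoints"))
      stop("labels must be given for matrix input")
    labels <- pointInfo(points)$label
  }
  if (is.null(groups) && is(points, "ScoredPoints"))
    groups <- pointInfo(points)$group
  if (length(groups) == 1L && is.na(groups)) groups <- NULL
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L) stop("need at least 2 classes")
  clIdx <- match(as.character(labels), classes)
  nC <- length(classes)
  minTrain <- min(table(clIdx)) * split
  if (k > floor(minTrain) * nC)
    stop("k = ", k, " exceeds the training-set size")
  conf <- array(0L, c(nReps, nC, nC))
  f1 <- numeric(nReps)
  for (r in seq_len(nReps)) {
    set.seed(seed + r)
    trIdx <- if (is.null(groups)) .stratifiedSplit(clIdx, split)
             else .groupSplit(clIdx, groups, split)
    teIdx <- setdiff(seq_along(clIdx), trIdx)
    pred <- .knnPredict(X[trIdx, , drop = FALSE], clIdx[trIdx],
                        X[teIdx, , drop = FALSE], k, nC)
    m <- matrix(0L, nC, nC)
    for (i in seq_along(teIdx))
      m[clIdx[teIdx[i]], pred[i]] <- m[clIdx[teIdx[i]], pred[i]] + 1L
    conf[r, , ] <- m
    f1[r] <- f1FromConfusion(m)$macroF1
  }
  run <- new("DecodingRun", classes = classes, confusions = conf, f1 = f1,
             k = as.integer(k), splitFraction = split,
             nReps = as.integer(nReps), seed = as.integer(seed))
  if (nShuffles > 0L)
    run@nullF1 <- shuffledNull(X, as.character(labels), groups = groups,
                               nShuffles = nShuffles, k = k, split = split,
                               seed = seed)
  run
}

#' Shuffled-label null distribution of the decoding score
#'
#' Randomly reassigns the labels over all points and reruns the decoding;
#' repeated \code{nShuffles} times (50 by default). The mean of the
#' returned scores is the empirical chance level (1/n_classes for balanced
#' designs: 0.25 for the four-pattern task, 0.5 for binary tasks).
#'
#' @inheritParams knnDecode
#' @param nShuffles number of label shufflings.
#' @param nRepsPerShuffle train/test splits per shuffle (each shuffle's
#'   score is the mean over its splits).
#' @param permutations optional list of explicit permutations (integer
#'   vectors over points, or over groups when \code{groups} is given),
#'   mainly for verification; overrides the random shuffles.
#' @return numeric vector of null F1 scores, one per shuffle.
#' @export
shuffledNull <- function(points, labels = NULL, groups = NULL,
                         nShuffles = 50L, k = 5L, split = 0.5,
                         nRepsPerShuffle = 1L, seed = 1L,
                         permutations = NULL) {
  X <- if (is(points, "ScoredPoints")) scores(points) else as.matrix(points)
  if (is.null(labels)) labels <- pointInfo(points)$label
  if (is.null(groups) && is(points, "ScoredPoints"))
    groups <- pointInfo(points)$group
  if (length(groups) == 1L && is.na(groups)) groups <- NULL
  labels <- as.character(labels)
  if (!is.null(permutations)) nShuffles <- length(permutations)
  out <- numeric(nShuffles)
  for (s in seq_len(nShuffles)) {
    set.seed(seed + 100000L + s)
    if (is.null(groups)) {
      perm <- if (is.null(permutations)) sample(length(labels))
              else permutations[[s]]
      shuffled <- labels[perm]
    } else {
      # labels are reassigned between whole groups, matching the split unit
      gid <- unique(groups)
      glab <- labels[match(gid, groups)]
      perm <- if (is.null(permutations)) sample(length(gid))
              else permutations[[s]]
      shuffled <- glab[perm][match(groups, gid)]
    }
    run <- knnDecode(X, shuffled, groups = groups, k = k, split = split,
                     nReps = nRepsPerShuffle, seed = seed + 200000L + s)
    out[s] <- mean(f1Scores(run))
  }
  out
}

#' Balance spontaneous windows against the evoked set
#'
#' kNN comparisons need equal numbers of spontaneous and evoked points, so
#' when more prestimulus windows are available than stimulation events
#' (e.g. 1600 versus 800), a uniform window-level subsample is drawn:
#' whole windows are kept or dropped, never individual time points.
#'
#' @param tensor a \linkS4class{TrialTensor} of prestimulus windows.
#' @param nTarget number of windows to retain.
#' @param seed RNG seed (the selection is reproducible).
#' @return the subsampled tensor; when \code{nTarget} equals the number of
#'   available windows the tensor is returned unchanged.
#' @export
balanceSpontaneous <- function(tensor, nTarget, seed = 1L) {
  nAvail <- dim(activity(tensor))[1L]
  if (nTarget > nAvail)
    stop("nTarget (", nTarget, ") exceeds available windows (", nAvail, ")")
  if (nTarget == nAvail) return(tensor)
  set.seed(seed)
  keep <- sort(sample(nAvail, nTarget))
  info <- trialInfo(tensor)[keep, , drop = FALSE]
  rownames(info) <- NULL
  initialize(tensor, activity = activity(tensor)[keep, , , drop = FALSE],
             trialInfo = info)
}

#' Time-windowed decoding of stimulus identity
#'
#' Splits the span into consecutive windows of fixed width (10 ms by
#' default: 30 windows for 0-300 ms, 120 for -200-1000 ms) and runs an
#' independent repeated-split kNN decode of the pattern labels in each
#' window, together with a shuffled-label null twin per window.
#'
#' @param points a \linkS4class{ScoredPoints} whose \code{pointInfo}
#'   carries \code{timeRel}.
#' @param labels label per point (defaults to pattern labels).
#' @param width window width, ms.
#' @param span length-2 numeric, decoded time span relative to onset, ms;
#'   must be an exact multiple of \code{width}.
#' @inheritParams knnDecode
#' @param nShuffles shuffled-label decodes per window.
#' @return a \linkS4class{WindowedCurve}.
#' @export
windowedDecoding <- function(points, labels = NULL, width = 10,
                             span = c(0, 300), k = 5L, nReps = 50L,
                             nShuffles = 50L, seed = 1L) {
  info <- pointInfo(points)
  if (is.null(labels)) labels <- info$label
  labels <- as.character(labels)
  nW <- (span[2L] - span[1L]) / width
  if (abs(nW - round(nW)) > 1e-9)
    stop("span must be an exact multiple of the window width")
  nW <- as.integer(round(nW))
  starts <- span[1L] + (seq_len(nW) - 1L) * width
  classes <- sort(unique(labels))
  f1M <- matrix(NA_real_, nW, nReps)
  nullM <- matrix(NA_real_, nW, max(nShuffles, 1L))
  X <- scores(points)
  grp <- info$group
  for (w in seq_len(nW)) {
    sel <- info$timeRel >= starts[w] & info$timeRel < starts[w] + width
    if (!any(sel)) stop("empty window at ", starts[w], " ms")
    run <- knnDecode(X[sel, , drop = FALSE], labels[sel],
                     groups = grp[sel], k = k, nReps = nReps,
                     seed = seed + 1000L * w)
    f1M[w, ] <- f1Scores(run)
    if (nShuffles > 0L)
      nullM[w, ] <- shuffledNull(X[sel, , drop = FALSE], labels[sel],
                                 groups = grp[sel],
                                 nShuffles = nShuffles, k = k,
                                 seed = seed + 1000L * w)
  }
  if (nShuffles == 0L) nullM <- matrix(numeric(0), nW, 0L)
  new("WindowedCurve",
      windows = data.frame(start = starts, width = width),
      f1Matrix = f1M, nullMatrix = nullM, classes = classes,
      k = as.integer(k), nReps = as.integer(nReps),
      seed = as.integer(seed))
}

#' Decoding accuracy versus number of neurons
#'
#' For each population size n, repeatedly draws n neurons at random,
#' rebuilds the spontaneous PC space on the subpopulation, projects the
#' evoked activity and decodes; reports mean F1 +/- 2 SD across draws.
#'
#' @param preTensor,postTensor (averaged, smoothed) prestimulus and
#'   poststimulus \linkS4class{TrialTensor}s over the full population.
#' @param nValues population sizes to test.
#' @param nDraws random subpopulations per size.
#' @param fraction explained-variance target for the PC count.
#' @inheritParams knnDecode
#' @return list with \code{draws} (one row per size x draw) and
#'   \code{summary} (mean, SD, mean +/- 2 SD per size).
#' @export
neuronSubsampleCurve <- function(preTensor, postTensor, nValues,
                                 nDraws = 10L, fraction = 0.95, k = 5L,
                                 nReps = 20L, seed = 1L) {
  nTotal <- dim(activity(preTensor))[3L]
  rows <- list()
  for (n in nValues) {
    if (n > nTotal) stop("n exceeds the population size")
    for (d in seq_len(nDraws)) {
      set.seed(seed + 1000L * n + d)
      sel <- if (n == nTotal) seq_len(nTotal) else sort(sample(nTotal, n))
      preS <- initialize(preTensor,
        activity = activity(preTensor)[, , sel, drop = FALSE])
      postS <- initialize(postTensor,
        activity = activity(postTensor)[, , sel, drop = FALSE])
      model <- fitSpontaneous(preS)
      nc <- nComponentsFor(model, fraction)
      pts <- projectActivity(model, postS, nc)
      run <- knnDecode(pts, k = k, nReps = nReps,
                       seed = seed + 1000L * n + d)
      rows[[length(rows) + 1L]] <- data.frame(n = n, draw = d,
        f1 = mean(f1Scores(run)), nComponents = nc)
    }
  }
  draws <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(draws, draws$n), function(g)
    data.frame(n = g$n[1L], meanF1 = mean(g$f1), sdF1 = stats::sd(g$f1))))
  agg$lo <- agg$meanF1 - 2 * agg$sdF1
  agg$hi <- agg$meanF1 + 2 * agg$sdF1
  rownames(agg) <- NULL
  list(draws = draws, summary = agg)
}

#' Single-neuron decoding of tactile versus visuo-tactile responses
#'
#' The single-neuron control: for each neuron and each tactile pattern,
#' per-trial temporal response profiles over the 300 ms poststimulus
#' window (1 ms bins convolved with a 5 ms Gaussian kernel) are classified
#' as tactile (-V) versus visuo-tactile (+V). Per repetition the trials
#' are split 50/50; PCs explaining 95\% of the variance across stimulus
#' repetitions are extracted from the training half only, and a kNN on the
#' scores yields one F1 per pattern pair. A neuron that never spikes in
#' the window gets chance F1 (0.5) and is flagged.
#'
#' @param session a \linkS4class{SpikeSession} from a visuo-tactile
#'   protocol (+V/-V conditions in the log).
#' @param post poststimulus window, ms.
#' @param kernelWidth smoothing kernel SD, ms.
#' @inheritParams knnDecode
#' @param neuronIds neurons to analyse.
#' @return data.frame with one row per neuron x pattern: mean F1 over
#'   repetitions and a \code{silent} flag.
#' @export
singleNeuronDecode <- function(session, post = 300, kernelWidth = 5,
                               k = 5L, nReps = 20L, seed = 1L,
                               neuronIds = NULL) {
  if (is.null(neuronIds)) neuronIds <- seq_len(session@nNeurons)
  tens <- extractTrials(session, pre = 300, post = post, binWidth = 1,
                        neuronIds = neuronIds)$post
  tens <- smoothGaussian(tens, kernelWidth)
  info <- trialInfo(tens)
  if (!all(c("+V", "-V") %in% info$condition))
    stop("session has no paired +V/-V trials")
  arr <- activity(tens)
  labsU <- unique(info$label)
  out <- list()
  for (ni in seq_along(neuronIds)) {
    prof <- arr[, , ni]  # trials x bins
    for (lab in labsU) {
      sel <- which(info$label == lab)
      cond <- info$condition[sel]
      P <- prof[sel, , drop = FALSE]
      silent <- sum(P) == 0
      if (silent) {
        out[[length(out) + 1L]] <- data.frame(neuron = neuronIds[ni],
          label = lab, f1 = 0.5, silent = TRUE)
        next
      }
      f1s <- numeric(nReps)
      clIdx <- match(cond, c("-V", "+V"))
      for (r in seq_len(nReps)) {
        set.seed(seed + 7919L * ni + 131L * match(lab, labsU) + r)
        trIdx <- .stratifiedSplit(clIdx, 0.5)
        teIdx <- setdiff(seq_along(clIdx), trIdx)
        ctr <- colMeans(P[trIdx, , drop = FALSE])
        Xc <- sweep(P[trIdx, , drop = FALSE], 2L, ctr)
        sv <- svd(Xc, nu = 0)
        ev <- sv$d^2
        nc <- which(cumsum(ev) / sum(ev) >= 0.95 - 1e-9)[1L]
        V <- sv$v[, seq_len(nc), drop = FALSE]
        trS <- Xc %*% V
        teS <- sweep(P[teIdx, , drop = FALSE], 2L, ctr) %*% V
        pred <- .knnPredict(trS, clIdx[trIdx], teS, k, 2L)
        m <- matrix(0L, 2L, 2L)
        for (i in seq_along(teIdx))
          m[clIdx[teIdx[i]], pred[i]] <- m[clIdx[teIdx[i]], pred[i]] + 1L
        f1s[r] <- f1FromConfusion(m)$macroF1
      }
      out[[length(out) + 1L]] <- data.frame(neuron = neuronIds[ni],
        label = lab, f1 = mean(f1s), silent = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
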