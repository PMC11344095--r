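#' Construct a CNN control specification
#'
#' @param nNeurons,nTimeBins input shape (neurons x binned time points).
#' @param epochs training epochs per restart (default 550: the learning
#'   rate reaches its floor after 500 epochs, plus one final period).
#' @param nRestarts restarts averaged into the confusion matrix.
#' @param ... further slots of \linkS4class{CNNSpec}.
#' @return a \linkS4class{CNNSpec}.
#' @export
cnnSpec <- function(nNeurons, nTimeBins, epochs = 550L, nRestarts = 24L,
                    ...) {
  new("CNNSpec", nNeurons = as.integer(nNeurons),
      nTimeBins = as.integer(nTimeBins), epochs = as.integer(epochs),
      nRestarts = as.integer(nRestarts), ...)
}

#' Normalized Xavier initialisation range
#'
#' Uniform initialisation bounds \code{c(-sqrt(6)/(m + n),
#' sqrt(6)/(m + n))} for a layer with \code{nIn} inputs and \code{nOut}
#' outputs per node -- the denominator is the plain sum m + n. The range
#' is symmetric about zero and shrinks monotonically as m + n grows.
#'
#' @param nIn,nOut input and output counts (>= 1).
#' @return length-2 numeric, lower and upper bound.
#' @export
xavierRange <- function(nIn, nOut) {
  if (nIn < 1L || nOut < 1L) stop("nIn and nOut must be >= 1")
  b <- sqrt(6) / (nIn + nOut)
  c(-b, b)
}

#' Learning-rate schedule
#'
#' \code{0.01 * 2^(-floor(epoch / 50))}, clipped from below at 1e-5: the
#' starting rate is halved every 50 epochs until it reaches the floor
#' (first binding at epoch 500).
#'
#' @param epoch epoch index, 0-based (vectorised).
#' @param lrStart,lrHalveEvery,lrFloor schedule parameters.
#' @return learning rate(s).
#' @export
lrSchedule <- function(epoch, lrStart = 0.01, lrHalveEvery = 50L,
                       lrFloor = 1e-5) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  pmax(lrStart * 2^(-floor(epoch / lrHalveEvery)), lrFloor)
}

#' Layer output shapes of the control network
#'
#' Shape arithmetic for the architecture: conv1 (extent 5, zero padding 4)
#' maps t to t + 4; max pooling (window 3, padding 1, stride 1) preserves
#' length; conv2 (extent 5, no padding) maps back to t; the flattened
#' feature vector has nNeurons x t x nFilters2 entries; dense1 has
#' 160 x nNeurons units; dense2 has 2.
#'
#' @param spec a \linkS4class{CNNSpec}.
#' @return named list of layer output sizes.
#' @export
cnnShapes <- function(spec) {
  t1 <- spec@nTimeBins + 2L * spec@convPad - spec@filterWidth + 1L
  t2 <- t1 + 2L * spec@poolPad - spec@poolWidth + 1L
  t3 <- t2 - spec@filterWidth + 1L
  list(conv1 = c(spec@nNeurons, t1, spec@nFilters1),
       pool = c(spec@nNeurons, t2, spec@nFilters1),
       conv2 = c(spec@nNeurons, t3, spec@nFilters2),
       flatten = spec@nNeurons * t3 * spec@nFilters2,
       dense1 = spec@denseFactor * spec@nNeurons,
       dense2 = 2L)
}

# ---- internal forward/backward -------------------------------------------
# Data layout: X is an (S * n) x t matrix (row = sample s, neuron i at
# r = s + (i-1) * S); convolutions run along time, independently per row.

.cnnInit <- function(spec, zero = FALSE) {
  fw <- spec@filterWidth
  runit <- function(lo, hi, n) stats::runif(n, lo, hi)
  xav <- function(nIn, nOut, n) {
    b <- xavierRange(nIn, nOut)
    runit(b[1L], b[2L], n)
  }
  glorot <- function(nIn, nOut, n) {
    b <- sqrt(6 / (nIn + nOut))
    runit(-b, b, n)
  }
  sh <- cnnShapes(spec)
  nFeat <- sh$flatten
  H <- sh$dense1
  if (zero) {
    list(w1 = matrix(0, spec@nFilters1, fw), b1 = numeric(spec@nFilters1),
         w2 = array(0, c(spec@nFilters2, spec@nFilters1, fw)),
         b2 = numeric(spec@nFilters2),
         W1 = matrix(0, nFeat, H), bd1 = numeric(H),
         W2 = matrix(0, H, 2L), bd2 = numeric(2L))
  } else {
    # conv layers use the printed normalized-Xavier rule; dense layers use
    # the standard Glorot bound (the printed rule is stated for the conv
    # layers; its literal form collapses for dense fan-ins of this size)
    list(w1 = matrix(xav(fw, spec@nFilters1, spec@nFilters1 * fw),
                     spec@nFilters1, fw),
         b1 = numeric(spec@nFilters1),
         w2 = array(xav(fw * spec@nFilters1, spec@nFilters2,
                        spec@nFilters2 * spec@nFilters1 * fw),
                    c(spec@nFilters2, spec@nFilters1, fw)),
         b2 = numeric(spec@nFilters2),
         W1 = matrix(glorot(nFeat, H, nFeat * H), nFeat, H),
         bd1 = numeric(H),
         W2 = matrix(glorot(H, 2L, H * 2L), H, 2L),
         bd2 = numeric(2L))
  }
}

# im2col: stack fw shifted views of M (rows x L) into an (rows*L) x fw
# matrix so a 1-d convolution becomes a single matrix product
.im2col <- function(M, fw, L) {
  R <- nrow(M)
  out <- matrix(0, R * L, fw)
  for (d in seq_len(fw))
    out[, d] <- M[, d:(d + L - 1L)]
  out
}

.cnnForward <- function(par, X, spec, S) {
  fw <- spec@filterWidth
  t0 <- ncol(X)
  pad <- spec@convPad
  L1 <- t0 + 2L * pad - fw + 1L
  R <- nrow(X)
  nF1 <- spec@nFilters1; nF2 <- spec@nFilters2
  Xp <- cbind(matrix(0, R, pad), X, matrix(0, R, pad))
  X1 <- .im2col(Xp, fw, L1)                        # (R*L1) x fw
  C1 <- X1 %*% t(par$w1)                           # (R*L1) x nF1
  C1 <- sweep(C1, 2L, par$b1, `+`)
  # max pool per filter, window 3, pad 1 (-Inf), stride 1
  dim(C1) <- c(R, L1, nF1)
  P1 <- array(-Inf, c(R, L1, nF1))
  amax <- array(1L, c(R, L1, nF1))
  for (o in 1:3) {
    src <- seq_len(L1) + o - 2L
    ok <- src >= 1L & src <= L1
    cand <- array(-Inf, c(R, L1, nF1))
    cand[, ok, ] <- C1[, src[ok], , drop = FALSE]
    upd <- cand > P1
    P1[upd] <- cand[upd]
    amax[upd] <- o
  }
  A1 <- pmax(P1, 0)
  L3 <- L1 - fw + 1L
  # conv2 mixes the nF1 channels: stack (R*L3) x (nF1*fw)
  A1m <- matrix(A1, R, L1 * nF1)
  A2stack <- matrix(0, R * L3, nF1 * fw)
  for (f in seq_len(nF1))
    A2stack[, (f - 1L) * fw + seq_len(fw)] <-
      .im2col(A1m[, (f - 1L) * L1 + seq_len(L1), drop = FALSE], fw, L3)
  w2m <- matrix(aperm(par$w2, c(3L, 2L, 1L)), nF1 * fw, nF2)
  C2 <- sweep(A2stack %*% w2m, 2L, par$b2, `+`)     # (R*L3) x nF2
  A2 <- pmax(C2, 0)
  # flatten (s, i, j, g) -> row s, feature (i, j, g)
  Fm <- matrix(A2, S, (R / S) * L3 * nF2)
  Z1 <- sweep(Fm %*% par$W1, 2L, par$bd1, `+`)
  A3 <- pmax(Z1, 0)
  Z2 <- sweep(A3 %*% par$W2, 2L, par$bd2, `+`)
  Z2m <- sweep(Z2, 1L, apply(Z2, 1L, max))
  E <- exp(Z2m)
  Pr <- E / rowSums(E)
  list(X1 = X1, amax = amax, A1 = A1, A2stack = A2stack, C2 = C2,
       w2m = w2m, Fm = Fm, A3 = A3, Pr = Pr, L1 = L1, L3 = L3, R = R)
}

.cnnLoss <- function(Pr, Y) {
  -mean(rowSums(Y * log(pmax(Pr, 1e-12))))
}

.cnnBackward <- function(par, fwd, Y, spec, S) {
  fw <- spec@filterWidth
  L1 <- fwd$L1; L3 <- fwd$L3; R <- fwd$R
  nF1 <- spec@nFilters1; nF2 <- spec@nFilters2
  dZ2 <- (fwd$Pr - Y) / S
  gW2 <- crossprod(fwd$A3, dZ2)
  gbd2 <- colSums(dZ2)
  dA3 <- tcrossprod(dZ2, par$W2)
  dZ1 <- dA3 * (fwd$A3 > 0)
  gW1 <- crossprod(fwd$Fm, dZ1)
  gbd1 <- colSums(dZ1)
  dF <- tcrossprod(dZ1, par$W1)                    # S x nFeat
  dC2 <- matrix(dF, R * L3, nF2) * (fwd$C2 > 0)
  gb2 <- colSums(dC2)
  gw2m <- crossprod(fwd$A2stack, dC2)              # (nF1*fw) x nF2
  gw2 <- aperm(array(gw2m, c(fw, nF1, nF2)), c(3L, 2L, 1L))
  dA2stack <- tcrossprod(dC2, fwd$w2m)             # (R*L3) x (nF1*fw)
  dA1 <- array(0, c(R, L1, nF1))
  for (f in seq_len(nF1))
    for (d in seq_len(fw)) {
      cols <- d:(d + L3 - 1L)
      dA1[, cols, f] <- dA1[, cols, f] +
        matrix(dA2stack[, (f - 1L) * fw + d], R, L3)
    }
  dP1 <- dA1 * (fwd$A1 > 0)
  # scatter through the max pool: pooled bin j, offset o -> conv bin
  # j + o - 2 (the -Inf padding at the edges is never the argmax)
  dC1 <- array(0, c(R, L1, nF1))
  for (o in 1:3) {
    src <- seq_len(L1) + o - 2L
    ok <- src >= 1L & src <= L1
    contrib <- dP1[, ok, , drop = FALSE] *
      (fwd$amax[, ok, , drop = FALSE] == o)
    dC1[, src[ok], ] <- dC1[, src[ok], , drop = FALSE] + contrib
  }
  gb1 <- apply(dC1, 3L, sum)
  gw1 <- t(crossprod(fwd$X1, matrix(dC1, R * L1, nF1)))
  list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2, W1 = gW1, bd1 = gbd1,
       W2 = gW2, bd2 = gbd2)
}

# one full sample array (S, n, t) -> (S*n) x t matrix
.cnnFlattenInput <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(1L, 2L, 3L)), d[1L] * d[2L], d[3L])
}

#' Train the convolutional control classifier
#'
#' Trains the control network to separate spontaneous from evoked
#' population activity. Inputs are per-trial neurons x time matrices (the
#' same binned format the PCA uses); labels are one-hot encoded. Each of
#' the \code{nRestarts} restarts draws a fresh 70/30 train/test split and
#' fresh initialisation, trains with full-batch gradient descent under the
#' halving learning-rate schedule, and keeps the weights with the lowest
#' test loss; the per-restart test confusion matrices are averaged
#' elementwise and the reported F1 is computed from the averaged matrix.
#' A restart with a non-finite loss is flagged and excluded with a
#' warning.
#'
#' @param spontTensor,evokedTensor \linkS4class{TrialTensor}s (or
#'   trials x bins x neurons arrays) of the two classes; trial counts
#'   should be balanced.
#' @param spec a \linkS4class{CNNSpec}; defaults to the architecture for
#'   the given input shape.
#' @param seed master RNG seed.
#' @param standardize z-score every input feature using training-set
#'   statistics before the forward pass (computed per restart from that
#'   restart's training split only). Standardisation conditions the
#'   fixed-schedule gradient descent; disable to train on raw binned
#'   activity.
#' @return a \linkS4class{CNNResult}.
#' @export
trainCNN <- function(spontTensor, evokedTensor, spec = NULL, seed = 1L,
                     standardize = TRUE) {
  getArr <- function(x) if (is(x, "TrialTensor")) activity(x) else x
  a1 <- getArr(spontTensor); a2 <- getArr(evokedTensor)
  if (!identical(dim(a1)[-1L], dim(a2)[-1L]))
    stop("spontaneous and evoked tensors must share bins and neurons")
  # (trials, bins, neurons) -> (trials, neurons, bins)
  a1 <- aperm(a1, c(1L, 3L, 2L)); a2 <- aperm(a2, c(1L, 3L, 2L))
  n <- dim(a1)[2L]; t0 <- dim(a1)[3L]
  if (is.null(spec)) spec <- cnnSpec(n, t0)
  S1 <- dim(a1)[1L]; S2 <- dim(a2)[1L]
  S <- S1 + S2
  X <- array(0, c(S, n, t0))
  X[seq_len(S1), , ] <- a1
  X[S1 + seq_len(S2), , ] <- a2
  yIdx <- c(rep(1L, S1), rep(2L, S2))
  conf <- array(0, c(spec@nRestarts, 2L, 2L))
  losses <- rep(NA_real_, spec@nRestarts)
  included <- rep(TRUE, spec@nRestarts)
  for (r in seq_len(spec@nRestarts)) {
    set.seed(seed + r)
    trIdx <- .stratifiedSplit(yIdx, spec@trainFraction)
    teIdx <- setdiff(seq_len(S), trIdx)
    Str <- length(trIdx); Ste <- length(teIdx)
    Xtr3 <- X[trIdx, , , drop = FALSE]
    Xte3 <- X[teIdx, , , drop = FALSE]
    if (standardize) {
      # per (neuron, time) feature, training-split statistics only
      mu <- colMeans(Xtr3, dims = 1L)
      sg <- pmax(sqrt(pmax(colMeans(Xtr3^2, dims = 1L) - mu^2, 0)), 1e-8)
      Xtr3 <- sweep(sweep(Xtr3, c(2L, 3L), mu), c(2L, 3L), sg, `/`)
      Xte3 <- sweep(sweep(Xte3, c(2L, 3L), mu), c(2L, 3L), sg, `/`)
    }
    Xtr <- .cnnFlattenInput(Xtr3)
    Xte <- .cnnFlattenInput(Xte3)
    Ytr <- diag(2)[yIdx[trIdx], , drop = FALSE]
    Yte <- diag(2)[yIdx[teIdx], , drop = FALSE]
    par <- .cnnInit(spec)
    bestLoss <- Inf
    bestPred <- NULL
    ok <- TRUE
    for (ep in seq_len(spec@epochs) - 1L) {
      fwd <- .cnnForward(par, Xtr, spec, Str)
      if (!all(is.finite(fwd$Pr))) { ok <- FALSE; break }
      gr <- .cnnBackward(par, fwd, Ytr, spec, Str)
      lr <- lrSchedule(ep, spec@lrStart, spec@lrHalveEvery, spec@lrFloor)
      for (nm in names(par)) par[[nm]] <- par[[nm]] - lr * gr[[nm]]
      fwdTe <- .cnnForward(par, Xte, spec, Ste)
      teLoss <- .cnnLoss(fwdTe$Pr, Yte)
      if (!is.finite(teLoss)) { ok <- FALSE; break }
      if (teLoss < bestLoss) {
        bestLoss <- teLoss
        bestPred <- max.col(fwdTe$Pr, ties.method = "first")
      }
    }
    if (!ok || is.null(bestPred)) {
      warning("restart ", r, " diverged (non-finite loss); excluded")
      included[r] <- FALSE
      next
    }
    losses[r] <- bestLoss
    m <- matrix(0, 2L, 2L)
    for (i in seq_len(Ste))
      m[yIdx[teIdx[i]], bestPred[i]] <- m[yIdx[teIdx[i]], bestPred[i]] + 1
    conf[r, , ] <- m
  }
  if (!any(included)) stop("all restarts diverged")
  avg <- apply(conf[included, , , drop = FALSE], c(2L, 3L), mean)
  new("CNNResult", confusions = conf, averagedConfusion = avg,
      f1 = f1FromConfusion(avg)$macroF1, testLosses = losses,
      included = included, classes = c("spontaneous", "evoked"))
}
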