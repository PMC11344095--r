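#' Cohen's d from group summary statistics
#'
#' \code{d = (mean1 - mean2) / SD_pooled} with
#' \code{SD_pooled = sqrt((sd1^2 + sd2^2) / 2)} (equal group sizes). The
#' sign follows the mean difference.
#'
#' @param mean1,sd1 first group mean and SD.
#' @param mean2,sd2 second group mean and SD.
#' @return signed effect size d.
#' @export
cohensD <- function(mean1, sd1, mean2, sd2) {
  if (any(c(sd1, sd2) < 0)) stop("SDs must be >= 0")
  if (sd1 == 0 && sd2 == 0) stop("both SDs are zero; d undefined")
  (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Two-sided paired-sample t test
#'
#' Standard paired t on the positionwise differences, df = n - 1,
#' two-sided p from the t distribution. Identical samples give t = 0 and
#' p = 1; a zero-variance non-zero difference is degenerate and rejected.
#'
#' @param a,b equal-length numeric samples, paired by position.
#' @return list with \code{t}, \code{df} and \code{p}.
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("samples must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(a) - 1L, p = 1))
    stop("degenerate pairing: constant non-zero differences")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Per-window summary of a decoding curve
#'
#' Mean F1, SD and normal-approximation 95\% CI
#' (\code{mean +/- 1.96 SD / sqrt(nReps)}) per window, the shuffled-null
#' mean and SD, and the curve smoothed with a centered rolling average of
#' three bins (edge windows truncate to two bins, so the series keeps its
#' length).
#'
#' @param curve a \linkS4class{WindowedCurve}.
#' @return data.frame with one row per window.
#' @export
windowSummary <- function(curve) {
  f1 <- f1Scores(curve)
  nReps <- ncol(f1)
  m <- rowMeans(f1)
  s <- apply(f1, 1L, stats::sd)
  nullM <- nullScores(curve)
  out <- data.frame(start = curve@windows$start,
                    width = curve@windows$width,
                    meanF1 = m, sdF1 = s,
                    ciLo = m - 1.96 * s / sqrt(nReps),
                    ciHi = m + 1.96 * s / sqrt(nReps))
  out$smoothedF1 <- zoo::rollapply(m, 3L, mean, partial = TRUE)
  if (ncol(nullM)) {
    out$nullMean <- rowMeans(nullM)
    out$nullSd <- apply(nullM, 1L, stats::sd)
  }
  out
}

#' Pool per-repetition F1 scores over window spans and sessions
#'
#' Groups the raw per-repetition F1 scores of one or more windowed curves
#' into pooled samples per time span (e.g. the 200 ms prestimulus window
#' versus five 200 ms poststimulus windows), preserving the (session,
#' window, repetition) indexing so that spans can be compared pairwise.
#' With 3 sessions x 20 windows x 50 repetitions each span pools
#' N = 3000 scores.
#'
#' @param curves list of \linkS4class{WindowedCurve}s (one per session)
#'   sharing the same window geometry.
#' @param spans named list of length-2 numeric spans \code{c(lo, hi)} in
#'   ms; windows with \code{lo <= start < hi} are pooled.
#' @return named list of data.frames with columns \code{f1},
#'   \code{session}, \code{window} (rank within span) and \code{rep},
#'   sorted by (session, window, rep).
#' @export
buildGroupedF1 <- function(curves, spans) {
  if (is(curves, "WindowedCurve")) curves <- list(curves)
  geo <- lapply(curves, function(cv) cv@windows)
  for (g in geo[-1L]) if (!identical(g, geo[[1L]]))
    stop("sessions have mismatching window geometry")
  starts <- geo[[1L]]$start
  lapply(spans, function(sp) {
    wIdx <- which(starts >= sp[1L] & starts < sp[2L])
    if (!length(wIdx)) stop("span [", sp[1L], ", ", sp[2L],
                            ") contains no windows")
    out <- do.call(rbind, lapply(seq_along(curves), function(s) {
      f1 <- f1Scores(curves[[s]])[wIdx, , drop = FALSE]
      data.frame(f1 = as.vector(t(f1)),
                 session = s,
                 window = rep(seq_along(wIdx), each = ncol(f1)),
                 rep = rep(seq_len(ncol(f1)), times = length(wIdx)))
    }))
    out[order(out$session, out$window, out$rep), , drop = FALSE]
  })
}

#' Effect-size report: prestimulus versus poststimulus decoding
#'
#' Compares the pooled prestimulus F1 distribution against each pooled
#' poststimulus span with a two-sided paired-sample t test (pairing by
#' session, window rank and repetition index) and Cohen's d from the two
#' group means and SDs.
#'
#' @param preGroup pooled prestimulus scores (one element of
#'   \code{\link{buildGroupedF1}}).
#' @param postGroups named list of pooled poststimulus score groups of the
#'   same size.
#' @return data.frame with one row per comparison: group means/SDs, t, df,
#'   two-sided p and d.
#' @export
effectReport <- function(preGroup, postGroups) {
  rows <- lapply(names(postGroups), function(nm) {
    po <- postGroups[[nm]]
    if (nrow(po) != nrow(preGroup))
      stop("span '", nm, "' has a different sample size than the ",
           "prestimulus group")
    tt <- pairedT(preGroup$f1, po$f1)
    data.frame(comparison = nm, n = nrow(po),
               preMean = mean(preGroup$f1), preSd = stats::sd(preGroup$f1),
               postMean = mean(po$f1), postSd = stats::sd(po$f1),
               t = tt$t, df = tt$df, p = tt$p,
               d = cohensD(mean(preGroup$f1), stats::sd(preGroup$f1),
                           mean(po$f1), stats::sd(po$f1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shapiro-Wilk normality diagnostic for pooled F1 groups
#'
#' Optional diagnostic (not a gate): Shapiro-Wilk statistic and p per
#' group, on a subsample when the group exceeds the test's 5000-value
#' limit.
#'
#' @param groups named list of pooled score groups.
#' @param seed subsampling seed.
#' @return data.frame with one row per group.
#' @export
normalityReport <- function(groups, seed = 1L) {
  rows <- lapply(names(groups), function(nm) {
    x <- groups[[nm]]$f1
    if (length(x) > 5000L) {
      set.seed(seed)
      x <- sample(x, 5000L)
    }
    sw <- stats::shapiro.test(x)
    data.frame(group = nm, W = unname(sw$statistic), p = sw$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
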