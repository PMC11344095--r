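# Shared fixtures, built once per test run.

# small tactile session for structural checks
tinyConfig <- simConfig(nNeurons = 12L, repsPerPattern = 6L,
                        baselineRateRange = c(4, 12), seed = 101L)
tinySession <- generateSession(tinyConfig)

# mid-size session reused by the state-space and kNN tests
midConfig <- simConfig(nNeurons = 30L, repsPerPattern = 30L, seed = 202L)
midSession <- generateSession(midConfig)

# deterministic spike table builder
spikeTable <- function(...) {
  args <- list(...)
  do.call(rbind, lapply(seq_along(args), function(i)
    data.frame(neuron = i, time = sort(args[[i]]))))
}

# independent brute-force kNN oracle: plain loops, same tie conventions
# (majority vote; ties by summed inverse distance, then lowest class index)
bruteKnn <- function(train, cl, test, k, nClasses) {
  pred <- integer(nrow(test))
  for (i in seq_len(nrow(test))) {
    d <- numeric(nrow(train))
    for (j in seq_len(nrow(train)))
      d[j] <- sqrt(sum((test[i, ] - train[j, ])^2))
    nb <- order(d)[seq_len(k)]
    counts <- rep(0L, nClasses)
    for (j in nb) counts[cl[j]] <- counts[cl[j]] + 1L
    best <- which(counts == max(counts))
    if (length(best) > 1L) {
      sc <- numeric(length(best))
      for (b in seq_along(best))
        for (j in nb) if (cl[j] == best[b])
          sc[b] <- sc[b] + 1 / max(d[j], 1e-300)
      best <- best[which.max(sc)]
    }
    pred[i] <- best[1L]
  }
  pred
}

# a minimal valid PCModel for constructing ScoredPoints by hand
identityModel <- function(n) {
  new("PCModel", center = rep(0, n), loadings = diag(n),
      eigenvalues = rep(1, n), varianceRatios = rep(1 / n, n),
      nPoints = n + 1L, source = "identity")
}
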