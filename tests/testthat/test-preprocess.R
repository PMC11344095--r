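test_that("qc filter applies the rate and ISI-violation criteria", {
  # neuron 1: 300 spikes over 600 s = 0.5 Hz -> excluded for rate
  # neuron 2: regular 100 ms ISIs at 10 Hz -> kept
  # neuron 3: 1000 ISIs of which 15 are 1 ms (1.5%) -> excluded for ISI
  isi3 <- c(rep(0.001, 15), rep(0.55, 985))
  set.seed(9); isi3 <- sample(isi3)
  tab <- spikeTable(seq(1, 600, by = 2),
                    seq(0.05, 600, by = 0.1),
                    cumsum(c(0.5, isi3)))
  qc <- qcFilter(tab, sessionLength = 600)
  expect_equal(qc$keep, 2L)
  expect_equal(qc$report$reason, c("rate", "", "isi"))
  # brute-force violation count agrees with the report
  expect_equal(qc$report$isiViolation[3], 15 / 1000)
  expect_error(qcFilter(tab, sessionLength = 0), "positive")
})

test_that("raising thresholds never enlarges the kept set", {
  set.seed(31)
  tab <- do.call(rbind, lapply(1:12, function(i)
    data.frame(neuron = i,
               time = sort(runif(rpois(1, 400) + 2, 0, 300)))))
  kept <- function(minRate, maxViol)
    qcFilter(tab, 300, minRate = minRate, maxViolation = maxViol)$keep
  for (r in c(0.5, 0.8, 1.2)) {
    expect_true(all(kept(r + 0.4, 0.01) %in% kept(r, 0.01)))
    expect_true(all(kept(r, 0.005) %in% kept(r, 0.02)))
  }
})

test_that("responsiveness needs two consecutive supra-threshold PSTH bins", {
  # identical trials: PSTH equals the per-trial pattern exactly.
  # prestimulus bins alternate 1/0 spikes -> mean 0.5, sd ~0.502;
  # threshold = mean + 2 sd ~ 1.5 spikes per 2 ms bin.
  onsets <- seq(5, 5 + 19, by = 1)
  preSpk <- as.vector(outer(-0.3 + (seq(1, 149, by = 2) - 0.5) * 0.002,
                            onsets, `+`))
  mkPost <- function(bins) as.vector(outer((bins - 0.5) * 0.002, onsets,
                                           `+`))
  lg <- data.frame(onset = onsets, label = "F5", modality = "tactile",
                   duration = 300, condition = "")
  # one isolated supra bin (2 spikes in bin 10) -> non-responsive
  iso <- data.frame(neuron = 1L,
                    time = sort(c(preSpk, mkPost(10), mkPost(10) + 1e-4)))
  rf <- responsivenessFilter(iso, lg)
  expect_false(rf$report$responsive[1])
  # two adjacent supra bins (bins 10 and 11) -> responsive
  adj <- data.frame(neuron = 1L,
    time = sort(c(preSpk, mkPost(10), mkPost(10) + 1e-4,
                  mkPost(11), mkPost(11) + 1e-4)))
  rf2 <- responsivenessFilter(adj, lg)
  expect_true(rf2$report$responsive[1])
  expect_error(responsivenessFilter(iso, lg[1, ]), "2 stimulus events")
})

test_that("homogeneous Poisson neurons are mostly non-responsive", {
  set.seed(77)
  onsets <- seq(3, 3 + 39, by = 1)
  lg <- data.frame(onset = onsets, label = "x", modality = "tactile",
                   duration = 300, condition = "")
  tab <- do.call(rbind, lapply(1:40, function(i)
    data.frame(neuron = i, time = sort(runif(rpois(1, 50 * 8), 0, 50)))))
  rf <- responsivenessFilter(tab, lg)
  expect_lt(mean(rf$report$responsive), 0.15)
})

test_that("binning conserves spike counts and nests across widths", {
  set.seed(5)
  tab <- data.frame(neuron = sample(1:6, 4000, replace = TRUE),
                    time = runif(4000, 0, 3))
  fr1 <- binSpikes(tab, 1, c(0, 3), neuronIds = 1:6)
  expect_equal(sum(activity(fr1)), 4000)
  fr300 <- binSpikes(tab, 300, c(0, 3), neuronIds = 1:6)
  reb <- apply(activity(fr1), 2L, function(col)
    colSums(matrix(col, 300)))
  expect_equal(unname(reb), unname(activity(fr300)))
  # empty table -> all-zero frame
  fr0 <- binSpikes(tab[0, ], 10, c(0, 1), neuronIds = 1:6)
  expect_true(all(activity(fr0) == 0))
  expect_equal(dim(activity(fr0)), c(100L, 6L))
  # partial final bin is dropped with a message
  expect_message(binSpikes(tab, 7, c(0, 3), neuronIds = 1:6), "partial")
})

test_that("trial extraction partitions time and preserves counts", {
  tens <- extractTrials(tinySession, pre = 300, post = 300, binWidth = 1)
  lg <- stimulusLog(tinySession)
  sp <- spikes(tinySession)
  expect_equal(dim(activity(tens$post)), c(nrow(lg), 300L, 12L))
  expect_equal(tens$pre@window, c(-300, 0))
  # counts equal a direct per-window recount
  e <- 5L
  inPre <- sum(sp$time >= lg$onset[e] - 0.3 & sp$time < lg$onset[e])
  inPost <- sum(sp$time >= lg$onset[e] & sp$time < lg$onset[e] + 0.3)
  expect_equal(sum(activity(tens$pre)[e, , ]), inPre)
  expect_equal(sum(activity(tens$post)[e, , ]), inPost)
  # concatenating pre+post and re-slicing returns the originals
  whole <- extractTrials(tinySession, pre = 300, post = 300,
                         binWidth = 1)
  joint <- abind <- array(0, c(nrow(lg), 600, 12))
  joint[, 1:300, ] <- activity(whole$pre)
  joint[, 301:600, ] <- activity(whole$post)
  expect_equal(joint[, 1:300, ], activity(tens$pre))
  expect_equal(joint[, 301:600, ], activity(tens$post))
  # overlapping windows rejected
  lg2 <- lg; lg2$onset <- seq(1, by = 0.4, length.out = nrow(lg))
  expect_error(extractTrials(spikes(tinySession), lg2, pre = 300,
                             post = 300, binWidth = 1), "verlapping")
})

test_that("sequential averaging groups per label in presentation order", {
  set.seed(12)
  nTr <- 40L
  arr <- array(rpois(nTr * 20 * 3, 2), c(nTr, 20, 3))
  info <- data.frame(label = rep(c("A", "B"), each = 20),
                     condition = "", onset = seq_len(nTr),
                     group = seq_len(nTr), windowType = "post")
  tens <- new("TrialTensor", activity = arr, binWidth = 1,
              window = c(0, 20), trialInfo = info)
  # group size 1 is the identity
  av1 <- averageSequential(tens, 1L)
  expect_equal(activity(av1), arr)
  av <- averageSequential(tens, 5L)
  expect_s4_class(av, "AveragedTrialTensor")
  expect_equal(dim(activity(av))[1], 8L)  # 20 / 5 = 4 groups per label
  # each group is the elementwise mean of its members
  expect_equal(activity(av)[1, , ], colMeans(arr[1:5, , ], dims = 1))
  # grand mean over groups equals grand mean over trials
  expect_equal(mean(activity(av)), mean(arr), tolerance = 1e-12)
  # partial groups are dropped, too-small labels rejected
  expect_message(averageSequential(tens, 15L), "dropping")
  expect_error(averageSequential(tens, 25L), "fewer trials")
})

test_that("Gaussian smoothing is unit-mass and matches the closed form", {
  arr <- array(0, c(2, 200, 2))
  tens <- new("TrialTensor", activity = arr, binWidth = 1,
              window = c(0, 200),
              trialInfo = data.frame(label = c("a", "b"), condition = "",
                                     onset = 1:2, group = 1:2,
                                     windowType = "post"))
  expect_true(all(activity(smoothGaussian(tens, 10)) == 0))
  # unit impulse -> sampled unit-mass Gaussian of the stated SD,
  # symmetric about the impulse (closed-form oracle via dnorm)
  arr[1, 100, 1] <- 1
  tens@activity <- arr
  sm <- activity(smoothGaussian(tens, 10))[1, , 1]
  w <- dnorm(-40:40, sd = 10); w <- w / sum(w)
  expected <- rep(0, 200); expected[100 + (-40:40)] <- w
  expect_equal(sm, expected, tolerance = 1e-12)
  expect_equal(which.max(sm), 100)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  # mass away from the boundaries is preserved to numerical precision
  set.seed(2)
  arr2 <- array(0, c(3, 300, 4))
  arr2[, 46:255, ] <- rpois(3 * 210 * 4, 1)   # interior support only
  t2 <- new("TrialTensor", activity = arr2, binWidth = 1,
            window = c(0, 300),
            trialInfo = data.frame(label = "a", condition = "",
                                   onset = 1:3, group = 1:3,
                                   windowType = "post"))
  s2 <- smoothGaussian(t2, 10)
  expect_equal(apply(activity(s2), c(1, 3), sum),
               apply(arr2, c(1, 3), sum), tolerance = 1e-9)
  expect_error(smoothGaussian(t2, 0.5), "kernel")
})
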