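test_that("F1 follows the printed precision/recall formulas", {
  # perfect diagonal -> macro F1 = 1
  expect_equal(f1FromConfusion(diag(5) * 7)$macroF1, 1)
  # binary TP=3, FP=1, FN=1, TN=3: precision = recall = F1 = 0.75
  m <- matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE)
  r <- f1FromConfusion(m)
  expect_equal(r$perClass$precision[1], 3 / (3 + 1))
  expect_equal(r$perClass$recall[1], 3 / (3 + 1))
  expect_equal(r$perClass$f1[1], 2 * 0.75 * 0.75 / (0.75 + 0.75))
  # uniform 4-class matrix -> macro F1 = 0.25
  expect_equal(f1FromConfusion(matrix(2, 4, 4))$macroF1, 0.25)
  # empty classes get zero factors, all-zero matrices are rejected
  m0 <- matrix(c(4, 2, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(f1FromConfusion(m0)$perClass$recall[2], 0)
  expect_error(f1FromConfusion(matrix(0, 2, 2)), "zero")
})

test_that("kNN predictions equal the brute-force oracle exactly", {
  set.seed(17)
  cases <- list(c(40, 25, 2), c(80, 60, 3), c(120, 80, 4), c(30, 30, 2),
                c(100, 100, 4))
  for (cs in cases) {
    nTr <- cs[1]; nTe <- cs[2]; nC <- cs[3]
    train <- matrix(rnorm(nTr * 3), nTr, 3)
    test <- matrix(rnorm(nTe * 3), nTe, 3)
    cl <- sample(rep_len(seq_len(nC), nTr))
    got <- popdecode:::.knnPredict(train, cl, test, 5L, nC)
    expect_identical(got, bruteKnn(train, cl, test, 5L, nC))
  }
})

test_that("separable clusters decode perfectly, identical ones at chance", {
  set.seed(23)
  X <- rbind(matrix(rnorm(60 * 4), 60, 4),
             matrix(rnorm(60 * 4, mean = 50), 60, 4))
  lab <- rep(c("a", "b"), each = 60)
  run <- knnDecode(X, lab, nReps = 10, seed = 5)
  expect_gte(mean(f1Scores(run)), 0.99)
  expect_equal(dim(confusionMatrices(run)), c(10L, 2L, 2L))
  # confusion rows sum to per-class test counts
  expect_true(all(apply(confusionMatrices(run), 1, rowSums) == 30))
  # same distribution for both classes: F1 within 3 null SDs of 0.5
  X0 <- matrix(rnorm(240 * 4), 240, 4)
  lab0 <- rep(c("a", "b"), each = 120)
  run0 <- knnDecode(X0, lab0, nReps = 20, seed = 6, nShuffles = 20)
  nullSd <- sd(nullScores(run0))
  expect_lt(abs(mean(f1Scores(run0)) - 0.5), 3 * nullSd)
  expect_lt(abs(mean(nullScores(run0)) - 0.5), 3 * nullSd)
  expect_error(knnDecode(X0[1:8, ], lab0[c(1:4, 121:124)], k = 50L),
               "exceeds")
})

test_that("decoding is deterministic under the seed", {
  set.seed(31)
  X <- matrix(rnorm(100 * 3), 100, 3)
  lab <- rep(c("a", "b"), 50)
  r1 <- knnDecode(X, lab, nReps = 5, seed = 9)
  r2 <- knnDecode(X, lab, nReps = 5, seed = 9)
  expect_identical(f1Scores(r1), f1Scores(r2))
  expect_identical(confusionMatrices(r1), confusionMatrices(r2))
})

test_that("forcing the identity permutation reproduces the real score", {
  set.seed(37)
  X <- rbind(matrix(rnorm(40 * 3), 40, 3),
             matrix(rnorm(40 * 3, mean = 2), 40, 3))
  lab <- rep(c("a", "b"), each = 40)
  seed <- 11L
  nullId <- shuffledNull(X, lab, permutations = list(seq_along(lab)),
                         seed = seed)
  direct <- knnDecode(X, lab, nReps = 1, seed = seed + 200000L + 1L)
  expect_equal(nullId, mean(f1Scores(direct)))
})

test_that("group-aware splits keep whole groups on one side", {
  set.seed(41)
  # two interleaved groups per class; within-group points are near-copies
  centers <- matrix(rnorm(8 * 3, sd = 5), 8, 3)
  X <- centers[rep(1:8, each = 10), ] + rnorm(240, sd = 1e-3)
  lab <- rep(rep(c("a", "b"), each = 4), each = 10)
  grp <- rep(1:8, each = 10)
  runG <- knnDecode(X, lab, groups = grp, nReps = 10, seed = 3)
  # with random group centers the classes are not separable: group-level
  # splits must stay near chance, while point-level splits leak group
  # identity and score almost perfectly
  runP <- knnDecode(X, lab, groups = NA, nReps = 10, seed = 3)
  expect_gt(mean(f1Scores(runP)), 0.95)
  expect_lt(mean(f1Scores(runG)), 0.8)
  expect_error(knnDecode(X, rep(c("a", "b"), 40), groups = grp),
               "single label")
})

test_that("spontaneous-window balancing subsamples whole windows", {
  arr <- array(abs(rnorm(20 * 5 * 3)), c(20, 5, 3))
  tens <- new("TrialTensor", activity = arr, binWidth = 1,
              window = c(-5, 0),
              trialInfo = data.frame(label = "s", condition = "",
                                     onset = 1:20, group = 1:20,
                                     windowType = "pre"))
  expect_identical(balanceSpontaneous(tens, 20L), tens)
  sub <- balanceSpontaneous(tens, 8L, seed = 2L)
  expect_equal(dim(activity(sub))[1], 8L)
  sub2 <- balanceSpontaneous(tens, 8L, seed = 2L)
  expect_identical(activity(sub), activity(sub2))
  # retained windows are intact rows of the original
  kept <- trialInfo(sub)$group
  expect_equal(activity(sub), arr[kept, , , drop = FALSE])
  expect_error(balanceSpontaneous(tens, 30L), "exceeds")
})

test_that("single-neuron decoding separates a time-shifted +V response", {
  onsets <- seq(2, by = 1, length.out = 40)
  cond <- rep(c("-V", "+V"), 20)
  lg <- data.frame(onset = onsets, label = "F5", modality = "visuotactile",
                   duration = 300, condition = cond)
  set.seed(3)
  mkTimes <- function(centers) unlist(lapply(seq_along(onsets), function(e) {
    ctr <- if (cond[e] == "+V") centers[2] else centers[1]
    onsets[e] + ctr + rnorm(8, sd = 0.005)
  }))
  # neuron 1: responds at 50 ms (-V) versus 150 ms (+V); neuron 2: same
  # latency in both conditions
  sp <- rbind(data.frame(neuron = 1L, time = mkTimes(c(0.05, 0.15))),
              data.frame(neuron = 2L, time = mkTimes(c(0.10, 0.10))))
  sp <- sp[order(sp$neuron, sp$time), ]
  sess <- new("SpikeSession", spikes = sp, stimulusLog = lg,
              sessionLength = 45, nNeurons = 2L)
  res <- singleNeuronDecode(sess, nReps = 10, seed = 4)
  f1Shift <- res$f1[res$neuron == 1]
  f1Same <- res$f1[res$neuron == 2]
  expect_gt(f1Shift, 0.85)
  expect_lt(abs(f1Same - 0.5), 0.25)
})
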