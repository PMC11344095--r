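test_that("planar data yields exactly two non-zero eigenvalues", {
  set.seed(1)
  B <- qr.Q(qr(matrix(rnorm(60 * 2), 60, 2)))
  pts <- matrix(rnorm(500 * 2), 500, 2) %*% t(B)
  pts <- sweep(pts, 2L, rnorm(60), `+`)
  m <- fitSpontaneous(pts)
  ev <- eigenvalues(m)
  expect_gt(ev[2], 1e-6)
  expect_true(all(ev[3:60] < 1e-10 * ev[1]))
  expect_equal(nComponentsFor(m, 1), 2L)
})

test_that("eigenvalues match an independent covariance eigendecomposition", {
  set.seed(3)
  pts <- matrix(rnorm(500 * 20), 500, 20) %*%
    matrix(rnorm(20 * 20, sd = 0.5), 20, 20)
  m <- fitSpontaneous(pts)
  oracle <- eigen(cov(pts), symmetric = TRUE)$values
  expect_equal(eigenvalues(m), pmax(oracle, 0), tolerance = 1e-8)
  expect_equal(sum(varianceRatios(m)), 1, tolerance = 1e-9)
  # orthonormality of the basis
  G <- crossprod(pcLoadings(m))
  expect_lt(max(abs(G - diag(20))), 1e-8)
  expect_error(fitSpontaneous(pts[1:10, ]), "fewer")
})

test_that("component counts are monotone in the variance fraction", {
  set.seed(4)
  pts <- matrix(rnorm(2000 * 25), 2000, 25) %*% diag(exp(seq(0, -3,
    length.out = 25)))
  m <- fitSpontaneous(pts)
  n50 <- nComponentsFor(m, 0.5)
  n95 <- nComponentsFor(m, 0.95)
  n100 <- nComponentsFor(m, 1.0)
  expect_lte(n50, n95)
  expect_lte(n95, n100)
  expect_equal(n100, 25L)
  expect_error(nComponentsFor(m, 0), "fraction")
  # isotropic 30-d Gaussian: near-linear cumulative spectrum
  iso <- fitSpontaneous(matrix(rnorm(6000 * 30), 6000, 30))
  expect_true(nComponentsFor(iso, 0.95) %in% c(29L, 30L))
})

test_that("projection is a centered orthonormal coordinate change", {
  set.seed(6)
  nTr <- 20L; nb <- 30L; nn <- 15L
  arr <- array(abs(rnorm(nTr * nb * nn, mean = 3)), c(nTr, nb, nn))
  info <- data.frame(label = rep(c("A", "B"), each = 10),
                     condition = "", onset = seq_len(nTr),
                     group = seq_len(nTr), windowType = "pre")
  tens <- new("TrialTensor", activity = arr, binWidth = 1,
              window = c(-nb, 0), trialInfo = info)
  m <- fitSpontaneous(tens)
  full <- projectActivity(m, tens, nComponents = nn)
  # round trip through the full basis recovers the data
  rec <- scores(full) %*% t(pcLoadings(m))
  rec <- sweep(rec, 2L, m@center, `+`)
  pts <- matrix(arr, nTr * nb, nn)
  expect_lt(max(abs(rec - pts)) / max(abs(pts)), 1e-10)
  # centering: spontaneous scores have zero mean per component
  expect_lt(max(abs(colMeans(scores(full)))), 1e-9)
  # score variances equal the model eigenvalues
  expect_equal(unname(apply(scores(full), 2L, var)), eigenvalues(m),
               tolerance = 1e-9)
  # distances are preserved by the full-rank basis
  d0 <- dist(pts[1:50, ])
  d1 <- dist(scores(full)[1:50, ])
  expect_lt(max(abs(d0 - d1)), 1e-8)
  # point labels cover every point, in flattening order
  inf <- pointInfo(full)
  expect_equal(nrow(inf), nTr * nb)
  expect_equal(inf$timeRel[1:nTr], rep(-30, nTr))
  expect_equal(inf$label[seq_len(nTr)], info$label)
  # neuron mismatch rejected
  expect_error(projectActivity(identityModel(4L), tens), "match")
})

test_that("static rate vectors give identical dimensionality at any width", {
  set.seed(8)
  nTr <- 60L; nn <- 10L
  base <- matrix(rexp(nTr * nn), nTr, nn)  # one static vector per trial
  counts <- function(w) {
    nb <- 300 / w
    arr <- array(0, c(nTr, nb, nn))
    for (b in seq_len(nb)) arr[, b, ] <- base * w
    new("TrialTensor", activity = arr, binWidth = w, window = c(-300, 0),
        trialInfo = data.frame(label = "s", condition = "",
                               onset = seq_len(nTr), group = seq_len(nTr),
                               windowType = "pre"))
  }
  ns <- vapply(c(1, 50, 300), function(w)
    nComponentsFor(fitSpontaneous(counts(w)), 0.95), 0L)
  expect_true(all(ns == ns[1]))
})

test_that("dimensionality decreases with coarser binning on fast-latent
           synthetic sessions", {
  ns <- vapply(1:5, function(s) {
    cfg <- simConfig(nNeurons = 24L, repsPerPattern = 20L, seed = 300L + s)
    sess <- generateSession(cfg)
    d <- dimensionalityVsResolution(sess, widths = c(1, 50, 300))
    expect_true(all(diff(d$nComponents) <= 0))  # monotone non-increasing
    d$nComponents[c(1, 3)]
  }, integer(2))
  expect_true(all(ns[1, ] > ns[2, ]))  # strict decrease, 1 ms vs 300 ms
})

test_that("scored point sets combine preserving labels and components", {
  m <- identityModel(3L)
  arr <- array(rnorm(8 * 5 * 3), c(8, 5, 3))
  info <- data.frame(label = "A", condition = "", onset = 1:8,
                     group = 1:8, windowType = "pre")
  t1 <- new("TrialTensor", activity = abs(arr), binWidth = 1,
            window = c(-5, 0), trialInfo = info)
  info2 <- info; info2$windowType <- "post"
  t2 <- new("TrialTensor", activity = abs(arr) + 1, binWidth = 1,
            window = c(0, 5), trialInfo = info2)
  p1 <- projectActivity(m, t1, 3L)
  p2 <- projectActivity(m, t2, 3L)
  cmb <- combineScoredPoints(p1, p2)
  expect_equal(nrow(scores(cmb)), 80L)
  expect_equal(range(pointInfo(cmb)$timeRel), c(-5, 4))
})
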