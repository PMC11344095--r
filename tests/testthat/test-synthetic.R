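test_that("stimulus log bookkeeping: exact repetition counts and spacing", {
  lg <- stimulusLog(tinySession)
  expect_equal(nrow(lg), 4L * 6L)
  expect_true(all(table(lg$label) == 6L))
  expect_true(all(diff(lg$onset) > 1.3))
  expect_true(all(diff(lg$onset) <= 2.0 + 1e-9))
})

test_that("identical configurations regenerate bit-identical sessions", {
  s2 <- generateSession(tinyConfig)
  expect_identical(spikes(s2), spikes(tinySession))
  expect_identical(stimulusLog(s2), stimulusLog(tinySession))
  s3 <- generateSession(simConfig(nNeurons = 12L, repsPerPattern = 6L,
                                  baselineRateRange = c(4, 12),
                                  seed = 102L))
  expect_false(identical(spikes(s3), spikes(tinySession)))
})

test_that("stimulus-free constant-rate session matches the Poisson count", {
  cfg <- simConfig(nNeurons = 60L, sessionLength = 600,
                   baselineRateRange = c(5, 5), nLatents = 0L,
                   patternSet = list(), refractoryMs = 0, seed = 7L)
  sess <- generateSession(cfg)
  expected <- 5 * 60 * 600           # closed-form Poisson mean
  tol <- 4 * sqrt(expected)          # 4 SD of the Poisson total
  expect_lt(abs(nrow(spikes(sess)) - expected), tol)
})

test_that("zero evoked gain and persistence leave evoked windows at the
           spontaneous rate", {
  cfg <- simConfig(nNeurons = 20L, repsPerPattern = 12L, evokedGain = 0,
                   persistenceAmplitude = 0, seed = 55L)
  sess <- generateSession(cfg)
  tens <- extractTrials(sess, pre = 300, post = 300, binWidth = 300)
  preMean <- mean(activity(tens$pre))
  postMean <- mean(activity(tens$post))
  expect_lt(abs(postMean - preMean) / preMean, 0.05)
})

test_that("persistence term decays exponentially and is pattern specific", {
  dirs <- patternDirections(c("A", "B"), 25L, seed = 3L)
  expect_equal(persistenceTerm(c(0, 50), 0, 150, dirs$A),
               matrix(0, 2, 25))
  v <- persistenceTerm(150, 2, 150, dirs$A)
  expect_equal(sqrt(sum(v^2)), 2 / exp(1), tolerance = 1e-12)
  cosSim <- sum(dirs$A * dirs$B)
  expect_lt(cosSim, 1 - 1e-6)
  expect_error(persistenceTerm(10, 1, -1, dirs$A), "tau")
  # tau = 0 disables the term entirely
  expect_equal(persistenceTerm(c(0, 10), 1, 0, dirs$A), matrix(0, 2, 25))
})

test_that("visual modulation conserves window-integrated rate per neuron", {
  set.seed(42)
  prof <- matrix(rexp(300 * 15), 300, 15)
  expect_identical(visualModulation(prof, 0), prof)
  for (g in c(0.3, 0.8)) {
    mod <- visualModulation(prof, g)
    expect_equal(colSums(mod), colSums(prof), tolerance = 1e-9)
    expect_true(all(mod >= 0))
    # at least one 10 ms sub-window differs between +V and -V
    sub <- vapply(seq(1, 291, by = 10), function(s)
      max(abs(colSums(mod[s:(s + 9), ]) - colSums(prof[s:(s + 9), ]))), 0)
    expect_gt(max(sub), 1e-3)
  }
  # profiles longer than the modulated window keep the tail untouched
  prof2 <- matrix(rexp(340 * 5), 340, 5)
  mod2 <- visualModulation(prof2, 0.5)
  expect_identical(mod2[301:340, ], prof2[301:340, ])
  expect_equal(colSums(mod2[1:300, ]), colSums(prof2[1:300, ]),
               tolerance = 1e-9)
  expect_error(visualModulation(prof, 1.2), "visualGainMod")
})

test_that("generator rejects impossible configurations", {
  expect_error(simConfig(nNeurons = 0L), "nNeurons")
  expect_error(simConfig(baselineRateRange = c(-1, 5)), "rates")
  expect_error(
    generateSession(simConfig(interStimulusInterval = 1.0,
                              repsPerPattern = 2L)),
    "interval too short")
  expect_error(
    generateSession(simConfig(patternSet = list(),
                              sessionLength = NA_real_)),
    "sessionLength")
})

test_that("sessions and configurations round-trip through text files", {
  d <- withr::local_tempdir()
  writeSession(tinySession, file.path(d, "sp.csv"), file.path(d, "lg.csv"))
  back <- readSession(file.path(d, "sp.csv"), file.path(d, "lg.csv"),
                      sessionLength = tinySession@sessionLength,
                      nNeurons = 12L)
  expect_equal(spikes(back)$time, spikes(tinySession)$time,
               tolerance = 1e-9)
  expect_equal(stimulusLog(back)$label, stimulusLog(tinySession)$label)
  writeSimConfig(tinyConfig, file.path(d, "cfg.yaml"))
  cfg2 <- readSimConfig(file.path(d, "cfg.yaml"))
  expect_equal(cfg2@seed, tinyConfig@seed)
  expect_equal(cfg2@baselineRateRange, tinyConfig@baselineRateRange)
  sess2 <- generateSession(cfg2)
  expect_identical(spikes(sess2), spikes(tinySession))
})

test_that("emitted spike trains respect the configured refractory period", {
  sp <- spikes(tinySession)
  isis <- unlist(tapply(sp$time, sp$neuron, function(t) diff(sort(t))))
  expect_true(all(isis * 1000 >= 2 - 1e-6))
})
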