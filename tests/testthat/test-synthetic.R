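test_that("MVAR simulation is seeded, sized and decoupled as requested", {
  sim <- simulateMVAR(5, data.frame(from = c(1, 2, 4), to = c(2, 3, 5)),
                      nSamples = 30000, seed = 91)
  expect_equal(duration(sim$recording), 120)
  expect_equal(nChannels(sim$recording), 5)
  again <- simulateMVAR(5, data.frame(from = c(1, 2, 4), to = c(2, 3, 5)),
                        nSamples = 30000, seed = 91)
  expect_identical(recordingData(sim$recording),
                   recordingData(again$recording))
  # no edges -> channels mutually uncorrelated
  free <- simulateMVAR(4, NULL, nSamples = 30000, seed = 92)
  x <- recordingData(free$recording)
  cc <- cor(t(x))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("unstable coefficient requests are rescaled to stability", {
  sim <- simulateMVAR(2, data.frame(from = 1, to = 2, coef = 5),
                      nSamples = 2000, seed = 93, diagCoef = 1.2)
  comp <- kurtoseg:::.companionMatrix(sim$truth$A)
  expect_lt(max(Mod(eigen(comp, only.values = TRUE)$values)), 1)
  expect_true(all(is.finite(recordingData(sim$recording))))
})

test_that("piecewise-stationary blocks alternate regimes on the tau grid", {
  sim <- simulatePiecewiseStationary(2, tau = 2, duration = 20, fs = 100,
                                     regimes = list(list(sd = 1),
                                                    list(sd = 5)),
                                     seed = 94)
  x <- recordingData(sim$recording)[1, ]
  blockSd <- vapply(1:10, function(b) sd(x[((b - 1) * 200 + 1):(b * 200)]),
                    numeric(1))
  expect_true(all(blockSd[seq(1, 9, 2)] < 2))
  expect_true(all(blockSd[seq(2, 10, 2)] > 3))
  # tau = t collapses to a single stationary block
  one <- simulatePiecewiseStationary(1, tau = 10, duration = 10, fs = 100,
                                     seed = 95)
  expect_equal(nSamples(one$recording), 1000)
  expect_error(simulatePiecewiseStationary(1, tau = 30, duration = 10),
               "exceed")
  expect_error(simulatePiecewiseStationary(1, tau = 1, duration = 10,
                                           regimes = list(list(sd = -1))),
               "positive")
})

test_that("a single regime leaves the variance profile flat in expectation", {
  # with no regime switching, Ksigma^2 follows the 24/n estimator law:
  # column means must fall with window length, with no knee
  cm <- 0
  for (s in 1:5) {
    sim <- simulatePiecewiseStationary(4, tau = 60, duration = 60,
                                       fs = 250, seed = 700 + s)
    cm <- cm + colMeans(kurtosisValues(kurtosisVarianceMatrix(sim$recording)))
  }
  cm <- cm / 5
  expected <- 24 / (250 * (1:10))
  expect_true(all(cm / expected > 0.5 & cm / expected < 2))
})

test_that("Laplace regimes carry their positive excess kurtosis", {
  sim <- simulatePiecewiseStationary(1, tau = 60, duration = 60, fs = 500,
                                     regimes = list(list(sd = 1,
                                                         dist = "laplace"),
                                                    list(sd = 1,
                                                         dist = "laplace")),
                                     seed = 96)
  k <- kurtosisExcess(recordingData(sim$recording)[1, ])
  expect_gt(k, 2); expect_lt(k, 4)        # Laplace excess is 3
})

test_that("cohort fixtures reproduce the retention worked example", {
  tab <- restingCohortTable()
  fracs <- cbind(tab$clean_s[tab$condition == "R1"] /
                   tab$raw_s[tab$condition == "R1"],
                 tab$clean_s[tab$condition == "R2"] /
                   tab$raw_s[tab$condition == "R2"])
  fx <- cohortFixture(10, cleanFractions = fracs, seed = 97,
                      makeRecordings = FALSE)
  expect_equal(length(retentionFilter(fx$cohort)$subjects), 6)
  # a single subject yields one R1/R2 pair, deterministically
  one <- cohortFixture(1, durationRange = c(20, 30),
                       channelRange = c(3, 4), seed = 98, fs = 50)
  expect_equal(nrow(one$cohort), 2)
  expect_equal(sort(names(one$recordings))[1], "S1_R1")
  oneAgain <- cohortFixture(1, durationRange = c(20, 30),
                            channelRange = c(3, 4), seed = 98, fs = 50)
  expect_identical(one$cohort, oneAgain$cohort)
  if (length(one$recordings) && length(oneAgain$recordings)) {
    expect_identical(recordingData(one$recordings[[1]]),
                     recordingData(oneAgain$recordings[[1]]))
  }
})
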