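test_that("MVAR least squares recovers known coefficients", {
  sim <- simulateMVAR(2, data.frame(from = 1, to = 2, coef = 0.4),
                      nSamples = 5000, seed = 51)
  fit <- fitMVAR(recordingData(sim$recording), 1)
  expect_lt(sqrt(mean((fit@A[[1]] - sim$truth$A[[1]])^2)), 0.05)
  expect_true(fit@stable)
  expect_true(isSymmetric(fit@Sigma))
  expect_true(all(eigen(fit@Sigma, only.values = TRUE)$values > -1e-12))
  expect_error(fitMVAR(matrix(rnorm(3 * 10), 3), 3), "underdetermined")
})

test_that("white noise yields no spurious structure", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    set.seed(60 + s)
    x <- matrix(rnorm(3 * 2000), 3)
    fit <- fitMVAR(x, 1)
    # standard error of an AR coefficient on white noise ~ 1/sqrt(n)
    se <- 1 / sqrt(2000)
    hits <- hits + sum(abs(fit@A[[1]]) < 3 * se)
    total <- total + 9
  }
  expect_gte(hits / total, 0.9)
})

test_that("order selection finds AR(2) structure and honours 'fixed'", {
  good <- 0
  for (s in 1:10) {
    sim <- simulateMVAR(2, data.frame(from = c(1, 1), to = c(2, 2),
                                      lag = c(1, 2), coef = c(0.3, -0.35)),
                        order = 2, nSamples = 3000, seed = 70 + s,
                        diagCoef = 0.3)
    p <- selectOrder(recordingData(sim$recording), orderMax = 8)
    good <- good + (p == 2)
  }
  expect_gte(good / 10, 0.8)
  expect_equal(selectOrder(NULL, criterion = "fixed", order = 5), 5)
  set.seed(71)
  expect_equal(selectOrder(matrix(rnorm(2 * 500), 2), orderMax = 1), 1)
})

test_that("transfer matrix honours closed forms and triangular structure", {
  M0 <- new("MVARModel", A = list(matrix(0, 3, 3)), Sigma = diag(3),
            order = 1L, nobs = 100L, stable = TRUE)
  H <- transferMatrix(M0, c(1, 10, 50), 250)
  for (k in 1:3) expect_equal(H[, , k], diag(3) + 0i, ignore_attr = TRUE)
  # scalar AR(1): |H(f)|^2 = 1 / |1 - a e^{-i 2 pi f / fs}|^2
  a <- 0.6
  M1 <- new("MVARModel", A = list(matrix(a, 1, 1)), Sigma = diag(1),
            order = 1L, nobs = 100L, stable = TRUE)
  H1 <- transferMatrix(M1, 1:125, 250)
  closed <- 1 / Mod(1 - a * exp(-2i * pi * (1:125) / 250))^2
  expect_equal(as.numeric(Mod(H1[1, 1, ])^2), closed, tolerance = 1e-8)
  # unidirectional coupling keeps the reverse path exactly zero
  A <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)        # 1 -> 2 only
  M2 <- new("MVARModel", A = list(A), Sigma = diag(2), order = 1L,
            nobs = 100L, stable = TRUE)
  H2 <- transferMatrix(M2, 1:40, 250)
  expect_true(all(Mod(H2[2, 1, ]) > 0))
  expect_true(all(Mod(H2[1, 2, ]) == 0))
})

test_that("the squared DTF is a row-normalized inflow fraction", {
  expect_equal(dtf(diag(3)), diag(3), ignore_attr = TRUE)
  D <- dtf(matrix(c(1, 0, 1, 1), 2, 2))          # H = [[1,1],[0,1]]
  expect_equal(D, rbind(c(0.5, 0.5), c(0, 1)), ignore_attr = TRUE)
  set.seed(52)
  Hr <- matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5, 5)
  expect_equal(rowSums(dtf(Hr)), rep(1, 5), tolerance = 1e-10)
  expect_error(dtf(matrix(0, 2, 2)), "zero")
})

test_that("the DTF tensor covers the 1 Hz grid and all segments", {
  sim <- simulateMVAR(5, data.frame(from = 1, to = 2, coef = 0.5),
                      nSamples = 15000, seed = 53)
  tens <- dtfTensor(sim$recording, 4, order = 3)
  expect_equal(dim(dtfValues(tens)), c(5, 5, 125, 15))
  expect_equal(tens@freqs, 1:125)
  # squared-DTF conservation on every fit
  sums <- apply(dtfValues(tens), c(1, 3, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-8)
  # the coupled edge dominates the null edges in any band
  bv <- bandAverage(tens, c(8, 13))
  nullLevels <- c(bv[3, 1, ], bv[1, 2, ], bv[4, 5, ])
  expect_gt(mean(bv[2, 1, ]), mean(nullLevels) * 5)
  expect_error(dtfTensor(sim$recording, 40), "insufficient segments")
})

test_that("band averaging is plain grid arithmetic", {
  sim <- simulateMVAR(2, NULL, nSamples = 2000, seed = 54)
  tens <- dtfTensor(sim$recording, 2, order = 1)
  bv <- bandAverage(tens, c(8, 13))
  manual <- apply(dtfValues(tens)[, , 8:13, , drop = FALSE], c(1, 2, 4),
                  mean)
  expect_equal(bv, manual, ignore_attr = TRUE)
  one <- bandAverage(tens, c(10, 10))
  expect_equal(one[, , 1], dtfValues(tens)[, , 10, 1], ignore_attr = TRUE)
  expect_error(bandAverage(tens, c(10.2, 10.8)), "empty band")
})

test_that("significance masking flags coupled edges and rejects S = 1", {
  sim <- simulateMVAR(4, data.frame(from = 1, to = 3, coef = 0.6),
                      nSamples = 12000, seed = 55)
  tens <- dtfTensor(sim$recording, 2, order = 2)
  adj <- significanceAdjacency(tens)
  expect_true(significanceMask(adj)[3, 1])
  expect_true(is.na(edgePvalues(adj)[1, 1]))
  expect_equal(sum(significanceMask(adj)), 1)   # only the true edge
  short <- dtfTensor(sim$recording, 20, order = 2)
  expect_equal(nSegments(short), 2)
  expect_error(bandAverage(short, c(8, 13))[, , 1:0], NA)
  # a 1-segment tensor is rejected by the t-test stage
  oneSeg <- new("DTFTensor", values = dtfValues(short)[, , , 1,
                                                       drop = FALSE],
                freqs = short@freqs, window = 20,
                labels = short@labels, orders = 2L, fs = 250)
  expect_error(significanceAdjacency(oneSeg), "insufficient segments")
})
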