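toyMatrix <- function() {
  m <- rbind(c(0.30, 0.10, 0.05),
             c(0.28, 0.12, 0.06),
             c(0.50, 0.11, 0.07),
             c(0.45, 0.40, 0.35))
  rownames(m) <- paste0("Ch", 1:4)
  m
}

test_that("gamma MLE recovers known shapes and handles degenerate input", {
  set.seed(41)
  x <- matrix(rgamma(600, shape = 4, scale = 0.05), 60, 10)
  fit <- fitVariancePdf(x)
  expect_lt(abs(fit$shape - 4) / 4, 0.15)
  expect_equal(fit$pk, (fit$shape - 1) / fit$rate)
  # chi-square with k df is Gamma(k/2, scale 2)
  y <- matrix(rchisq(2000, df = 4), 200, 10)
  fit2 <- fitVariancePdf(y)
  expect_lt(abs(fit2$shape - 2) / 2, 0.15)
  expect_lt(abs(1 / fit2$rate - 2) / 2, 0.15)
  # point mass and all-zero cases
  const <- matrix(0.3, 5, 10)
  expect_true(fitVariancePdf(const)$degenerate)
  expect_equal(fitVariancePdf(const)$pk, 0.3)
  expect_error(fitVariancePdf(matrix(0, 5, 10)), "degenerate")
})

test_that("the interval search equals the brute-force enumeration oracle", {
  vals <- toyMatrix()
  res <- varianceSearch(vals, threshold1 = 0.5)
  orc <- oracleVarianceSearch(vals, 1:3, res$pk, res$c, threshold1 = 0.5)
  expect_equal(res$selection$duration, orc$duration)
  expect_equal(res$selection$variance, orc$variance)
  expect_equal(res$interval, orc$interval)
  # randomized matrices up to 8 channels x 10 windows
  set.seed(42)
  for (rep in 1:25) {
    M <- sample(2:8, 1); W <- sample(3:10, 1)
    vals <- matrix(runif(M * W, 0, 1)^2, M, W)
    rownames(vals) <- paste0("Ch", seq_len(M))
    t1 <- runif(1, 0.3, 0.9); t2 <- runif(1, 0.2, 0.8)
    # some draws are unsatisfiable; both routes must then agree on empty
    res <- suppressWarnings(varianceSearch(vals, threshold1 = t1,
                                           threshold2 = t2))
    orc <- oracleVarianceSearch(vals, seq_len(W), res$pk, res$c,
                                threshold1 = t1, threshold2 = t2)
    expect_equal(res$selection$duration, orc$duration)
    expect_equal(res$selection$variance, orc$variance)
    expect_equal(res$iterations, orc$k)
  }
})

test_that("limit cases of the interval search behave as stated", {
  vals <- toyMatrix()
  # an interval spanning everything selects every channel at its
  # shortest qualifying duration
  wide <- varianceSearch(vals, c = 10, threshold1 = 0.5, threshold2 = 1)
  expect_equal(nrow(wide$selection), 4)
  expect_equal(sort(wide$selection$duration), c(1, 1, 1, 1))
  # impossible joint demand -> empty selection with a warning
  expect_warning(
    empty <- varianceSearch(vals, threshold1 = 1, threshold2 = 1e-6,
                            kMax = 20),
    "no qualifying")
  expect_equal(nrow(empty$selection), 0)
})

test_that("the percentage domain spans all channels at 100% and is monotone", {
  vals <- toyMatrix()
  d <- percentageDomain(vals, windowLengths = 1:3)
  expect_equal(unique(d$channelsAny[d$percentage == 100]), 4)
  # channel capture never decreases as the interval widens
  for (w in 1:3) {
    cw <- d$count[d$window == w][order(d$percentage[d$window == w])]
    expect_true(all(diff(cw) >= 0))
  }
  # exhaustive membership check per cell
  fit <- fitVariancePdf(vals)
  for (r in seq_len(nrow(d))) {
    manual <- sum(vals[, d$window[r]] >= d$lower[r] &
                    vals[, d$window[r]] <= d$upper[r])
    expect_equal(d$count[r], manual)
  }
  one <- percentageDomain(vals[1, , drop = FALSE], windowLengths = 1:3)
  expect_true(all(one$count[one$count > 0] == 1))
})

test_that("window selection prefers dominating and shorter durations", {
  # duration 2 dominates: its tight low-variance cluster sits at the
  # density peak while the other durations are diffuse and far away
  set.seed(43)
  vals <- cbind(runif(12, 0.5, 3.0),
                runif(12, 0.010, 0.020),
                runif(12, 0.4, 2.0))
  rownames(vals) <- paste0("Ch", 1:12)
  sel <- selectWindow(vals, windowLengths = 1:3)
  expect_equal(selectedWindow(sel), 2)
  # the exact qualifying percentage gathers the required channel count
  expect_gte(length(channelLabels(sel)), 6)
  expect_true(all(channelLabels(sel) %in% paste0("Ch", 1:12)))
  # exact tie between two durations -> the shorter wins
  tie <- cbind(c(0.1, 0.1, 0.5), c(0.1, 0.1, 0.5), c(0.9, 0.9, 0.9))
  st <- selectWindow(tie, threshold1 = 0.5, windowLengths = 1:3)
  expect_equal(selectedWindow(st), 1)
  # unreachable channel demand errors with the diagnostic table
  expect_error(selectWindow(toyMatrix(), threshold1 = 1.5,
                            windowLengths = 1:3), "no duration reaches")
})

test_that("piecewise-stationary recordings recover their 4 s timescale", {
  wins <- vapply(1:6, function(s) {
    sim <- simulatePiecewiseStationary(6, tau = 4, duration = 160,
                                       fs = 250, seed = 500 + s)
    K <- kurtosisVarianceMatrix(sim$recording)
    selectedWindow(selectWindow(K))
  }, numeric(1))
  expect_gte(mean(wins == 4), 0.8)
})

test_that("cohort aggregation reproduces the example selection table", {
  agg <- aggregateSelection(restingSelectionTable())
  expect_equal(agg$modalWindow, 4)
  expect_equal(agg$meanChannelPct, 69)
  expect_equal(agg$meanVariancePct, 41)
  # permutation invariance of the mode
  shuffled <- restingSelectionTable()[sample(12), ]
  expect_equal(aggregateSelection(shuffled)$modalWindow, 4)
  # single result: the mode is that window
  one <- aggregateSelection(restingSelectionTable()[1, , drop = FALSE])
  expect_equal(one$modalWindow, 5)
  expect_error(aggregateSelection(list()), "empty")
})
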