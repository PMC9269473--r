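# Independent oracles used to cross-check package computations.
# These are deliberately naive (loops, enumeration, closed forms) and
# share no code with the implementation.

# dominant frequency of a series by raw periodogram
oracleDominantFreq <- function(x, fs) {
  n <- length(x)
  P <- Mod(stats::fft(x - mean(x)))[seq_len(n %/% 2)]^2
  freqs <- (seq_len(n %/% 2) - 1) * fs / n
  freqs[which.max(P)]
}

# amplitude of a sinusoidal component at frequency f via projection
oracleAmplitudeAt <- function(x, fs, f) {
  n <- length(x)
  tt <- (seq_len(n) - 1) / fs
  2 * sqrt(mean(x * cos(2 * pi * f * tt))^2 +
             mean(x * sin(2 * pi * f * tt))^2)
}

# Brute-force variance-interval search: enumerate every interval width
# k*c on the grid, recompute membership and the stopping conditions
# from scratch with plain loops.
oracleVarianceSearch <- function(vals, windowLengths, pk, cstep,
                                 threshold1 = 0.5, threshold2 = 0.4,
                                 kMax = 200) {
  M <- nrow(vals)
  maxRef <- mean(apply(vals, 1, max))
  for (k in seq_len(kMax)) {
    lb <- pk - k * cstep
    hb <- pk + k * cstep
    chans <- c(); durs <- c(); vars <- c()
    for (ch in seq_len(M)) {
      best <- NA
      for (w in order(windowLengths)) {
        v <- vals[ch, w]
        if (v >= lb && v <= hb) { best <- w; break }
      }
      if (!is.na(best)) {
        chans <- c(chans, ch)
        durs <- c(durs, windowLengths[best])
        vars <- c(vars, vals[ch, best])
      }
    }
    if (length(chans) > threshold1 * M && mean(vars) <= threshold2 * maxRef) {
      ord <- order(vars, chans)
      return(list(channel = chans[ord], duration = unname(durs[ord]),
                  variance = unname(vars[ord]), interval = c(lb, hb),
                  k = k))
    }
  }
  list(channel = integer(), duration = numeric(), variance = numeric(),
       interval = NULL, k = kMax)
}

# Floyd-Warshall all-pairs shortest paths on a binary digraph
oracleDistances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && A[i, j] > 0) d[i, j] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracleIntegration <- function(A) {
  d <- oracleDistances(A)
  off <- row(d) != col(d)
  fin <- off & is.finite(d)
  list(charPathLength = if (any(fin)) mean(d[fin]) else NA_real_,
       globalEfficiency = mean(ifelse(is.finite(d[off]), 1 / d[off], 0)))
}

# Betweenness by explicit shortest-path counting (BFS per source with
# sigma accumulation), normalized by (N-1)(N-2).
oracleBetweenness <- function(A) {
  n <- nrow(A)
  if (n < 3) return(rep(0, n))
  d <- oracleDistances(A)
  # sigma[s, t]: number of shortest s->t paths, by DP over distance
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (len in 1:n) {
      for (t in seq_len(n)) {
        if (is.finite(d[s, t]) && d[s, t] == len) {
          acc <- 0
          for (u in seq_len(n)) {
            if (A[u, t] > 0 && d[s, u] == len - 1) acc <- acc + sigma[s, u]
          }
          sigma[s, t] <- acc
        }
      }
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v) next
      if (!is.finite(d[s, t])) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  bc / ((n - 1) * (n - 2))
}

# Fagiolo total clustering by enumerating ordered neighbor pairs
oracleClustering <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    tri <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      tri <- tri + (A[i, j] + A[j, i]) * (A[i, h] + A[h, i]) *
        (A[j, h] + A[h, j])
    }
    tri <- tri / 2
    dtot <- sum(A[i, ] + A[, i])
    dbi <- sum(A[i, ] * A[, i])
    denom <- dtot * (dtot - 1) - 2 * dbi
    out[i] <- if (denom > 0) tri / denom else 0
  }
  out
}

oracleLocalEfficiency <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which((A[i, ] + A[, i]) > 0)
    nb <- setdiff(nb, i)
    if (length(nb) < 2) return(0)
    oracleIntegration(A[nb, nb, drop = FALSE])$globalEfficiency
  }, numeric(1))
}

# enumerate all binary digraphs (no self-loops) on n nodes
allDigraphs <- function(n) {
  cells <- n * (n - 1)
  lapply(0:(2^cells - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(cells)]
    A <- matrix(0, n, n)
    A[row(A) != col(A)] <- bits
    A
  })
}

# compare all graph measures of a DirectedNetwork-equivalent binary
# adjacency against the oracles
expectGraphMatchesOracle <- function(A, tol = 1e-10) {
  W <- A * 0.5
  if (all(W == 0)) return(invisible(TRUE))
  net <- costThreshold(W, 100)
  b <- basicMeasures(net)
  expect_equal(b$nodes$inDegree, colSums(A), ignore_attr = TRUE)
  expect_equal(b$nodes$outDegree, rowSums(A), ignore_attr = TRUE)
  expect_equal(b$density, 100 * sum(A) / (nrow(A) * (nrow(A) - 1)))
  it <- integrationMeasures(net)
  or <- oracleIntegration(A)
  expect_equal(it$charPathLength, or$charPathLength, tolerance = tol)
  expect_equal(it$globalEfficiency, or$globalEfficiency, tolerance = tol)
  sg <- segregationMeasures(net)
  expect_equal(sg$clustering, oracleClustering(A), tolerance = tol,
               ignore_attr = TRUE)
  expect_equal(sg$localEfficiency, oracleLocalEfficiency(A),
               tolerance = tol, ignore_attr = TRUE)
  expect_equal(unname(betweennessCentrality(net)), oracleBetweenness(A),
               tolerance = tol)
  invisible(TRUE)
}
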