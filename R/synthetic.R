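#' @include AllClasses.R
NULL

.rlaplace <- function(n, sd = 1) {
  # difference of exponentials; variance 2b^2, excess kurtosis 3
  b <- sd / sqrt(2)
  stats::rexp(n, 1 / b) - stats::rexp(n, 1 / b)
}

.stabilize <- function(A, target = 0.95) {
  comp <- .companionMatrix(A)
  rad <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rad >= target) {
    f <- target / rad
    A <- lapply(seq_along(A), function(k) A[[k]] * f^k)
  }
  A
}

#' Simulate a recording from a known MVAR model
#'
#' Generates a stable Gaussian- (or Laplace-) innovation MVAR
#' realization with a known directed-coupling graph, for validating
#' connectivity recovery. Each channel carries a damped autoregressive
#' diagonal; the requested edges add off-diagonal coefficients at their
#' lags. If the requested coefficients are unstable the whole
#' coefficient set is spectral-radius rescaled to 0.95.
#'
#' @param nChannels number of channels M.
#' @param edges NULL (no coupling) or a `data.frame` with columns
#'   `from`, `to`, and optionally `lag` (default 1) and `coef`
#'   (default 0.4): source channel `from` drives sink `to`.
#' @param order MVAR order (>= max edge lag; default 1).
#' @param nSamples samples per channel.
#' @param fs sampling rate (Hz, default 250).
#' @param seed RNG seed for reproducibility.
#' @param innovations `"gaussian"` (default) or `"laplace"`.
#' @param diagCoef lag-1 self-coefficient per channel (default 0.5).
#' @param burnin samples discarded before recording (default 500).
#' @return A list with `recording` ([EEGRecording-class]) and `truth`
#'   (edge list, coefficient matrices, seed).
#' @examples
#' sim <- simulateMVAR(3, data.frame(from = 1, to = 2), nSamples = 1000,
#'                     seed = 1)
#' @export
simulateMVAR <- function(nChannels, edges = NULL, order = 1, nSamples,
                         fs = 250, seed = NULL,
                         innovations = c("gaussian", "laplace"),
                         diagCoef = 0.5, burnin = 500) {
  innovations <- match.arg(innovations)
  if (!is.null(seed)) set.seed(seed)
  M <- nChannels
  if (!is.null(edges)) {
    if (!all(c("from", "to") %in% names(edges))) {
      stop("'edges' needs columns 'from' and 'to'")
    }
    if (is.null(edges$lag)) edges$lag <- 1L
    if (is.null(edges$coef)) edges$coef <- 0.4
    order <- max(order, edges$lag)
  }
  A <- lapply(seq_len(order), function(k) matrix(0, M, M))
  diag(A[[1]]) <- diagCoef
  if (!is.null(edges)) {
    for (r in seq_len(nrow(edges))) {
      A[[edges$lag[r]]][edges$to[r], edges$from[r]] <- edges$coef[r]
    }
  }
  A <- .stabilize(A)
  p <- length(A)
  ntot <- nSamples + burnin
  innov <- switch(innovations,
                  gaussian = matrix(stats::rnorm(M * ntot), M, ntot),
                  laplace = matrix(.rlaplace(M * ntot), M, ntot))
  x <- matrix(0, M, ntot)
  x[, seq_len(p)] <- innov[, seq_len(p)]
  for (tt in (p + 1):ntot) {
    acc <- innov[, tt]
    for (k in seq_len(p)) acc <- acc + A[[k]] %*% x[, tt - k]
    x[, tt] <- acc
  }
  rec <- EEGRecording(x[, (burnin + 1):ntot, drop = FALSE], fs = fs)
  list(recording = rec,
       truth = list(edges = edges, A = A, order = p, seed = seed,
                    innovations = innovations))
}

#' Simulate a piecewise-stationary recording
#'
#' Channels are built from consecutive blocks of `tau` seconds drawn
#' from alternating regimes (cycled in order). Within a block samples
#' are i.i.d. from the regime's distribution, optionally AR(1)
#' filtered, so the signal is stationary below the timescale `tau` and
#' regime-switching above it. Windows that are aligned multiples of
#' `tau` see homogeneous segments (excess kurtosis near the regime's
#' own value), while misaligned longer windows mix regimes and inflate
#' both the kurtosis and its across-segment variance -- the structure
#' the window-selection algorithm is designed to detect.
#'
#' @param nChannels number of channels M.
#' @param tau regime block duration (seconds); the ground-truth
#'   stationarity timescale.
#' @param duration total duration (seconds), `>= tau`.
#' @param fs sampling rate (Hz, default 250).
#' @param regimes list of at least 2 regime descriptors, each a list
#'   with `sd` and optionally `dist` (`"gaussian"` or `"laplace"`) and
#'   `ar` (AR(1) coefficient). Default: Gaussian with sd 1 and 3.
#' @param seed RNG seed.
#' @return A list with `recording` and `truth` (tau, regimes, seed).
#' @export
simulatePiecewiseStationary <- function(nChannels, tau = 4, duration,
                                        fs = 250,
                                        regimes = list(list(sd = 1),
                                                       list(sd = 3)),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (tau > duration) stop("'tau' must not exceed 'duration'")
  if (length(regimes) < 2) {
    # a single regime is allowed for the stationary control case
    if (length(regimes) < 1) stop("at least one regime is required")
  }
  for (rg in regimes) {
    if (is.null(rg$sd) || rg$sd <= 0) stop("each regime needs a positive 'sd'")
  }
  spb <- as.integer(round(tau * fs))
  n <- as.integer(round(duration * fs))
  nblocks <- ceiling(n / spb)
  x <- matrix(0, nChannels, n)
  for (ch in seq_len(nChannels)) {
    sig <- numeric(0)
    for (b in seq_len(nblocks)) {
      rg <- regimes[[(b - 1) %% length(regimes) + 1]]
      dist <- if (is.null(rg$dist)) "gaussian" else rg$dist
      blk <- switch(dist,
                    gaussian = stats::rnorm(spb, sd = rg$sd),
                    laplace = .rlaplace(spb, sd = rg$sd),
                    stop("unknown regime distribution: ", dist))
      if (!is.null(rg$ar) && rg$ar != 0) {
        blk <- as.numeric(stats::filter(blk, rg$ar, method = "recursive"))
        blk <- blk * rg$sd / stats::sd(blk)
      }
      sig <- c(sig, blk)
    }
    x[ch, ] <- sig[seq_len(n)]
  }
  rec <- EEGRecording(x, fs = fs)
  list(recording = rec,
       truth = list(tau = tau, regimes = regimes, seed = seed))
}

#' Generate a paired-condition cohort fixture
#'
#' Builds `nSubjects` subjects with one R1 (open-eyes) and one R2
#' (closed-eyes) recording each, plus the cohort metadata table the
#' retention filter consumes. Raw durations, clean fractions and
#' channel counts are sampled within the given ranges; artifact
#' rejection itself is not simulated, so the clean duration simply
#' scales the raw one. Defaults mirror a high-density resting-state
#' acquisition (55-62 channels, 3-5 minute recordings); note that at
#' those sizes the recordings are large, so tests typically pass
#' smaller ranges and `fs`.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param durationRange raw-duration range in seconds (default
#'   `c(180, 330)`).
#' @param channelRange retained-channel-count range (default
#'   `c(55, 62)`).
#' @param cleanFractions NULL (sampled uniformly in `[0.15, 0.95]`) or
#'   a numeric matrix/data.frame `nSubjects x 2` of per-condition clean
#'   fractions.
#' @param fs sampling rate for the generated signals (Hz, default 250,
#'   the post-resampling rate).
#' @param tau stationarity timescale passed to the piecewise generator.
#' @param seed RNG seed.
#' @param makeRecordings generate the signal matrices (default TRUE);
#'   FALSE returns metadata only.
#' @return A list with `cohort` (metadata `data.frame` as accepted by
#'   [retentionFilter()]) and `recordings` (named list of
#'   [EEGRecording-class], clean-duration long), plus `seed`.
#' @export
cohortFixture <- function(nSubjects, durationRange = c(180, 330),
                          channelRange = c(55, 62), cleanFractions = NULL,
                          fs = 250, tau = 4, seed = NULL,
                          makeRecordings = TRUE) {
  stopifnot(nSubjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(cleanFractions)) {
    cleanFractions <- as.matrix(cleanFractions)
    stopifnot(nrow(cleanFractions) == nSubjects, ncol(cleanFractions) == 2)
  } else {
    cleanFractions <- matrix(stats::runif(2 * nSubjects, 0.15, 0.95),
                             nSubjects, 2)
  }
  rows <- list(); recs <- list()
  for (s in seq_len(nSubjects)) {
    sid <- paste0("S", s)
    for (ci in 1:2) {
      cond <- c("R1", "R2")[ci]
      raw <- round(stats::runif(1, durationRange[1], durationRange[2]))
      frac <- cleanFractions[s, ci]
      clean <- round(raw * frac)
      chn <- as.integer(round(stats::runif(1, channelRange[1],
                                           channelRange[2])))
      rows[[length(rows) + 1]] <- data.frame(
        subject = sid, condition = cond, raw_s = raw, clean_s = clean,
        channels = chn, stringsAsFactors = FALSE)
      if (makeRecordings && clean >= tau) {
        sim <- simulatePiecewiseStationary(chn, tau = tau,
                                           duration = clean, fs = fs)
        rec <- sim$recording
        rec@subjectId <- sid
        rec@condition <- cond
        recs[[paste(sid, cond, sep = "_")]] <- rec
      }
    }
  }
  list(cohort = do.call(rbind, rows), recordings = recs, seed = seed)
}
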