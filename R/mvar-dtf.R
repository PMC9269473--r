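#' @include AllClasses.R
NULL

#' Fit a multivariate autoregressive model by least squares
#'
#' Ordinary least squares on the stacked lag regression of a
#' channels-by-samples block (channels demeaned first). The residual
#' covariance uses denominator `n - p`. Stability is checked on the
#' companion matrix; an unstable fit is returned with a warning so
#' callers can exclude the segment.
#'
#' @param x numeric matrix, channels (M) by samples (n), or an
#'   [EEGRecording-class].
#' @param order model order p; requires `n > p * M + 1`.
#' @return An [MVARModel-class] object.
#' @export
fitMVAR <- function(x, order) {
  if (is(x, "EEGRecording")) x <- x@data
  x <- as.matrix(x)
  M <- nrow(x); n <- ncol(x)
  p <- as.integer(order)
  stopifnot(p >= 1)
  if (n <= p * M + 1) {
    stop("underdetermined: need more samples than p*M + 1 (n=", n,
         ", p=", p, ", M=", M, ")")
  }
  x <- x - rowMeans(x)
  Y <- t(x[, (p + 1):n, drop = FALSE])                  # (n-p) x M
  X <- matrix(0, n - p, p * M)
  for (k in seq_len(p)) {
    X[, ((k - 1) * M + 1):(k * M)] <- t(x[, (p + 1 - k):(n - k), drop = FALSE])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient regressor matrix")
  B <- qr.coef(qrX, Y)                                  # (p*M) x M
  res <- Y - X %*% B
  Sigma <- crossprod(res) / (n - p)
  A <- lapply(seq_len(p), function(k) {
    t(B[((k - 1) * M + 1):(k * M), , drop = FALSE])     # M x M, lag k
  })
  comp <- .companionMatrix(A)
  stable <- max(Mod(eigen(comp, only.values = TRUE)$values)) < 1
  if (!stable) warning("fitted MVAR model is unstable")
  new("MVARModel", A = A, Sigma = (Sigma + t(Sigma)) / 2,
      order = p, nobs = as.integer(n), stable = stable)
}

.companionMatrix <- function(A) {
  p <- length(A); M <- nrow(A[[1]])
  comp <- matrix(0, p * M, p * M)
  comp[seq_len(M), ] <- do.call(cbind, A)
  if (p > 1) {
    comp[(M + 1):(p * M), seq_len((p - 1) * M)] <- diag((p - 1) * M)
  }
  comp
}

#' Select the MVAR order by information criterion
#'
#' Fits orders `1..orderMax` and minimizes AIC or BIC computed from the
#' log-determinant of the maximum-likelihood residual covariance, with
#' penalty `p * M^2` parameters. `criterion = "fixed"` bypasses the
#' scan and returns `order`.
#'
#' @param x numeric matrix (M x n) or [EEGRecording-class].
#' @param orderMax largest order scanned (default 12).
#' @param criterion `"bic"` (default), `"aic"` or `"fixed"`.
#' @param order the order returned when `criterion = "fixed"`.
#' @return The selected order (integer).
#' @export
selectOrder <- function(x, orderMax = 12, criterion = c("bic", "aic", "fixed"),
                        order = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "fixed") {
    if (is.null(order)) stop("criterion 'fixed' requires 'order'")
    return(as.integer(order))
  }
  if (is(x, "EEGRecording")) x <- x@data
  M <- nrow(x); n <- ncol(x)
  stopifnot(orderMax >= 1)
  ic <- rep(Inf, orderMax)
  for (p in seq_len(orderMax)) {
    if (n <= p * M + 1) break
    fit <- suppressWarnings(fitMVAR(x, p))
    neff <- n - p
    ld <- determinant(fit@Sigma, logarithm = TRUE)$modulus
    pen <- if (criterion == "aic") 2 else log(neff)
    ic[p] <- as.numeric(ld) + pen * p * M^2 / neff
  }
  if (all(!is.finite(ic))) stop("no order could be fitted")
  which.min(ic)
}

#' Spectral transfer matrix of an MVAR model
#'
#' `H(f) = [I - sum_k A_k exp(-i 2 pi f k / fs)]^-1`, evaluated at each
#' requested frequency. `H` carries the spectral and phase information
#' from which the directed transfer function is computed.
#'
#' @param model an [MVARModel-class] object.
#' @param freqs frequencies (Hz).
#' @param fs sampling rate (Hz).
#' @return Complex array M x M x length(freqs).
#' @export
transferMatrix <- function(model, freqs, fs) {
  stopifnot(is(model, "MVARModel"))
  M <- nrow(model@Sigma)
  H <- array(complex(real = 0), c(M, M, length(freqs)))
  I <- diag(M)
  for (fi in seq_along(freqs)) {
    Af <- I + 0i
    for (k in seq_along(model@A)) {
      Af <- Af - model@A[[k]] * exp(-2i * pi * freqs[fi] * k / fs)
    }
    Hf <- tryCatch(solve(Af), error = function(e) {
      stop("transfer matrix singular at ", freqs[fi], " Hz")
    })
    H[, , fi] <- Hf
  }
  H
}

#' Squared directed transfer function at one frequency
#'
#' Row-normalized squared magnitude of the transfer matrix:
#' `DTF[i, j] = |H_ij|^2 / sum_m |H_im|^2`, the fraction of the total
#' spectral inflow into sink `i` contributed by source `j`. Every row
#' sums to one.
#'
#' @param H complex (or numeric) M x M transfer matrix at one
#'   frequency.
#' @return Numeric M x M matrix with unit row sums.
#' @export
dtf <- function(H) {
  P <- Mod(H)^2
  denom <- rowSums(P)
  if (any(denom <= 0 | !is.finite(denom))) {
    stop("zero or non-finite inflow row in transfer matrix")
  }
  P / denom
}

#' Segment-wise DTF tensor of a recording
#'
#' Cuts the recording into non-overlapping segments of the selected
#' window length, fits one MVAR model per segment, and evaluates the
#' squared DTF on the 1 Hz grid from 1 Hz to the Nyquist frequency.
#' Segments with unstable fits are excluded (their indices are kept in
#' the result) without shifting the indices of the remaining segments.
#'
#' @param rec a preprocessed [EEGRecording-class] object.
#' @param window segment duration tW (seconds); at least 2 segments
#'   must fit in the recording.
#' @param order fixed MVAR order; when NULL the order is chosen per
#'   segment by `criterion` up to `orderMax`.
#' @param orderMax,criterion passed to [selectOrder()].
#' @param freqs frequency grid (Hz); default `1:(fs/2)` in 1 Hz steps.
#' @return A [DTFTensor-class] object (M x M x F x S).
#' @export
dtfTensor <- function(rec, window, order = NULL, orderMax = 12,
                      criterion = "bic", freqs = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  M <- nrow(rec@data)
  spseg <- as.integer(round(window * fs))
  S <- ncol(rec@data) %/% spseg
  if (S < 2) stop("insufficient segments: floor(t/tW) must be >= 2")
  if (is.null(freqs)) freqs <- seq_len(floor(fs / 2))
  vals <- array(NA_real_, c(M, M, length(freqs), S))
  orders <- integer(S)
  keep <- logical(S)
  for (s in seq_len(S)) {
    block <- rec@data[, ((s - 1) * spseg + 1):(s * spseg), drop = FALSE]
    p <- if (is.null(order)) {
      selectOrder(block, orderMax = orderMax, criterion = criterion)
    } else as.integer(order)
    fit <- withCallingHandlers(
      fitMVAR(block, p),
      warning = function(w) invokeRestart("muffleWarning"))
    orders[s] <- p
    if (!fit@stable) {
      message("segment ", s, " excluded: unstable MVAR fit")
      next
    }
    H <- transferMatrix(fit, freqs, fs)
    for (fi in seq_along(freqs)) vals[, , fi, s] <- dtf(H[, , fi])
    keep[s] <- TRUE
  }
  if (!any(keep)) stop("all segments produced unstable fits")
  new("DTFTensor",
      values = vals[, , , keep, drop = FALSE],
      freqs = as.numeric(freqs), window = as.numeric(window),
      labels = rec@labels, orders = orders[keep],
      excluded = which(!keep), fs = fs)
}

#' Band-average a DTF tensor
#'
#' Elementwise arithmetic mean of the DTF values over the inclusive
#' frequency band, per segment. The default band is the alpha rhythm
#' (8--13 Hz), the dominant resting-state band.
#'
#' @param tensor a [DTFTensor-class] object.
#' @param band two-element numeric, band limits in Hz (inclusive).
#' @return Numeric array M x M x S of band-averaged DTF values.
#' @export
bandAverage <- function(tensor, band = c(8, 13)) {
  stopifnot(is(tensor, "DTFTensor"))
  bins <- which(tensor@freqs >= band[1] & tensor@freqs <= band[2])
  if (!length(bins)) stop("empty band: no frequency bins in [",
                          band[1], ", ", band[2], "] Hz")
  out <- apply(tensor@values[, , bins, , drop = FALSE], c(1, 2, 4), mean)
  dimnames(out) <- list(tensor@labels, tensor@labels, NULL)
  out
}

# Phase-randomized surrogate of one channel: preserves the amplitude
# spectrum, destroys cross-channel phase relations.
.phaseRandomize <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  half <- floor((n - 1) / 2)
  if (half >= 1) {
    ph <- stats::runif(half, 0, 2 * pi)
    idx <- 2:(half + 1)
    X[idx] <- Mod(X[idx]) * exp(1i * ph)
    X[n + 2 - idx] <- Conj(X[idx])
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Significance-masked band adjacency
#'
#' For every directed off-diagonal edge, a one-sample, one-sided
#' t-test asks whether the S across-segment band-averaged DTF values
#' exceed a null inflow level. Two nulls are available: `"uniform"`
#' tests against `1/M`, the squared-DTF level when all sources feed a
#' sink equally (a conservative reference, since estimated off-diagonal
#' DTF under no coupling sits well below it); `"surrogate"` tests
#' against the edge-specific mean DTF of phase-randomized copies of the
#' recording, which calibrates the test to the no-coupling
#' distribution of the estimator itself.
#'
#' @param tensor a [DTFTensor-class] object with at least 2 segments.
#' @param band frequency band (Hz, inclusive; default alpha 8--13).
#' @param alpha significance level (default 0.05).
#' @param null `"uniform"` (default) or `"surrogate"`.
#' @param recording the [EEGRecording-class] the tensor came from;
#'   required for the surrogate null.
#' @param nSurrogates number of phase-randomized copies (default 20).
#' @param correct `"none"` (default, raw p < alpha) or `"BH"` for
#'   Benjamini-Hochberg adjustment across edges.
#' @param transform scale of the t-test: `"cuberoot"` (default)
#'   applies the Wilson-Hilferty cube-root normalizing transform to
#'   the chi-square-like DTF values (and to the null level) so the
#'   one-sided t-test is approximately calibrated; `"none"` tests on
#'   the raw scale, which is conservative under right skew.
#' @return A [BandAdjacency-class] object.
#' @export
significanceAdjacency <- function(tensor, band = c(8, 13), alpha = 0.05,
                                  null = c("uniform", "surrogate"),
                                  recording = NULL, nSurrogates = 20,
                                  correct = c("none", "BH"),
                                  transform = c("cuberoot", "none")) {
  stopifnot(is(tensor, "DTFTensor"))
  null <- match.arg(null)
  correct <- match.arg(correct)
  transform <- match.arg(transform)
  g <- if (transform == "cuberoot") function(x) x^(1 / 3) else identity
  bandVals <- bandAverage(tensor, band)
  M <- dim(bandVals)[1]
  S <- dim(bandVals)[3]
  if (S < 2) stop("insufficient segments: need >= 2 for the t-test")
  if (null == "uniform") {
    nullLevel <- matrix(g(1 / M), M, M)
  } else {
    if (is.null(recording)) {
      stop("surrogate null requires the source recording")
    }
    pFix <- as.integer(round(stats::median(tensor@orders)))
    bandFreqs <- tensor@freqs[tensor@freqs >= band[1] &
                                tensor@freqs <= band[2]]
    acc <- matrix(0, M, M)
    for (b in seq_len(nSurrogates)) {
      surData <- t(apply(recording@data, 1, .phaseRandomize))
      sur <- EEGRecording(surData, fs = recording@fs,
                          labels = recording@labels)
      # surrogates are only needed inside the band
      st <- dtfTensor(sur, tensor@window, order = pFix, freqs = bandFreqs)
      acc <- acc + apply(g(bandAverage(st, band)), c(1, 2), mean)
    }
    nullLevel <- acc / nSurrogates
  }
  pvals <- matrix(NA_real_, M, M, dimnames = list(tensor@labels,
                                                  tensor@labels))
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i == j) next
      v <- g(bandVals[i, j, ])
      if (stats::sd(v) == 0) {
        pvals[i, j] <- if (mean(v) > nullLevel[i, j]) 0 else 1
        message("edge ", j, "->", i, ": zero variance across segments")
      } else {
        pvals[i, j] <- stats::t.test(v, mu = nullLevel[i, j],
                                     alternative = "greater")$p.value
      }
    }
  }
  padj <- pvals
  if (correct == "BH") {
    off <- !is.na(pvals)
    padj[off] <- stats::p.adjust(pvals[off], method = "BH")
  }
  mask <- !is.na(padj) & padj < alpha
  meanMat <- apply(bandVals, c(1, 2), mean)
  dimnames(meanMat) <- list(tensor@labels, tensor@labels)
  new("BandAdjacency", band = as.numeric(band), mean = meanMat,
      pvalues = pvals, mask = mask, alpha = alpha, null = null)
}
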