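#' @include AllClasses.R
NULL

#' Split a channel into non-overlapping segments
#'
#' Builds the segment matrix for one channel at window duration
#' `i * windowLength` seconds: `floor(t / w)` rows, each holding one
#' chronologically ordered segment of `w * fs` samples. Trailing
#' samples that do not fill a whole segment are dropped. Row `r`
#' (1-based) starts at sample `(r - 1) * w * fs + 1`.
#'
#' @param x numeric vector, single-channel series.
#' @param fs sampling rate (Hz).
#' @param windowLength basis window duration W_L (seconds, default 1).
#' @param i window multiple (segment duration is `i * windowLength`).
#' @return Numeric matrix of segments (rows) by samples (columns).
#' @examples
#' segmentSignal(rnorm(2500), fs = 250, windowLength = 1, i = 5)
#' @export
segmentSignal <- function(x, fs, windowLength = 1, i = 1) {
  stopifnot(i >= 1, windowLength > 0, fs > 0)
  spseg <- as.integer(round(i * windowLength * fs))
  nseg <- length(x) %/% spseg
  if (nseg < 1) {
    stop("signal shorter than one segment of ", i * windowLength, " s")
  }
  matrix(x[seq_len(nseg * spseg)], nrow = nseg, ncol = spseg, byrow = TRUE)
}

#' Excess kurtosis of a segment
#'
#' Population-moment estimator of the fourth standardized central
#' moment minus 3: `mean((x - m)^4) / mean((x - m)^2)^2 - 3`. Zero for
#' a Gaussian sample in expectation, so the value scores a segment's
#' departure from the Gaussian (strictly stationary) reference. A
#' small-sample bias-corrected variant (the G2 estimator) is available
#' via `biasCorrected = TRUE`.
#'
#' @param x numeric vector of at least 4 samples with positive
#'   variance.
#' @param biasCorrected use the unbiased-under-normality G2 estimator
#'   instead of the plain moment ratio (default FALSE).
#' @return Excess kurtosis (scalar). Invariant under affine maps
#'   `x -> a * x + b`, `a != 0`.
#' @examples
#' kurtosisExcess(rep(c(1, -1), 50))  # exactly -2
#' @export
kurtosisExcess <- function(x, biasCorrected = FALSE) {
  n <- length(x)
  if (n < 4) stop("segment must hold at least 4 samples")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= 0 || !is.finite(m2)) stop("degenerate segment: zero variance")
  k <- mean(xc^4) / m2^2 - 3
  if (biasCorrected) {
    k <- ((n + 1) * k + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  k
}

#' Excess-kurtosis profiles over iterative segmentation
#'
#' Segments `x` at every window multiple `i = 1..nWindows` of the basis
#' window and computes the excess kurtosis of each segment, yielding
#' one kurtosis vector per duration (length `floor(t / (i * W_L))`).
#' These profiles trace how short-time Gaussianity evolves along the
#' recording at each temporal scale.
#'
#' @param x numeric vector, single-channel series.
#' @param fs sampling rate (Hz).
#' @param windowLength basis window W_L (seconds, default 1).
#' @param nWindows number of segmentation iterations N_w (default 10;
#'   the longest duration examined is `nWindows * windowLength`).
#' @param biasCorrected passed to [kurtosisExcess()].
#' @return A list of class `"kurtosisProfile"` with elements `profiles`
#'   (list of numeric vectors), `windowLengths`, `basisWindow`, `fs`.
#' @export
kurtosisProfile <- function(x, fs, windowLength = 1, nWindows = 10,
                            biasCorrected = FALSE) {
  stopifnot(nWindows >= 1)
  profiles <- vector("list", nWindows)
  for (i in seq_len(nWindows)) {
    seg <- segmentSignal(x, fs, windowLength, i)
    profiles[[i]] <- vapply(seq_len(nrow(seg)), function(r) {
      tryCatch(kurtosisExcess(seg[r, ], biasCorrected),
               error = function(e) {
                 stop(sprintf("degenerate segment at i=%d, segment %d: %s",
                              i, r, conditionMessage(e)), call. = FALSE)
               })
    }, numeric(1))
  }
  structure(list(profiles = profiles,
                 windowLengths = seq_len(nWindows) * windowLength,
                 basisWindow = windowLength, fs = fs),
            class = "kurtosisProfile")
}

#' Interpolate kurtosis profiles onto a common grid
#'
#' Kurtosis vectors have duration-dependent lengths `floor(t / w_i)`;
#' to compare or pool them (e.g. to estimate a per-channel kurtosis
#' density) each vector is linearly interpolated onto the finest grid,
#' the one of the basis window. Endpoints are preserved; a
#' single-segment vector becomes a constant row.
#'
#' @param profile a `"kurtosisProfile"` from [kurtosisProfile()].
#' @return Numeric matrix, `nWindows` rows by `floor(t / W_L)` columns.
#' @export
interpolateProfiles <- function(profile) {
  stopifnot(inherits(profile, "kurtosisProfile"))
  target <- length(profile$profiles[[1]])
  out <- matrix(NA_real_, length(profile$profiles), target)
  for (i in seq_along(profile$profiles)) {
    v <- profile$profiles[[i]]
    if (length(v) == 1) {
      out[i, ] <- v
    } else if (length(v) == target) {
      out[i, ] <- v
    } else {
      out[i, ] <- stats::approx(seq(0, 1, length.out = length(v)), v,
                                xout = seq(0, 1, length.out = target))$y
    }
  }
  rownames(out) <- sprintf("w_l=%gs", profile$windowLengths)
  out
}

# population variance (denominator n)
.popVar <- function(v) mean((v - mean(v))^2)

#' Kurtosis-variance matrix of a recording
#'
#' For every channel and window multiple, the variance (denominator n)
#' of the uninterpolated excess-kurtosis vector collapses each profile
#' to a single dispersion score. The resulting channels-by-multiples
#' matrix is the search domain of the window-selection algorithm: a
#' small entry means the channel's short-time Gaussianity is stable
#' across the recording at that segment duration.
#'
#' @param rec an [EEGRecording-class] object.
#' @param windowLength basis window W_L (seconds, default 1).
#' @param nWindows number of window multiples N_w (default 10).
#' @param biasCorrected passed to [kurtosisExcess()].
#' @return A [KurtosisVariance-class] object (M x N_w).
#' @export
kurtosisVarianceMatrix <- function(rec, windowLength = 1, nWindows = 10,
                                   biasCorrected = FALSE) {
  stopifnot(is(rec, "EEGRecording"))
  M <- nrow(rec@data)
  values <- matrix(NA_real_, M, nWindows)
  for (ch in seq_len(M)) {
    prof <- tryCatch(
      kurtosisProfile(rec@data[ch, ], rec@fs, windowLength, nWindows,
                      biasCorrected),
      error = function(e) {
        stop(sprintf("channel %s: %s", rec@labels[ch],
                     conditionMessage(e)), call. = FALSE)
      })
    values[ch, ] <- vapply(prof$profiles, .popVar, numeric(1))
  }
  rownames(values) <- rec@labels
  KurtosisVariance(values, seq_len(nWindows) * windowLength, windowLength)
}

#' Write / read a kurtosis-variance matrix as a delimited table
#'
#' Channel labels as row names, `w_l=<seconds>s` column names.
#'
#' @param K a [KurtosisVariance-class] object.
#' @param path output (input) path.
#' @return `path` invisibly; `readKurtosisVariance` returns the object.
#' @export
writeKurtosisVariance <- function(K, path) {
  stopifnot(is(K, "KurtosisVariance"))
  utils::write.csv(as.data.frame(K@values), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeKurtosisVariance
#' @export
readKurtosisVariance <- function(path) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  w <- as.numeric(sub("^w_l=([0-9.]+)s$", "\\1", colnames(tab)))
  if (any(is.na(w))) stop("column names must follow 'w_l=<seconds>s'")
  KurtosisVariance(as.matrix(tab), w, min(w))
}
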