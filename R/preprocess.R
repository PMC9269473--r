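#' @include AllClasses.R
NULL

# Kaiser-window FIR design. Classical formulas: beta from the target
# stopband attenuation A (dB), tap count from A and the normalized
# transition width. Returns odd-length (type I) coefficients so the
# group delay is an integer number of samples.
.kaiserBeta <- function(A) {
  if (A > 50) 0.1102 * (A - 8.7)
  else if (A >= 21) 0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
  else 0
}

.kaiserTaps <- function(A, transitionHz, fs) {
  dw <- 2 * pi * transitionHz / fs
  n <- ceiling((A - 7.95) / (2.285 * dw))
  if (n %% 2 == 1) n <- n + 1           # even order -> odd length
  as.integer(n)
}

.designKaiserFIR <- function(band, fs, type = c("low", "pass"),
                             stopbandDb = 60, transitionHz = 1) {
  type <- match.arg(type)
  beta <- .kaiserBeta(stopbandDb)
  n <- .kaiserTaps(stopbandDb, transitionHz, fs)
  w <- band / (fs / 2)
  if (any(w <= 0 & type == "pass") || any(w >= 1)) {
    stop("band edges must lie strictly inside (0, fs/2)")
  }
  signal::fir1(n, w, type, signal::kaiser(n + 1, beta))
}

# Zero-phase application of a linear-phase FIR: reflect-pad both ends,
# FFT convolution, compensate the (ntaps-1)/2 group delay.
.applyFIRZeroPhase <- function(x, b) {
  nb <- length(b)
  half <- (nb - 1) %/% 2
  npad <- min(length(x) - 1L, nb)
  # even reflection: preserves the local mean at the boundaries, so a
  # stopband DC null is not polluted by pad discontinuities
  head_pad <- x[(npad + 1):2]
  tail_pad <- x[(length(x) - 1):(length(x) - npad)]
  xp <- c(head_pad, x, tail_pad)
  nfft <- stats::nextn(length(xp) + nb - 1, 2)
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, nfft - length(xp)))) *
                       stats::fft(c(b, rep(0, nfft - nb))), inverse = TRUE)) / nfft
  y[(npad + half + 1):(npad + half + length(x))]
}

#' Resample a recording to a lower rate
#'
#' Anti-alias filtered polyphase resampling. The signal is upsampled by
#' the rational factor's numerator where needed, low-pass filtered with
#' a zero-phase Kaiser FIR cut at `cutoffFactor` times the target
#' Nyquist frequency, and decimated. The canonical EEG use is the
#' reduction from a 1000 Hz acquisition rate to 250 Hz before
#' connectivity analysis.
#'
#' @param rec an [EEGRecording-class] object.
#' @param targetFs target sampling rate (Hz), strictly below the
#'   current rate and rationally related to it.
#' @param cutoffFactor anti-alias cutoff as a fraction of the target
#'   Nyquist (default 0.9).
#' @param stopbandDb stopband attenuation of the anti-alias filter (dB).
#' @return The resampled [EEGRecording-class].
#' @export
resampleRecording <- function(rec, targetFs, cutoffFactor = 0.9,
                              stopbandDb = 60) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  if (targetFs >= fs) stop("target rate must be below the current rate")
  ratio <- targetFs / fs
  up <- NA_integer_
  for (den in 1:512) {
    num <- ratio * den
    if (abs(num - round(num)) < 1e-9) { up <- as.integer(round(num)); break }
  }
  if (is.na(up)) stop("fs / targetFs must be rational (denominator <= 512)")
  down <- den
  n <- ncol(rec@data)
  interFs <- fs * up
  cutoff <- cutoffFactor * targetFs / 2
  transition <- (1 - cutoffFactor) * targetFs  # cutoff .. target Nyquist
  b <- .designKaiserFIR(cutoff, interFs, "low", stopbandDb, transition)
  out <- matrix(0, nrow(rec@data), length(seq(1, n * up, by = down)))
  for (ch in seq_len(nrow(rec@data))) {
    x <- rec@data[ch, ]
    if (up > 1) {
      xi <- numeric(n * up)
      xi[seq(1, n * up, by = up)] <- x * up
    } else xi <- x
    y <- .applyFIRZeroPhase(xi, b)
    out[ch, ] <- y[seq(1, length(y), by = down)]
  }
  EEGRecording(out, fs = targetFs, labels = rec@labels,
               subjectId = rec@subjectId, condition = rec@condition)
}

#' Band-pass filter a recording (Kaiser-window FIR, zero phase)
#'
#' Zero-phase band-pass filtering with a linear-phase FIR designed with
#' a Kaiser window. Zero-phase application matters here: segment-wise
#' kurtosis downstream must not be distorted by group delay. The
#' default 0.5--50 Hz band removes DC/drift and line-frequency residue
#' while keeping all conventional EEG rhythms.
#'
#' @param rec an [EEGRecording-class] object.
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @param stopbandDb stopband attenuation (dB, default 60).
#' @param transitionHz transition width at both edges (Hz, default 1).
#' @return The filtered [EEGRecording-class].
#' @export
bandpassRecording <- function(rec, lo = 0.5, hi = 50, stopbandDb = 60,
                              transitionHz = 1) {
  stopifnot(is(rec, "EEGRecording"))
  if (!(lo > 0 && lo < hi && hi < rec@fs / 2)) {
    stop("invalid band edges: need 0 < lo < hi < fs/2")
  }
  # the low-edge transition must not bleed across 0 Hz, or DC would
  # escape the stopband; cap it at the edge frequency itself
  effTrans <- min(transitionHz, lo)
  b <- .designKaiserFIR(c(lo, hi), rec@fs, "pass", stopbandDb, effTrans)
  out <- rec@data
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- .applyFIRZeroPhase(rec@data[ch, ], b)
  }
  EEGRecording(out, fs = rec@fs, labels = rec@labels,
               subjectId = rec@subjectId, condition = rec@condition)
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels,
#' so that the across-channel mean is zero at each time point. The
#' operation is idempotent.
#'
#' @param rec an [EEGRecording-class] object with at least two channels.
#' @return The re-referenced [EEGRecording-class].
#' @export
commonAverageReference <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (nrow(rec@data) < 2) stop("common-average reference needs >= 2 channels")
  out <- sweep(rec@data, 2, colMeans(rec@data))
  EEGRecording(out, fs = rec@fs, labels = rec@labels,
               subjectId = rec@subjectId, condition = rec@condition)
}

#' Full digital-conditioning chain
#'
#' Applies, in order: resampling to `targetFs` (skipped when the
#' recording is already at or below that rate), Kaiser FIR band-pass
#' filtering, and common-average referencing. This is the conditioning
#' applied to every recording before segmentation and connectivity.
#'
#' @param rec an [EEGRecording-class] object.
#' @param targetFs target sampling rate (Hz, default 250).
#' @param band band-pass edges in Hz (default `c(0.5, 50)`).
#' @param car apply common-average referencing (default TRUE).
#' @param ... passed on to [resampleRecording()] and
#'   [bandpassRecording()].
#' @return The conditioned [EEGRecording-class].
#' @export
preprocessRecording <- function(rec, targetFs = 250, band = c(0.5, 50),
                                car = TRUE, ...) {
  stopifnot(is(rec, "EEGRecording"))
  if (rec@fs > targetFs) rec <- resampleRecording(rec, targetFs, ...)
  rec <- bandpassRecording(rec, band[1], band[2])
  if (car) rec <- commonAverageReference(rec)
  if (any(!is.finite(rec@data))) stop("non-finite samples after preprocessing")
  rec
}
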