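#' @import methods
NULL

#' EEGRecording: a multichannel EEG recording
#'
#' Container for a channels-by-samples matrix of EEG potentials
#' (microvolts) together with its sampling rate, channel labels and
#' subject/condition metadata. Conditions follow the resting-state
#' convention \code{"R1"} (open eyes) and \code{"R2"} (closed eyes);
#' any other tag is accepted but the two-condition cohort helpers
#' expect R1/R2.
#'
#' @slot data numeric matrix, channels (rows) by samples (columns).
#' @slot fs sampling rate in Hz.
#' @slot labels character vector of unique channel names (10-20 system
#'   strings for scalp EEG).
#' @slot subjectId subject identifier.
#' @slot condition condition tag, e.g. \code{"R1"} or \code{"R2"}.
#'
#' @seealso [EEGRecording()] for the user-facing constructor,
#'   [readRecording()] to read from disk.
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    labels = "character",
    subjectId = "character",
    condition = "character"
  ),
  prototype(
    fs = NA_real_,
    subjectId = NA_character_,
    condition = NA_character_
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) {
    msg <- c(msg, "'data' must be a numeric matrix")
  }
  if (nrow(object@data) < 1) {
    msg <- c(msg, "recording must contain at least one channel")
  }
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0) {
    msg <- c(msg, "'fs' must be a single positive number")
  }
  if (length(object@labels) != nrow(object@data)) {
    msg <- c(msg, "one label per channel is required")
  }
  if (anyDuplicated(object@labels)) {
    msg <- c(msg, "channel labels must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data numeric matrix, channels by samples. A plain vector is
#'   treated as a single channel.
#' @param fs sampling rate (Hz).
#' @param labels channel names; defaults to \code{Ch1..ChM}.
#' @param subjectId subject identifier string.
#' @param condition condition tag (\code{"R1"} open eyes, \code{"R2"}
#'   closed eyes, or any other string).
#'
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(500), nrow = 2), fs = 250)
#' duration(rec)
#' @export
EEGRecording <- function(data, fs, labels = NULL, subjectId = NA_character_,
                         condition = NA_character_) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  storage.mode(data) <- "double"
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(data))) rownames(data) else
      paste0("Ch", seq_len(nrow(data)))
  }
  rownames(data) <- labels
  new("EEGRecording", data = data, fs = as.numeric(fs),
      labels = as.character(labels),
      subjectId = as.character(subjectId),
      condition = as.character(condition))
}

#' KurtosisVariance: the kurtosis-variance search domain
#'
#' Channels-by-window-multiples matrix of kurtosis variances. Entry
#' (chn, i) is the variance, across segments, of the excess-kurtosis
#' profile of channel chn computed at window duration i * basisWindow.
#' This matrix is the search domain of the window-length selection
#' algorithm.
#'
#' @slot values numeric matrix, channels by window multiples; all
#'   entries non-negative and finite.
#' @slot windowLengths candidate segment durations (seconds), one per
#'   column.
#' @slot basisWindow the elemental window duration W_L (seconds).
#'
#' @seealso [kurtosisVarianceMatrix()], [selectWindow()].
#' @exportClass KurtosisVariance
setClass("KurtosisVariance",
  representation(
    values = "matrix",
    windowLengths = "numeric",
    basisWindow = "numeric"
  )
)

setValidity("KurtosisVariance", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@windowLengths)) {
    msg <- c(msg, "one window length per column is required")
  }
  if (any(!is.finite(object@values))) {
    msg <- c(msg, "kurtosis variances must be finite")
  }
  if (any(object@values < 0)) {
    msg <- c(msg, "kurtosis variances must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

KurtosisVariance <- function(values, windowLengths, basisWindow) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("Ch", seq_len(nrow(values)))
  }
  colnames(values) <- sprintf("w_l=%gs", windowLengths)
  new("KurtosisVariance", values = values,
      windowLengths = as.numeric(windowLengths),
      basisWindow = as.numeric(basisWindow))
}

#' WindowSelection: result of segment-length selection for one recording
#'
#' @slot window selected segment duration (seconds).
#' @slot interval lower/upper kurtosis-variance limits of the accepted
#'   search interval.
#' @slot variancePct percentage of the peak-anchored variance span used
#'   by the accepted interval.
#' @slot channels labels of the channels sharing the selected window's
#'   stationarity range.
#' @slot channelPct retained channels as a rounded percentage of all
#'   channels.
#' @slot domain the percentage-threshold domain table (long format; one
#'   row per percentage x duration cell) used for the selection.
#' @slot subjectId,condition provenance copied from the recording, when
#'   known.
#' @exportClass WindowSelection
setClass("WindowSelection",
  representation(
    window = "numeric",
    interval = "numeric",
    variancePct = "numeric",
    channels = "character",
    channelPct = "numeric",
    domain = "data.frame",
    subjectId = "character",
    condition = "character"
  ),
  prototype(subjectId = NA_character_, condition = NA_character_)
)

#' DTFTensor: directed transfer function values per segment
#'
#' Four-dimensional array of squared DTF values (sink i, source j,
#' frequency, segment), each slice row-normalized so that the inflow
#' into every sink sums to one.
#'
#' @slot values numeric array M x M x F x S in \[0, 1\].
#' @slot freqs frequency grid (Hz).
#' @slot window segment duration used for the MVAR fits (seconds).
#' @slot labels channel labels.
#' @slot orders MVAR order fitted on each retained segment.
#' @slot excluded indices of segments dropped for unstable fits.
#' @slot fs sampling rate of the underlying recording (Hz).
#' @exportClass DTFTensor
setClass("DTFTensor",
  representation(
    values = "array",
    freqs = "numeric",
    window = "numeric",
    labels = "character",
    orders = "integer",
    excluded = "integer",
    fs = "numeric"
  ),
  prototype(excluded = integer())
)

setValidity("DTFTensor", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 4 || d[1] != d[2]) {
    msg <- c(msg, "'values' must be an M x M x F x S array")
  }
  if (length(object@freqs) != d[3]) {
    msg <- c(msg, "frequency grid must match the third dimension")
  }
  if (length(msg)) msg else TRUE
})

#' BandAdjacency: band-averaged, significance-masked connectivity
#'
#' @slot band frequency band limits (Hz, inclusive).
#' @slot mean across-segment mean band-averaged DTF matrix (sinks in
#'   rows, sources in columns).
#' @slot pvalues per-edge one-sided p-values (diagonal NA).
#' @slot mask logical matrix of significant directed edges.
#' @slot alpha significance level.
#' @slot null description of the null level the t-test was run against.
#' @exportClass BandAdjacency
setClass("BandAdjacency",
  representation(
    band = "numeric",
    mean = "matrix",
    pvalues = "matrix",
    mask = "matrix",
    alpha = "numeric",
    null = "character"
  )
)

#' DirectedNetwork: cost-thresholded directed graph
#'
#' A weighted adjacency (significance-masked DTF magnitudes) binarized
#' at a given network cost: the p% cost keeps every edge whose weight is
#' at least (100 - p)% of the maximum weight.
#'
#' @slot weights weighted adjacency, zero where non-significant; no
#'   self-loops.
#' @slot binary logical adjacency at the given cost.
#' @slot cost cost level in percent.
#' @slot labels node (channel) labels.
#' @exportClass DirectedNetwork
setClass("DirectedNetwork",
  representation(
    weights = "matrix",
    binary = "matrix",
    cost = "numeric",
    labels = "character"
  )
)

setValidity("DirectedNetwork", function(object) {
  msg <- character()
  if (any(diag(object@weights) != 0)) {
    msg <- c(msg, "self-loops are not allowed")
  }
  if (!identical(dim(object@weights), dim(object@binary))) {
    msg <- c(msg, "'weights' and 'binary' must have identical shape")
  }
  if (length(msg)) msg else TRUE
})

#' MVARModel: multivariate autoregressive model fit
#'
#' @slot A list of p coefficient matrices (M x M); A\[\[k\]\]\[i, j\] is the
#'   influence of channel j at lag k on channel i.
#' @slot Sigma residual covariance matrix.
#' @slot order model order p.
#' @slot nobs number of samples the model was fitted on.
#' @slot stable TRUE when all companion-matrix eigenvalues lie inside
#'   the unit circle.
#' @exportClass MVARModel
setClass("MVARModel",
  representation(
    A = "list",
    Sigma = "matrix",
    order = "integer",
    nobs = "integer",
    stable = "logical"
  )
)
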