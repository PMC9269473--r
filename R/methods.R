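#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))

#' @rdname accessors
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("duration", "EEGRecording", function(x) ncol(x@data) / x@fs)

#' @rdname accessors
#' @export
setMethod("recordingData", "EEGRecording", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("nChannels", "KurtosisVariance", function(x) nrow(x@values))

#' @rdname accessors
#' @export
setMethod("channelLabels", "KurtosisVariance", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("windowLengths", "KurtosisVariance", function(x) x@windowLengths)

#' Kurtosis-variance values
#'
#' @param x a [KurtosisVariance-class] object.
#' @return The channels-by-window-multiples numeric matrix.
#' @export
kurtosisValues <- function(x) {
  stopifnot(is(x, "KurtosisVariance"))
  x@values
}

#' @rdname accessors
#' @export
setMethod("selectedWindow", "WindowSelection", function(x) x@window)

#' @rdname accessors
#' @export
setMethod("channelLabels", "WindowSelection", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("nChannels", "DTFTensor", function(x) dim(x@values)[1])

#' @rdname accessors
#' @export
setMethod("channelLabels", "DTFTensor", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("samplingRate", "DTFTensor", function(x) x@fs)

#' Number of retained segments in a DTF tensor
#'
#' @param x a [DTFTensor-class] object.
#' @return Integer count of segments (fourth array dimension).
#' @export
nSegments <- function(x) {
  stopifnot(is(x, "DTFTensor"))
  dim(x@values)[4]
}

#' DTF tensor values
#'
#' @param x a [DTFTensor-class] object.
#' @return The M x M x F x S array of squared DTF values.
#' @export
dtfValues <- function(x) {
  stopifnot(is(x, "DTFTensor"))
  x@values
}

#' Significance results of a band adjacency
#'
#' `adjacencyMatrix` returns the across-segment mean DTF with
#' non-significant edges zeroed; `significanceMask` and `edgePvalues`
#' return the underlying mask and p-value matrices.
#'
#' @param x a [BandAdjacency-class] object.
#' @return A numeric or logical matrix.
#' @export
adjacencyMatrix <- function(x) {
  stopifnot(is(x, "BandAdjacency"))
  out <- x@mean
  out[!x@mask] <- 0
  diag(out) <- 0
  out
}

#' @rdname adjacencyMatrix
#' @export
significanceMask <- function(x) {
  stopifnot(is(x, "BandAdjacency"))
  x@mask
}

#' @rdname adjacencyMatrix
#' @export
edgePvalues <- function(x) {
  stopifnot(is(x, "BandAdjacency"))
  x@pvalues
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(object@data), ncol(object@data), object@fs,
    ncol(object@data) / object@fs))
  if (!is.na(object@subjectId) || !is.na(object@condition)) {
    cat(sprintf("  subject: %s  condition: %s\n",
                object@subjectId, object@condition))
  }
  lab <- object@labels
  if (length(lab) > 6) lab <- c(lab[1:6], "...")
  cat("  channels:", paste(lab, collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "KurtosisVariance", function(object) {
  cat(sprintf(
    "KurtosisVariance: %d channels x %d window multiples (W_L = %g s)\n",
    nrow(object@values), ncol(object@values), object@basisWindow))
  cat(sprintf("  durations: %s s\n",
              paste(object@windowLengths, collapse = ", ")))
  cat(sprintf("  range: [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
  invisible(object)
})

setMethod("show", "WindowSelection", function(object) {
  cat(sprintf("WindowSelection: window = %g s\n", object@window))
  cat(sprintf("  variance interval [%.4g, %.4g] (%d%% of span)\n",
              object@interval[1], object@interval[2],
              as.integer(round(object@variancePct))))
  cat(sprintf("  channels retained: %d (%d%%)\n",
              length(object@channels),
              as.integer(round(object@channelPct))))
  invisible(object)
})

setMethod("show", "DTFTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "DTFTensor: %d x %d channels, %d frequencies (%g-%g Hz), %d segments\n",
    d[1], d[2], d[3], min(object@freqs), max(object@freqs), d[4]))
  cat(sprintf("  window = %g s; MVAR orders: %s\n", object@window,
              paste(sort(unique(object@orders)), collapse = ", ")))
  if (length(object@excluded)) {
    cat("  excluded unstable segments:",
        paste(object@excluded, collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "BandAdjacency", function(object) {
  cat(sprintf("BandAdjacency: %g-%g Hz, %d x %d channels\n",
              object@band[1], object@band[2],
              nrow(object@mean), ncol(object@mean)))
  cat(sprintf("  significant edges: %d of %d (alpha = %g, null = %s)\n",
              sum(object@mask, na.rm = TRUE),
              nrow(object@mean) * (nrow(object@mean) - 1),
              object@alpha, object@null))
  invisible(object)
})

setMethod("show", "DirectedNetwork", function(object) {
  n <- nrow(object@binary)
  e <- sum(object@binary)
  cat(sprintf("DirectedNetwork: %d nodes, %d edges at cost %g%% (density %.1f%%)\n",
              n, e, object@cost, 100 * e / (n * (n - 1))))
  invisible(object)
})

setMethod("show", "MVARModel", function(object) {
  cat(sprintf("MVARModel: order %d, %d channels, fitted on %d samples%s\n",
              object@order, nrow(object@Sigma), object@nobs,
              if (object@stable) "" else " [UNSTABLE]"))
  invisible(object)
})
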