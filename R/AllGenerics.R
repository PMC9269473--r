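#' @include AllClasses.R
NULL

#' Accessors for EEG containers
#'
#' `nChannels`, `nSamples`, `samplingRate`, `channelLabels` and
#' `duration` expose the dimensions and metadata of the package's S4
#' containers without touching slots directly.
#'
#' @param x an [EEGRecording-class], [KurtosisVariance-class],
#'   [DTFTensor-class] or [DirectedNetwork-class] object.
#' @return The requested scalar or vector.
#' @name accessors
#' @examples
#' rec <- EEGRecording(matrix(0, 3, 500), fs = 250)
#' nChannels(rec); nSamples(rec); duration(rec)
NULL

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))

#' @rdname accessors
#' @export
setGeneric("windowLengths", function(x) standardGeneric("windowLengths"))

#' @rdname accessors
#' @export
setGeneric("selectedWindow", function(x) standardGeneric("selectedWindow"))
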