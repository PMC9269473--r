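#' @include AllClasses.R
NULL

#' Read a multichannel recording from disk
#'
#' Supports European Data Format (EDF, continuous signals) and a
#' delimited text layout: a first line `# fs=<Hz>`, a header row of
#' channel labels, then one column per channel (comma or tab
#' separated).
#'
#' @param path path to the file.
#' @param format `"auto"` (sniff the EDF magic bytes), `"edf"` or
#'   `"delimited"`.
#' @param subjectId,condition optional metadata tags attached to the
#'   returned recording.
#' @return An [EEGRecording-class] object in channel-major order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeRecording(EEGRecording(matrix(rnorm(750), 3), fs = 250), f)
#' rec <- readRecording(f)
#' @export
readRecording <- function(path, format = c("auto", "edf", "delimited"),
                          subjectId = NA_character_,
                          condition = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    con <- file(path, "rb")
    magic <- readBin(con, "raw", 8)
    close(con)
    format <- if (identical(rawToChar(magic), "0       ")) "edf" else "delimited"
  }
  if (format == "edf") {
    edf <- .readEDF(path)
    EEGRecording(edf$data, fs = edf$fs, labels = edf$labels,
                 subjectId = subjectId, condition = condition)
  } else {
    .readDelimited(path, subjectId = subjectId, condition = condition)
  }
}

.readDelimited <- function(path, subjectId = NA_character_,
                           condition = NA_character_) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*fs\\s*=\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2) {
    stop("missing sampling rate: expected a first line '# fs=<Hz>' in ", path)
  }
  fs <- as.numeric(m[2])
  sep <- if (grepl("\t", readLines(path, n = 2L)[2])) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE, skip = 1L,
                           check.names = FALSE, fill = FALSE,
                           colClasses = "numeric")
  if (nrow(tab) < 1) stop("no samples in ", path)
  data <- t(as.matrix(tab))
  if (any(!is.finite(data))) {
    stop("inconsistent sample counts or non-numeric values in ", path)
  }
  EEGRecording(data, fs = fs, labels = colnames(tab),
               subjectId = subjectId, condition = condition)
}

#' Write a recording to disk
#'
#' Delimited output round-trips through [readRecording()] to full
#' double precision; EDF output is quantized to the 16-bit dynamic
#' range of the data (the format's native resolution).
#'
#' @param rec an [EEGRecording-class] object.
#' @param path output path.
#' @param format `"delimited"` (default) or `"edf"`.
#' @param digits significant digits for delimited output (default 15,
#'   full double round-trip).
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("delimited", "edf"),
                           digits = 15) {
  stopifnot(is(rec, "EEGRecording"))
  format <- match.arg(format)
  if (format == "edf") return(.writeEDF(rec, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec@fs), con)
  writeLines(paste(rec@labels, collapse = ","), con)
  mat <- t(rec@data)
  lines <- apply(mat, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

# --- Minimal EDF (continuous) support -------------------------------------
# Fixed 256-byte main header + 256 bytes per signal, then data records of
# 16-bit little-endian integers, signal-blocked. All signals must share one
# sampling rate here (the scalp-EEG case); annotation channels are not
# supported.

.padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

.writeEDF <- function(rec, path) {
  M <- nrow(rec@data)
  fs <- rec@fs
  # one-second records; pad the tail record with zeros
  spr <- as.integer(round(fs))
  if (abs(spr - fs) > 1e-9) stop("EDF writer requires an integer Hz rate")
  nrec <- ceiling(ncol(rec@data) / spr)
  padded <- matrix(0, M, nrec * spr)
  padded[, seq_len(ncol(rec@data))] <- rec@data
  physMax <- max(1e-6, max(abs(padded)))
  dig <- round(padded / physMax * 32767)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .padField("0", 8),
    .padField(ifelse(is.na(rec@subjectId), "X", rec@subjectId), 80),
    .padField(ifelse(is.na(rec@condition), "X", rec@condition), 80),
    .padField("01.01.00", 8), .padField("00.00.00", 8),
    .padField(256 * (1 + M), 8),
    .padField("", 44),
    .padField(nrec, 8),
    .padField(format(1), 8),
    .padField(M, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste(vapply(vals, .padField, "", width = width),
                    collapse = ""), con, eos = NULL)
  }
  fld(rec@labels, 16)
  fld(rep("", M), 80)                      # transducer
  fld(rep("uV", M), 8)                     # physical dimension
  fld(rep(sprintf("%.6g", -physMax), M), 8)
  fld(rep(sprintf("%.6g", physMax), M), 8)
  fld(rep("-32768", M), 8)
  fld(rep("32767", M), 8)
  fld(rep("", M), 80)                      # prefiltering
  fld(rep(spr, M), 8)
  fld(rep("", M), 32)                      # reserved
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(M)) {
      writeBin(as.integer(dig[s, idx]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

.readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  version <- rd(8)
  if (version != "0") stop("not an EDF file: ", path)
  patient <- rd(80); recordingId <- rd(80)
  rd(8); rd(8)                             # start date/time
  rd(8)                                    # header bytes
  rd(44)                                   # reserved
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  M <- as.integer(rd(4))
  fld <- function(width) vapply(seq_len(M), function(i) rd(width), "")
  labels <- fld(16)
  fld(80)
  fld(8)
  physMin <- as.numeric(fld(8))
  physMax <- as.numeric(fld(8))
  digMin <- as.numeric(fld(8))
  digMax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1) {
    stop("EDF reader supports a single shared sampling rate only")
  }
  fs <- spr[1] / recDur
  data <- matrix(0, M, nrec * spr[1])
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    for (s in seq_len(M)) {
      vals <- readBin(con, "integer", spr[s], size = 2, signed = TRUE,
                      endian = "little")
      if (length(vals) < spr[s]) stop("truncated EDF data record in ", path)
      idx <- ((r - 1) * spr[s] + 1):(r * spr[s])
      data[s, idx] <- physMin[s] + scale[s] * (vals - digMin[s])
    }
  }
  list(data = data, fs = fs, labels = labels,
       patient = patient, recordingId = recordingId)
}
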