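#' @include AllClasses.R
NULL

# half-up rounding for printed percentages (e.g. 235/308 -> 76%)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Example resting-state cohort metadata
#'
#' `restingCohortTable()` returns per-recording raw/clean durations and
#' retained channel counts for a ten-subject resting-state EEG cohort
#' (two conditions per subject: R1 open eyes, R2 closed eyes), shipped
#' with the package as a worked example for the retention filter.
#' `restingSelectionTable()` returns the matching per-recording
#' window-selection results (variance interval, variance percentage,
#' selected window and retained-channel percentage) for the six
#' subjects that survive the 50% retention rule.
#'
#' @return A `data.frame`.
#' @examples
#' retentionFilter(restingCohortTable())$subjects
#' @export
restingCohortTable <- function() {
  path <- system.file("extdata", "resting_cohort.csv", package = "kurtoseg",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname restingCohortTable
#' @export
restingSelectionTable <- function() {
  path <- system.file("extdata", "resting_selection.csv",
                      package = "kurtoseg", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.checkCohort <- function(cohort) {
  need <- c("subject", "condition", "raw_s", "clean_s", "channels")
  if (!all(need %in% names(cohort))) {
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(cohort) == 0) stop("empty cohort table")
  if (any(cohort$clean_s < 0 | cohort$clean_s > cohort$raw_s)) {
    stop("clean duration must lie in [0, raw duration]")
  }
  invisible(cohort)
}

#' Clean-duration retention filter
#'
#' Artifact rejection shortens recordings; a recording whose surviving
#' clean duration is a small fraction of the acquisition is unusable
#' for segment-based connectivity. A subject is retained only when the
#' rounded clean-duration percentage reaches `threshold` in BOTH
#' conditions, so a subject failing in either condition is dropped
#' entirely (the filter operates per subject, not per recording).
#'
#' @param cohort a cohort `data.frame` with columns `subject`,
#'   `condition`, `raw_s`, `clean_s`, `channels` (see
#'   [restingCohortTable()] for the layout).
#' @param threshold minimum clean-duration percentage (default 50).
#' @param totalChannels full montage size used for the channel
#'   percentage (default 62).
#' @return A list with `subjects` (retained subject ids), `recordings`
#'   (the retained rows, with `clean_pct` and `channel_pct` columns
#'   added), `discarded` (dropped subject ids) and `summary` (the
#'   per-condition means over ALL input rows, see [cohortSummary()]).
#' @export
retentionFilter <- function(cohort, threshold = 50, totalChannels = 62) {
  .checkCohort(cohort)
  cohort$clean_pct <- .roundHalfUp(100 * cohort$clean_s / cohort$raw_s)
  cohort$channel_pct <- .roundHalfUp(100 * cohort$channels / totalChannels)
  ok <- tapply(cohort$clean_pct >= threshold, cohort$subject, all)
  subjects <- names(ok)[ok]
  # preserve input order of subjects
  subjects <- unique(cohort$subject)[unique(cohort$subject) %in% subjects]
  list(
    subjects = subjects,
    recordings = cohort[cohort$subject %in% subjects, , drop = FALSE],
    discarded = setdiff(unique(cohort$subject), subjects),
    summary = cohortSummary(cohort)
  )
}

#' Per-condition cohort summary
#'
#' Means of raw duration (rounded to the second), clean duration (one
#' decimal) and selected-channel count (nearest integer) for each
#' condition, over all rows of the table.
#'
#' @param cohort a cohort `data.frame` (see [retentionFilter()]).
#' @return A `data.frame` with one row per condition.
#' @export
cohortSummary <- function(cohort) {
  .checkCohort(cohort)
  conds <- unique(cohort$condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    rows <- cohort[cohort$condition == cc, , drop = FALSE]
    data.frame(
      condition = cc,
      n = nrow(rows),
      raw_mean_s = round(mean(rows$raw_s)),
      clean_mean_s = round(mean(rows$clean_s), 1),
      channels_mean = round(mean(rows$channels))
    )
  }))
  rownames(out) <- NULL
  out
}
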