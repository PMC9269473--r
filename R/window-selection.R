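#' @include AllClasses.R
NULL

#' Fit the kurtosis-variance density and locate its peak
#'
#' Pools all entries of the kurtosis-variance matrix and fits a Gamma
#' density by maximum likelihood (the chi-square family is the
#' Gamma(k/2, scale 2) special case, so the Gamma covers it). The peak
#' `pk` anchors the interval search: it is the fitted mode
#' `(shape - 1) * scale` when `shape > 1` and the support minimum of
#' the data otherwise. A matrix whose entries are all equal is treated
#' as a point mass at that value.
#'
#' @param K a [KurtosisVariance-class] object or a numeric matrix of
#'   kurtosis variances. The Gamma MLE needs at least 10 finite
#'   entries; below that a method-of-moments fit is used instead.
#' @return A list with `shape`, `rate`, `pk`, and `degenerate` (TRUE
#'   for the point-mass case).
#' @export
fitVariancePdf <- function(K) {
  vals <- if (is(K, "KurtosisVariance")) K@values else as.matrix(K)
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2) stop("need at least 2 finite kurtosis variances")
  if (all(vals == 0)) stop("degenerate fit: all kurtosis variances are zero")
  if (diff(range(vals)) == 0) {
    return(list(shape = NA_real_, rate = NA_real_, pk = vals[1],
                degenerate = TRUE))
  }
  pos <- vals[vals > 0]
  m <- mean(pos); v <- stats::var(pos)
  if (!is.finite(v) || v <= 0) v <- m^2   # single positive value
  start <- list(shape = max(m^2 / v, 1e-2), rate = max(m / v, 1e-6))
  fit <- NULL
  if (length(pos) >= 10) {
    fit <- tryCatch(
      MASS::fitdistr(pos, "gamma", start = start, lower = c(1e-8, 1e-8),
                     method = "L-BFGS-B"),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    est <- c(shape = start$shape, rate = start$rate)  # method-of-moments
  } else {
    est <- fit$estimate
  }
  pk <- if (est["shape"] > 1) {
    (est["shape"] - 1) / est["rate"]
  } else {
    min(vals)
  }
  list(shape = unname(est["shape"]), rate = unname(est["rate"]),
       pk = unname(pk), degenerate = FALSE)
}

# per-channel shortest duration whose variance falls inside [lb, hb];
# returns a data.frame of (channel, duration, variance) triples
.selectInInterval <- function(vals, windowLengths, lb, hb) {
  hits <- vals >= lb & vals <= hb
  rows <- which(rowSums(hits) > 0)
  if (!length(rows)) {
    return(data.frame(channel = character(), duration = numeric(),
                      variance = numeric()))
  }
  ord <- order(windowLengths)
  dur <- vapply(rows, function(r) {
    windowLengths[ord[which(hits[r, ord])[1]]]
  }, numeric(1))
  vv <- vapply(seq_along(rows), function(k) {
    vals[rows[k], which(windowLengths == dur[k])[1]]
  }, numeric(1))
  labs <- rownames(vals)
  if (is.null(labs)) labs <- paste0("Ch", seq_len(nrow(vals)))
  data.frame(channel = labs[rows], duration = dur, variance = vv,
             stringsAsFactors = FALSE)
}

#' Variance-interval searching strategy
#'
#' Starting from the fitted density peak `pk`, the interval
#' `[Lb, Hb] = [pk - k*c, pk + k*c]` widens by `c` per side each
#' iteration. At every width the per-channel SHORTEST duration whose
#' kurtosis variance lies inside the interval is selected; the search
#' stops at the first width where (a) the number of selected channels
#' exceeds `threshold1 * M` and (b) the mean of the selected variances
#' is at most `threshold2` times the mean of the per-channel maximum
#' variances. Widening never removes a channel, so the channel count is
#' non-decreasing in the interval width.
#'
#' @param K a [KurtosisVariance-class] object or numeric matrix.
#' @param c searching-rate increment per iteration; default 1% of the
#'   global range of the matrix.
#' @param threshold1 minimum channel fraction (default 0.5).
#' @param threshold2 dispersion bound as a fraction of the mean
#'   per-channel maximum variance (default 0.4).
#' @param kMax safety bound on the number of widenings (default 200).
#' @param windowLengths candidate durations (taken from `K` when it is
#'   a [KurtosisVariance-class] object).
#' @return A list with `selection` (data.frame of channel, duration,
#'   variance triples sorted by variance; empty with a warning when no
#'   interval qualifies within `kMax`), `interval`, `iterations`, `pk`
#'   and `c`.
#' @export
varianceSearch <- function(K, c = NULL, threshold1 = 0.5, threshold2 = 0.4,
                           kMax = 200, windowLengths = NULL) {
  if (is(K, "KurtosisVariance")) {
    vals <- K@values
    windowLengths <- K@windowLengths
  } else {
    vals <- as.matrix(K)
    if (is.null(windowLengths)) windowLengths <- seq_len(ncol(vals))
  }
  fit <- fitVariancePdf(vals)
  pk <- fit$pk
  rng <- diff(range(vals))
  if (is.null(c)) c <- 0.01 * rng
  if (c <= 0) stop("searching rate 'c' must be positive")
  M <- nrow(vals)
  maxRef <- mean(apply(vals, 1, max))
  for (k in seq_len(kMax)) {
    lb <- pk - k * c
    hb <- pk + k * c
    sel <- .selectInInterval(vals, windowLengths, lb, hb)
    if (nrow(sel) > threshold1 * M) {
      if (mean(sel$variance) <= threshold2 * maxRef) {
        sel <- sel[order(sel$variance), , drop = FALSE]
        rownames(sel) <- NULL
        return(list(selection = sel, interval = c(lb, hb), iterations = k,
                    pk = pk, c = c))
      }
    }
  }
  warning("no qualifying interval within kMax iterations; empty selection")
  list(selection = .selectInInterval(vals, windowLengths, Inf, -Inf),
       interval = c(pk - kMax * c, pk + kMax * c), iterations = kMax,
       pk = pk, c = c)
}

#' Percentage-threshold search domain
#'
#' Anchored at the density peak `pk`, the interval at percentage `p`
#' spans `p`% of the distance from `pk` down to the matrix minimum and
#' up to the matrix maximum:
#' `[pk - p/100 * (pk - min), pk + p/100 * (max - pk)]`, so `p = 100`
#' covers every entry. Each (percentage, duration) cell counts the
#' channels whose kurtosis variance at that duration falls inside the
#' interval; `channelsAny` counts channels with at least one duration
#' inside.
#'
#' @param K a [KurtosisVariance-class] object or numeric matrix.
#' @param percentages percentage thresholds (default 10, 20, ..., 100).
#' @param windowLengths candidate durations when `K` is a bare matrix.
#' @return A long-format `data.frame` with columns `percentage`,
#'   `window`, `count`, `lower`, `upper`, `channelsAny`.
#' @export
percentageDomain <- function(K, percentages = seq(10, 100, by = 10),
                             windowLengths = NULL) {
  if (is(K, "KurtosisVariance")) {
    vals <- K@values
    windowLengths <- K@windowLengths
  } else {
    vals <- as.matrix(K)
    if (is.null(windowLengths)) windowLengths <- seq_len(ncol(vals))
  }
  fit <- fitVariancePdf(vals)
  pk <- fit$pk
  lo <- min(vals); hi <- max(vals)
  out <- vector("list", length(percentages))
  for (ip in seq_along(percentages)) {
    p <- percentages[ip]
    lb <- pk - p / 100 * (pk - lo)
    hb <- pk + p / 100 * (hi - pk)
    inside <- vals >= lb & vals <= hb
    out[[ip]] <- data.frame(
      percentage = p,
      window = windowLengths,
      count = colSums(inside),
      lower = lb,
      upper = hb,
      channelsAny = sum(rowSums(inside) > 0)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select the segment length for one recording
#'
#' Picks the duration reachable at the LOWEST percentage threshold: for
#' every candidate duration the minimal percentage at which its
#' interval gathers at least `ceiling(threshold1 * M)` channels is
#' computed exactly (a channel at variance `v` enters the
#' peak-anchored interval at `p = 100 (v - pk) / (max - pk)` above the
#' peak, `100 (pk - v) / (pk - min)` below it, so the qualifying
#' percentage of a duration is the `minChannels`-th smallest entry
#' percentage of its column). The duration with the smallest
#' qualifying percentage wins; ties go to the SHORTER duration, since
#' more segments per recording stabilize the downstream MVAR
#' statistics. The 10%-step domain table of [percentageDomain()] is
#' attached for reporting.
#'
#' @param K a [KurtosisVariance-class] object or numeric matrix.
#' @param threshold1 minimum channel fraction (default 0.5; raise it to
#'   demand broader spatial agreement).
#' @param percentages grid used for the attached domain table (default
#'   10, ..., 100; the selection itself uses exact percentages).
#' @param windowLengths candidate durations when `K` is a bare matrix.
#' @param subjectId,condition provenance stored in the result.
#' @return A [WindowSelection-class] object.
#' @export
selectWindow <- function(K, threshold1 = 0.5,
                         percentages = seq(10, 100, by = 10),
                         windowLengths = NULL,
                         subjectId = NA_character_,
                         condition = NA_character_) {
  if (is(K, "KurtosisVariance")) {
    vals <- K@values
    windowLengths <- K@windowLengths
  } else {
    vals <- as.matrix(K)
    if (is.null(windowLengths)) windowLengths <- seq_len(ncol(vals))
  }
  M <- nrow(vals)
  minChannels <- ceiling(threshold1 * M)
  fit <- fitVariancePdf(vals)
  pk <- fit$pk
  lo <- min(vals); hi <- max(vals)
  # entry percentage of each matrix value
  entryPct <- function(v) {
    ifelse(v >= pk,
           if (hi > pk) 100 * (v - pk) / (hi - pk) else 0,
           if (pk > lo) 100 * (pk - v) / (pk - lo) else 0)
  }
  pw <- vapply(seq_along(windowLengths), function(wi) {
    pv <- sort(entryPct(vals[, wi]))
    if (length(pv) < minChannels) Inf else pv[minChannels]
  }, numeric(1))
  domain <- percentageDomain(vals, percentages, windowLengths)
  if (all(!is.finite(pw))) {
    stop("no duration reaches ", minChannels, " channels; domain table:\n",
         paste(utils::capture.output(print(domain)), collapse = "\n"))
  }
  pBest <- min(pw)
  wBest <- min(windowLengths[pw == pBest])
  lb <- pk - pBest / 100 * (pk - lo)
  hb <- pk + pBest / 100 * (hi - pk)
  col <- vals[, which(windowLengths == wBest)[1]]
  inside <- col >= lb & col <= hb
  labs <- rownames(vals)
  if (is.null(labs)) labs <- paste0("Ch", seq_len(M))
  new("WindowSelection",
      window = wBest,
      interval = c(lb, hb),
      variancePct = pBest,
      channels = labs[inside],
      channelPct = .roundHalfUp(100 * sum(inside) / M),
      domain = domain,
      subjectId = as.character(subjectId),
      condition = as.character(condition))
}

#' Aggregate per-recording selections to a cohort choice
#'
#' The cohort window is the statistical mode of the per-recording
#' selected windows (ties broken toward the shorter duration); the
#' variance and channel percentages are averaged and rounded to the
#' nearest integer.
#'
#' @param results a list of [WindowSelection-class] objects, or a
#'   `data.frame` with columns `window_s`, `variance_pct`,
#'   `channel_pct` (the layout of [restingSelectionTable()]).
#' @return A list with `modalWindow`, `meanVariancePct`,
#'   `meanChannelPct`, and the per-recording `table`.
#' @export
aggregateSelection <- function(results) {
  if (is.data.frame(results)) {
    tab <- results
    need <- c("window_s", "variance_pct", "channel_pct")
    if (!all(need %in% names(tab))) {
      stop("data.frame input needs columns: ", paste(need, collapse = ", "))
    }
  } else {
    if (length(results) == 0) stop("empty result list")
    stopifnot(all(vapply(results, is, logical(1), "WindowSelection")))
    tab <- do.call(rbind, lapply(results, function(r) {
      data.frame(subject = r@subjectId, condition = r@condition,
                 window_s = r@window, variance_pct = r@variancePct,
                 channel_pct = r@channelPct, stringsAsFactors = FALSE)
    }))
  }
  if (nrow(tab) == 0) stop("empty result list")
  counts <- table(tab$window_s)
  winners <- as.numeric(names(counts)[counts == max(counts)])
  list(
    modalWindow = min(winners),
    meanVariancePct = .roundHalfUp(mean(tab$variance_pct)),
    meanChannelPct = .roundHalfUp(mean(tab$channel_pct)),
    table = tab
  )
}
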