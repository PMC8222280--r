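## HU time traces, baseline/peak measurements per contour, percent HU
## change, and the per-bin statistical testing (paired t, KS normality,
## Bonferroni).

#' HUTrace: mean HU per frame over one contour
#'
#' @slot times acquisition times, s.
#' @slot meanHu arithmetic mean HU of in-mask voxels, one per frame.
#' @slot label contour label.
#' @slot nVoxels voxels in the contour.
#' @export
setClass("HUTrace",
  representation(times = "numeric", meanHu = "numeric", label = "character",
                 nVoxels = "integer"))

setValidity("HUTrace", function(object) {
  if (length(object@times) != length(object@meanHu))
    return("times and meanHu must have equal length")
  if (object@nVoxels <= 0L) return("nVoxels must be positive")
  TRUE
})

setMethod("show", "HUTrace", function(object) {
  cat(sprintf("HUTrace '%s': %d frames over %d voxels, HU %.1f..%.1f\n",
              object@label, length(object@times), object@nVoxels,
              min(object@meanHu), max(object@meanHu)))
})

#' @rdname extractTrace
#' @export
traceMeanHu <- function(trace) trace@meanHu

#' Extract the mean-HU time trace of a contour from a dynamic series
#'
#' @param series a \linkS4class{DynamicSeries}.
#' @param mask non-empty \linkS4class{BinaryMask} on the series geometry.
#' @param label contour label carried on the trace.
#' @return An \linkS4class{HUTrace}; \code{traceMeanHu} returns its
#'   per-frame means.
#' @export
extractTrace <- function(series, mask, label = "roi") {
  stopifnot(is(series, "DynamicSeries"))
  assertSameGeometry(seriesFrame(series, 1L), mask)
  idx <- which(mask@values)
  if (length(idx) == 0L) stop("empty mask")
  mh <- vapply(seriesFrames(series),
               function(f) mean(f@values[idx]), numeric(1))
  new("HUTrace", times = seriesTimes(series), meanHu = mh,
      label = label, nVoxels = length(idx))
}

#' Baseline HU of a trace
#'
#' The first frame of the dynamic series is acquired before contrast
#' injection, so its mean is the unenhanced baseline.
#'
#' @param trace an \linkS4class{HUTrace}.
#' @return baseline HU (first frame's mean).
#' @export
baselineHu <- function(trace) {
  stopifnot(is(trace, "HUTrace"))
  trace@meanHu[1]
}

#' Peak HU of a trace
#'
#' Maximum of the per-frame means: the frame at which contrast
#' concentration peaks in the contour. Measured only for vessel contours.
#'
#' @param trace an \linkS4class{HUTrace}.
#' @return peak HU.
#' @export
peakHu <- function(trace) {
  stopifnot(is(trace, "HUTrace"))
  max(trace@meanHu)
}

#' Percent HU change between timepoints
#'
#' Two conventions. \code{"magnitude"} (default) divides by \code{|pre|},
#' so that a density increase in negative-baseline lung (e.g. -800 to
#' -700 HU) reads as a positive percent change, matching how lung density
#' increases are reported. \code{"literal"} divides by the signed
#' \code{pre}, which sign-inverts percentages for negative baselines.
#'
#' @param huPre,huPost HU values at the two timepoints.
#' @param convention \code{"magnitude"} or \code{"literal"}.
#' @return percent change.
#' @examples
#' deltaHuPercent(-800, -700)              # +12.5
#' deltaHuPercent(-800, -700, "literal")   # -12.5
#' @export
deltaHuPercent <- function(huPre, huPost,
                           convention = c("magnitude", "literal")) {
  convention <- match.arg(convention)
  if (any(huPre == 0)) stop("zero pre-RT HU: percent change undefined")
  den <- switch(convention, magnitude = abs(huPre), literal = huPre)
  (huPost - huPre) / den * 100
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of comparisons (the number of dose bins tested in a
#'   family: 5 bins at alpha 0.05 gives the adjusted threshold 0.01).
#' @return \code{alpha / m}.
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Average replicate scan measurements
#'
#' Repeat scans acquired minutes apart at one timepoint are independent
#' noise draws of the same state; their per-contour means are averaged
#' before any statistics.
#'
#' @param measurements data.frame of per-scan measurements with columns
#'   \code{subject}, \code{timepoint}, \code{bin}, \code{compartment},
#'   \code{laterality}, \code{eqd2}, \code{baseline_hu} and optionally
#'   \code{peak_hu}; rows are replicates of the same key.
#' @return data.frame with one row per (subject, timepoint, bin,
#'   compartment), replicate means in \code{baseline_hu} / \code{peak_hu}.
#' @export
averageReplicates <- function(measurements) {
  req <- c("subject", "timepoint", "bin", "compartment", "baseline_hu")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns: ", paste(req, collapse = ", "))
  key <- interaction(measurements$subject, measurements$timepoint,
                     measurements$bin, measurements$compartment, drop = TRUE)
  first <- !duplicated(key)
  out <- measurements[first, , drop = FALSE]
  out$baseline_hu <- as.numeric(
    tapply(measurements$baseline_hu, key, mean)[as.character(key[first])])
  if ("peak_hu" %in% names(measurements))
    out$peak_hu <- as.numeric(
      tapply(measurements$peak_hu, key, mean)[as.character(key[first])])
  rownames(out) <- NULL
  out
}

#' Per-bin paired statistics of pre vs post-RT HU
#'
#' For each dose bin: a two-tailed Student paired t test of the pre vs
#' post values across subjects, a Kolmogorov-Smirnov normality check on
#' the standardized paired differences, the mean and SD of the percent
#' change, and a significance flag at the Bonferroni-adjusted threshold
#' \code{alpha / m} with m defaulting to the number of bins tested.
#'
#' @param cohort data.frame with columns \code{subject}, \code{timepoint},
#'   \code{bin}, \code{compartment}, \code{laterality}, \code{eqd2} and
#'   the measured value column.
#' @param timepointPre,timepointPost the two timepoints to pair.
#' @param compartment \code{"parenchyma"}, \code{"vessel"} or
#'   \code{"lung"}.
#' @param value measured column: \code{"baseline_hu"} (density) or
#'   \code{"peak_hu"} (vessel contrast peak).
#' @param alpha family-wise error rate (default 0.05).
#' @param m comparisons for Bonferroni; default = number of bins tested.
#' @param convention percent-change convention, see
#'   \code{\link{deltaHuPercent}}.
#' @return data.frame with one row per bin: n, \code{mean_delta_pct},
#'   \code{sd_delta_pct}, \code{t_p}, \code{ks_p}, \code{significant},
#'   \code{eqd2}, \code{laterality}. Bins with fewer than 2 subjects are
#'   skipped with a warning.
#' @export
binStatistics <- function(cohort, timepointPre = "pre", timepointPost,
                          compartment = "parenchyma",
                          value = c("baseline_hu", "peak_hu"),
                          alpha = 0.05, m = NULL,
                          convention = "magnitude") {
  value <- match.arg(value)
  d <- cohort[cohort$compartment == compartment, , drop = FALSE]
  pre <- d[d$timepoint == timepointPre, , drop = FALSE]
  post <- d[d$timepoint == timepointPost, , drop = FALSE]
  bins <- unique(pre$bin)
  rows <- list()
  for (b in bins) {
    for (lat in unique(pre$laterality[pre$bin == b])) {
      p1 <- pre[pre$bin == b & pre$laterality == lat, , drop = FALSE]
      p2 <- post[post$bin == b & post$laterality == lat, , drop = FALSE]
      common <- intersect(p1$subject, p2$subject)
      if (length(common) < 2L) {
        warning(sprintf("bin %s (%s): fewer than 2 paired subjects, skipped",
                        b, lat))
        next
      }
      x <- p1[[value]][match(common, p1$subject)]
      y <- p2[[value]][match(common, p2$subject)]
      delta <- deltaHuPercent(x, y, convention)
      tp <- if (stats::sd(y - x) == 0) 1
            else stats::t.test(y, x, paired = TRUE)$p.value
      dd <- y - x
      ks <- if (stats::sd(dd) == 0) NA_real_ else
        suppressWarnings(
          stats::ks.test((dd - mean(dd)) / stats::sd(dd), "pnorm")$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, laterality = lat, n = length(common),
        mean_delta_pct = mean(delta), sd_delta_pct = stats::sd(delta),
        t_p = tp, ks_p = ks,
        eqd2 = p1$eqd2[1], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  if (is.null(m)) m <- nrow(out)
  thr <- bonferroniThreshold(alpha, m)
  out$p_threshold <- thr
  out$significant <- out$t_p < thr
  rownames(out) <- NULL
  out
}
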