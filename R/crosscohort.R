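## Dose-response line fitting, the EQD2-matched "adjusted" swine dataset,
## swine-human correlation, the in/out-of-vessel coupling fit, and the
## tidy report writer.

#' Ordinary least squares fit with Pearson statistics
#'
#' @param x,y numeric vectors of equal length, n >= 2; x must not be
#'   constant.
#' @return A \linkS4class{LinearFit}: OLS slope/intercept, R-squared,
#'   Pearson r and its two-sided p-value from the t-distribution
#'   transform (NA when n < 3).
#' @examples
#' linearFit(c(1, 2, 3), c(1, 2, 4))  # slope 1.5, r ~ 0.982
#' @export
linearFit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 points")
  if (stats::sd(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  n <- length(x)
  p <- NA_real_
  if (n >= 3L && abs(r) < 1) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  } else if (n >= 3L) {
    p <- 0
  }
  new("LinearFit", slope = unname(co[2]), intercept = unname(co[1]),
      rSquared = r^2, pearsonR = r, pValue = p, n = as.integer(n))
}

#' EQD2-matched adjusted swine dataset
#'
#' The swine and human cohorts receive different fractionation schemes,
#' so their dose bins land on different EQD2 values. To correlate them,
#' the swine dose-response line is evaluated at the EQD2 values of the
#' human bins, giving predicted swine percent HU changes at exactly the
#' human abscissae. When the swine relation is strongly linear the
#' interpolation error is negligible.
#'
#' @param fit \linkS4class{LinearFit} of swine percent HU change vs EQD2.
#' @param humanEqd2 strictly increasing EQD2 values of the human bins, Gy.
#' @return data.frame with \code{eqd2} and \code{swine_pred} (percent).
#' @export
adjustedSwine <- function(fit, humanEqd2) {
  stopifnot(is(fit, "LinearFit"))
  if (length(humanEqd2) == 0L) stop("empty EQD2 list")
  if (any(diff(humanEqd2) <= 0)) stop("humanEqd2 must be strictly increasing")
  data.frame(eqd2 = humanEqd2,
             swine_pred = fit@slope * humanEqd2 + fit@intercept)
}

#' Swine-human cross-cohort correlation
#'
#' Regresses human per-bin percent HU change (y) on the EQD2-matched
#' adjusted swine values (x). The slope reads as "% change in human per
#' % change in swine": a slope near 1 means the swine response at its
#' timepoint models the human response at the compared timepoint.
#'
#' @param adjustedSwinePct adjusted swine percent changes (x).
#' @param humanPct human percent changes, same bins in the same order (y).
#' @return A \linkS4class{LinearFit}.
#' @export
crossCohortCorrelation <- function(adjustedSwinePct, humanPct) {
  if (length(adjustedSwinePct) != length(humanPct))
    stop("adjusted swine and human vectors must pair one-to-one by bin")
  if (length(humanPct) < 3L) stop("need at least 3 paired bins")
  linearFit(adjustedSwinePct, humanPct)
}

#' In-vessel vs out-of-vessel HU coupling fit
#'
#' Fits the cohort-averaged per-bin in-vessel peak percent HU change (y)
#' against the out-of-vessel baseline percent HU change (x). A dominant
#' negative slope indicates that the HU gained outside the vasculature is
#' fed by contrast lost from inside it (radiation-induced vascular
#' leakage); the accompanying correlation pairs the out-of-vessel
#' increase with the magnitude of the in-vessel reduction.
#'
#' @param outVesselPct per-bin out-of-vessel percent HU change
#'   (cohort-averaged).
#' @param inVesselPct per-bin in-vessel peak percent HU change, same bins.
#' @return list with \code{fit} (a \linkS4class{LinearFit}, slope in
#'   \%-in per \%-out) and \code{reductionCor} (Pearson correlation of
#'   out-of-vessel increase with in-vessel reduction magnitude).
#' @export
vesselCouplingFit <- function(outVesselPct, inVesselPct) {
  if (length(outVesselPct) != length(inVesselPct))
    stop("vectors must pair one-to-one by bin")
  if (length(outVesselPct) < 3L) stop("need at least 3 bins")
  fit <- linearFit(outVesselPct, inVesselPct)
  list(fit = fit, reductionCor = stats::cor(outVesselPct, -inVesselPct))
}

#' Write the tidy results report
#'
#' Emits one tidy CSV (subject, timepoint, bin, compartment, metric,
#' value) with deterministic row and field ordering, plus a JSON summary
#' of the fits and tests. Re-running on identical inputs reproduces the
#' files byte for byte.
#'
#' @param measurements cohort measurement data.frame (may have zero
#'   rows: a header-only CSV is written).
#' @param fits named list of \linkS4class{LinearFit} objects and/or plain
#'   values to serialize.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeReport <- function(measurements, fits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "measurements.csv")
  keys <- c("subject", "timepoint", "bin", "compartment")
  idCols <- intersect(keys, names(measurements))
  metricCols <- setdiff(names(measurements),
                        c(idCols, "laterality", "eqd2"))
  rows <- list()
  if (nrow(measurements) > 0) {
    ord <- do.call(order, measurements[idCols])
    m <- measurements[ord, , drop = FALSE]
    for (col in sort(metricCols)) {
      rows[[col]] <- data.frame(
        m[idCols],
        metric = col, value = m[[col]],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  tidy <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(), timepoint = character(),
               bin = character(), compartment = character(),
               metric = character(), value = numeric())
  if (nrow(tidy))
    tidy <- tidy[do.call(order, tidy[c(idCols, "metric")]), , drop = FALSE]
  utils::write.csv(tidy, csv, row.names = FALSE)
  js <- file.path(dir, "fits.json")
  ser <- lapply(fits, function(f) {
    if (is(f, "LinearFit")) as.list(fitAsDataFrame(f)) else f
  })
  if (length(ser)) ser <- ser[order(names(ser))]
  jsonlite::write_json(ser, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, json = js))
}
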