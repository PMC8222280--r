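## 10 Gy isodose-bin contours from a dose grid, contralateral mirroring as
## within-subject unirradiated controls, and EQD2 conversion under the
## linear-quadratic model.

#' Equivalent dose in 2 Gy fractions (EQD2)
#'
#' Linear-quadratic conversion \code{EQD2 = D * (d + alpha/beta) /
#' (2 + alpha/beta)}, where D is the total dose, d the dose per fraction
#' and alpha/beta the tissue fractionation-sensitivity ratio (3 Gy for
#' lung).
#'
#' @param totalDose D, Gy.
#' @param dosePerFraction d, Gy.
#' @param alphaBeta alpha/beta, Gy (default 3).
#' @return EQD2, Gy.
#' @examples
#' eqd2(60, 12, 3)  # 180: swine research course, 60 Gy in 5 fractions
#' eqd2(15, 10, 3)  # 39: upper edge of the 5-15 Gy bin at 50 Gy / 5 fx
#' @export
eqd2 <- function(totalDose, dosePerFraction, alphaBeta = 3) {
  if (any(totalDose <= 0) || any(dosePerFraction <= 0) || any(alphaBeta <= 0))
    stop("eqd2 requires positive totalDose, dosePerFraction and alphaBeta")
  totalDose * (dosePerFraction + alphaBeta) / (2 + alphaBeta)
}

#' EQD2 of a dose-bin representative dose under a fractionation scheme
#'
#' Converts a bin's representative physical dose D (the midpoint of
#' \code{[lo, hi)}, so the \code{[15, 25)} bin is "the 20 Gy bin") to EQD2.
#' Two conventions for the dose per fraction d are offered, because
#' clinical reports rarely state which is meant:
#' \describe{
#'   \item{prescription_fraction (default)}{d is the prescribed dose per
#'     fraction, \code{rxTotal / nFractions}, regardless of bin. This is
#'     the only convention that maps the 5 and 15 Gy edges at 50 Gy in 5
#'     fractions to 13 and 39 Gy EQD2.}
#'   \item{bin_fraction}{d = D / nFractions: the bin dose itself delivered
#'     over the scheme's fractions.}
#' }
#'
#' @param doseGy representative physical dose of the bin, Gy (scalar or
#'   vector).
#' @param scheme a \linkS4class{FractionationScheme}.
#' @param convention \code{"prescription_fraction"} or
#'   \code{"bin_fraction"}.
#' @return EQD2, Gy.
#' @examples
#' s <- FractionationScheme(50, 5)
#' binEqd2(c(5, 15), s)  # 13, 39
#' @export
binEqd2 <- function(doseGy, scheme,
                    convention = c("prescription_fraction", "bin_fraction")) {
  stopifnot(is(scheme, "FractionationScheme"))
  convention <- match.arg(convention)
  d <- switch(convention,
              prescription_fraction = scheme@rxTotal / scheme@nFractions,
              bin_fraction = doseGy / scheme@nFractions)
  eqd2(doseGy, d, scheme@alphaBeta)
}

#' Build 10 Gy dose-bin contours inside the lung
#'
#' Bin b holds in-lung voxels with \code{lo <= dose < hi}; the final bin of
#' the edge set is closed at the top so the prescription isodose is not
#' orphaned. Bins are pairwise disjoint and, unioned with the sub-5 Gy
#' region, cover the lung. Bins under \code{minCc} are excluded from
#' statistics (the analysis bin width was chosen so that contour volumes
#' stay above 30 cc, keeping the measurement standard deviation below
#' 25\%); they are dropped with a warning rather than merged.
#'
#' @param dose \linkS4class{ImageGrid} of physical dose, Gy.
#' @param lung \linkS4class{BinaryMask} on the same geometry.
#' @param edges ascending bin edges, Gy; default
#'   \code{c(5, 15, 25, 35, 45, 55, 65)}.
#' @param minCc minimum bin volume for inclusion, cc (default 30).
#' @param scheme optional \linkS4class{FractionationScheme} used to fill
#'   each bin's EQD2 (prescription_fraction convention); NA otherwise.
#' @return list of \linkS4class{DoseBin} (laterality \code{"irradiated"}).
#' @export
makeDoseBins <- function(dose, lung, edges = c(5, 15, 25, 35, 45, 55, 65),
                         minCc = 30, scheme = NULL) {
  assertSameGeometry(dose, lung)
  if (any(diff(edges) <= 0)) stop("edges must be strictly ascending")
  voxCc <- prod(dose@spacing) / 1000
  bins <- list()
  for (i in seq_len(length(edges) - 1L)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    top <- i == length(edges) - 1L
    sel <- lung@values & dose@values >= lo &
      (if (top) dose@values <= hi else dose@values < hi)
    vol <- sum(sel) * voxCc
    if (vol == 0) next
    mid <- (lo + hi) / 2
    e2 <- if (is.null(scheme)) NA_real_ else binEqd2(mid, scheme)
    b <- new("DoseBin", lo = lo, hi = hi,
             mask = BinaryMask(sel, reference = dose),
             volumeCc = vol, eqd2 = e2, laterality = "irradiated",
             label = sprintf("%gGy", mid))
    if (vol < minCc) {
      warning(sprintf(
        "dose bin %s has %.1f cc (< %g cc): excluded from statistics",
        b@label, vol, minCc))
      next
    }
    bins <- c(bins, b)
  }
  bins
}

# Reflect a logical volume across the plane x = xMid (index units)
reflectX <- function(values, xMidIndex) {
  d <- dim(values)
  out <- array(FALSE, d)
  src <- which(values, arr.ind = TRUE)
  if (nrow(src) == 0L) return(out)
  xr <- round(2 * xMidIndex - src[, 1])
  keep <- xr >= 1 & xr <= d[1]
  if (!any(keep)) return(out)
  out[cbind(xr[keep], src[keep, 2], src[keep, 3])] <- TRUE
  out
}

#' Mirror dose-bin contours onto the contralateral lung as controls
#'
#' Each bin mask is reflected across the mid-sagittal plane — the plane
#' x = midpoint between the two lung-mask centroids, with voxel indices
#' reflected along the left-right axis — and intersected with the
#' contralateral lung mask. The mirrored contours sample unirradiated
#' tissue and serve as within-subject null regions, so every control mask
#' is verified to receive a maximum dose below \code{maxControlGy}.
#'
#' @param bins list of irradiated \linkS4class{DoseBin}.
#' @param leftLung,rightLung \linkS4class{BinaryMask} per-lung masks.
#' @param dose \linkS4class{ImageGrid} physical dose, Gy.
#' @param maxControlGy contamination bound for controls (default 5).
#' @return list of \linkS4class{DoseBin} with laterality \code{"control"};
#'   bins whose mirror misses the contralateral lung are dropped with a
#'   warning, and a control receiving >= \code{maxControlGy} raises an
#'   error naming the bin.
#' @export
mirrorContours <- function(bins, leftLung, rightLung, dose,
                           maxControlGy = 5) {
  assertSameGeometry(leftLung, rightLung)
  assertSameGeometry(leftLung, dose)
  cL <- mean(which(leftLung@values, arr.ind = TRUE)[, 1])
  cR <- mean(which(rightLung@values, arr.ind = TRUE)[, 1])
  xMid <- (cL + cR) / 2
  contra <- leftLung@values | rightLung@values
  out <- list()
  voxCc <- prod(dose@spacing) / 1000
  for (b in bins) {
    refl <- reflectX(b@mask@values, xMid)
    # keep only the part that lands in the lung opposite the bin's side
    src <- which(b@mask@values, arr.ind = TRUE)
    binSideLeft <- mean(src[, 1]) < xMid
    target <- if (binSideLeft) rightLung@values else leftLung@values
    m <- refl & target
    if (!any(m)) {
      warning(sprintf(
        "mirrored contour for bin %s misses the contralateral lung: dropped",
        b@label))
      next
    }
    mx <- max(dose@values[m])
    if (mx >= maxControlGy)
      stop(sprintf(
        "control contour for bin %s is contaminated: max dose %.2f Gy >= %g Gy",
        b@label, mx, maxControlGy))
    out <- c(out, new("DoseBin", lo = b@lo, hi = b@hi,
                      mask = BinaryMask(m, reference = dose),
                      volumeCc = sum(m) * voxCc, eqd2 = b@eqd2,
                      laterality = "control", label = b@label))
  }
  out
}
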