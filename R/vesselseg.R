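## Vessel segmentation from a dynamic contrast-enhanced series: MIP across
## frames, bimodal histogram of the pre-contrast frame, threshold 2 sigma
## above the soft-tissue/blood mode, strict-inequality thresholding.

#' Maximum intensity projection across the frames of a dynamic series
#'
#' The voxel-wise maximum over all frames captures peak contrast wherever
#' and whenever it occurs, compensating for the timing offset of contrast
#' flowing through different vessels. Frames are assumed co-registered
#' (registration is upstream of this pipeline).
#'
#' @param series a \linkS4class{DynamicSeries}.
#' @return An \linkS4class{ImageGrid}: the MIP.
#' @export
buildMip <- function(series) {
  stopifnot(is(series, "DynamicSeries"))
  frames <- seriesFrames(series)
  if (length(frames) == 0L) stop("empty series")
  m <- frames[[1]]@values
  for (i in seq_along(frames)[-1]) m <- pmax(m, frames[[i]]@values)
  ImageGrid(m, spacing = gridSpacing(series), origin = gridOrigin(series))
}

movingAverage3 <- function(x, w) {
  # centered moving average, zero-padded ends
  n <- length(x)
  half <- (w - 1L) %/% 2L
  xp <- c(rep(0, half), x, rep(0, half))
  s <- stats::filter(xp, rep(1 / w, w), sides = 2)
  as.numeric(s[(half + 1L):(half + n)])
}

localMaxima <- function(s) {
  n <- length(s)
  if (n < 3L) return(integer(0))
  which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n] &
          s[2:(n - 1)] > 0) + 1L
}

# 3-point parabolic vertex refinement around index i; returns c(pos, height)
parabolicVertex <- function(mid, s, i) {
  if (i <= 1L || i >= length(s)) return(c(mid[i], s[i]))
  y1 <- s[i - 1]; y2 <- s[i]; y3 <- s[i + 1]
  den <- y1 - 2 * y2 + y3
  if (abs(den) < .Machine$double.eps) return(c(mid[i], s[i]))
  d <- 0.5 * (y1 - y3) / den
  d <- max(-0.5, min(0.5, d))
  h <- y2 - 0.25 * (y1 - y3) * d
  c(mid[i] + d * (mid[2] - mid[1]), h)
}

# interpolated half-maximum crossings around peak index i -> FWHM
interpolatedFwhm <- function(mid, s, i, height) {
  half <- height / 2
  bw <- mid[2] - mid[1]
  # walk left
  l <- i
  while (l > 1L && s[l - 1] >= half) l <- l - 1L
  left <- if (l == 1L) mid[1] - bw / 2 else {
    frac <- (s[l] - half) / (s[l] - s[l - 1])
    mid[l] - frac * bw
  }
  r <- i
  n <- length(s)
  while (r < n && s[r + 1] >= half) r <- r + 1L
  right <- if (r == n) mid[n] + bw / 2 else {
    frac <- (s[r] - half) / (s[r] - s[r + 1])
    mid[r] + frac * bw
  }
  right - left
}

#' Fit the bimodal in-lung HU histogram of a pre-contrast frame
#'
#' Histograms the in-lung voxels of a pre-contrast volume (use the first
#' frame of the dynamic series, acquired before injection), smooths the
#' counts with a centred moving average, and locates the two largest local
#' maxima separated by at least \code{minSeparation} HU: mode 1 is aerated
#' parenchyma, mode 2 the soft-tissue/blood mode. The FWHM of mode 2 is
#' measured by linear interpolation of the half-maximum crossings on the
#' smoothed histogram and converted to a standard deviation by the
#' Gaussian relation FWHM = 2.35 sigma.
#'
#' Bin width, histogram span, smoothing window and minimum mode separation
#' are explicit parameters: robustness choices, not measurements.
#'
#' @param volume \linkS4class{ImageGrid}, a frame with no contrast present.
#' @param lung \linkS4class{BinaryMask} on the same geometry.
#' @param binWidth histogram bin width, HU (default 5).
#' @param range histogram span, HU (default \code{c(-1100, 300)}).
#' @param smoothBins moving-average window in bins (default 3).
#' @param minSeparation minimum HU distance between the two modes.
#' @param minRelHeight minimum height of a qualifying local maximum,
#'   relative to the tallest peak; screens out single-count noise bumps
#'   in sparse histogram tails.
#' @return A \linkS4class{ModeFit}.
#' @export
fitBimodalHistogram <- function(volume, lung, binWidth = 5,
                                range = c(-1100, 300), smoothBins = 3L,
                                minSeparation = 100, minRelHeight = 0.02) {
  assertSameGeometry(volume, lung)
  if (!any(lung@values)) stop("empty lung mask")
  v <- volume@values[lung@values]
  v <- v[v >= range[1] & v <= range[2]]
  breaks <- seq(range[1], range[2], by = binWidth)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  h <- hist(v, breaks = breaks, plot = FALSE)
  mid <- h$mids
  counts <- h$counts
  s <- movingAverage3(counts, as.integer(smoothBins))
  peaks <- localMaxima(s)
  peaks <- peaks[s[peaks] >= minRelHeight * max(s[peaks])]
  if (length(peaks) < 2L)
    stop("histogram not bimodal: fewer than two local maxima found")
  ord <- peaks[order(s[peaks], decreasing = TRUE)]
  p1 <- ord[1]
  p2 <- NA_integer_
  for (p in ord[-1]) {
    if (abs(mid[p] - mid[p1]) >= minSeparation) { p2 <- p; break }
  }
  if (is.na(p2))
    stop("histogram not bimodal: no second mode at least ", minSeparation,
         " HU from the first")
  iLo <- min(p1, p2); iHi <- max(p1, p2)
  v1 <- parabolicVertex(mid, s, iLo)
  v2 <- parabolicVertex(mid, s, iHi)
  fwhm <- interpolatedFwhm(mid, s, iHi, v2[2])
  new("ModeFit", mode1Mean = v1[1], mode2Mean = v2[1],
      mode2Fwhm = fwhm, mode2Sigma = fwhm / 2.35,
      histogram = data.frame(mid = mid, count = counts, smoothed = s))
}

#' Vessel HU threshold from a bimodal mode fit
#'
#' Two standard deviations above the mean of the second (soft-tissue/blood)
#' mode, so that voxels are classified as vessel only when elevated by
#' iodinated contrast rather than by moderately dense lung structures.
#'
#' @param fit a \linkS4class{ModeFit}.
#' @return threshold in HU: \code{mode2Mean + 2 * mode2Sigma}.
#' @examples
#' # FWHM 94 HU -> sigma 40 HU; mode at -100 HU -> threshold -20 HU
#' @export
vesselThreshold <- function(fit) {
  stopifnot(is(fit, "ModeFit"))
  fit@mode2Mean + 2 * fit@mode2Sigma
}

#' Segment vessels by thresholding the MIP within the lung
#'
#' Any voxel inside the lung mask with MIP value strictly above the
#' threshold is classified as vessel.
#'
#' @param mip \linkS4class{ImageGrid} maximum intensity projection.
#' @param lung \linkS4class{BinaryMask}.
#' @param threshold HU threshold from \code{\link{vesselThreshold}}.
#' @return \linkS4class{BinaryMask} of vessel voxels.
#' @export
segmentVessels <- function(mip, lung, threshold) {
  assertSameGeometry(mip, lung)
  BinaryMask(lung@values & (mip@values > threshold), reference = mip)
}

# 6-connected binary dilation, k iterations
dilate6 <- function(values, k) {
  d <- dim(values)
  for (it in seq_len(k)) {
    out <- values
    out[-1, , ] <- out[-1, , ] | values[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | values[-1, , ]
    out[, -1, ] <- out[, -1, ] | values[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | values[, -1, ]
    out[, , -1] <- out[, , -1] | values[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | values[, , -1]
    values <- out
  }
  values
}

#' Non-vessel lung parenchyma mask
#'
#' The lung mask with the segmented vasculature subtracted. An optional
#' 6-connected dilation of the vessel mask by \code{dilate} voxels before
#' subtraction guards against edge-voxel contamination (partial-volume
#' voxels at vessel boundaries that fall below the contrast threshold);
#' the default 0 performs the plain subtraction.
#'
#' @param lung,vessels \linkS4class{BinaryMask} objects on one geometry.
#' @param dilate non-negative integer, voxels of vessel dilation.
#' @return \linkS4class{BinaryMask} of parenchyma voxels.
#' @export
parenchymaMask <- function(lung, vessels, dilate = 0L) {
  assertSameGeometry(lung, vessels)
  v <- vessels@values & lung@values
  if (dilate > 0L) v <- dilate6(v, as.integer(dilate))
  BinaryMask(lung@values & !v, reference = lung)
}
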