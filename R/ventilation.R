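## Jacobian-determinant ventilation surrogate: det(I + grad u) maps from
## displacement fields, longitudinal Jacobian ratios, damaged-voxel
## fractions at the 0.95 threshold, and equivalent-tidal-volume phase
## selection.

# spacing-aware partial derivative of a 3D array along axis: central in
# the interior, one-sided at the boundary slabs
partialDeriv <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  if (n < 3L) stop("degenerate grid: need at least 3 voxels along each axis")
  g <- array(0, d)
  idx <- function(i) switch(axis,
                            a[i, , , drop = FALSE],
                            a[, i, , drop = FALSE],
                            a[, , i, drop = FALSE])
  assign_slab <- function(i, val) {
    if (axis == 1L) g[i, , ] <<- val
    else if (axis == 2L) g[, i, ] <<- val
    else g[, , i] <<- val
  }
  interior <- 2:(n - 1L)
  ctr <- (idx(3:n) - idx(1:(n - 2L))) / (2 * h)
  if (axis == 1L) g[interior, , ] <- ctr
  else if (axis == 2L) g[, interior, ] <- ctr
  else g[, , interior] <- ctr
  assign_slab(1L, (idx(2L) - idx(1L)) / h)
  assign_slab(n, (idx(n) - idx(n - 1L)) / h)
  g
}

#' Jacobian-determinant map of a displacement field
#'
#' Computes \code{det(I + grad u)} per voxel, with displacements in mm and
#' spacing-aware finite differences: central differences in the grid
#' interior, one-sided at the boundary slabs (boundary voxels are kept
#' rather than excluded). A determinant of 1 means no local volume
#' change, above 1 expansion, below 1 contraction; it is the standard
#' 4DCT surrogate for regional ventilation.
#'
#' @param field a \linkS4class{VectorField} (inhale-to-exhale or
#'   timepoint-to-timepoint displacement, mm).
#' @return An \linkS4class{ImageGrid} of determinants. Non-positive
#'   values (folding) are preserved here and excluded downstream by
#'   \code{\link{jacobianRatio}}.
#' @export
jacobianMap <- function(field) {
  stopifnot(is(field, "VectorField"))
  sp <- field@spacing
  u1 <- field@u[, , , 1]; u2 <- field@u[, , , 2]; u3 <- field@u[, , , 3]
  a11 <- 1 + partialDeriv(u1, 1L, sp[1])
  a12 <- partialDeriv(u1, 2L, sp[2])
  a13 <- partialDeriv(u1, 3L, sp[3])
  a21 <- partialDeriv(u2, 1L, sp[1])
  a22 <- 1 + partialDeriv(u2, 2L, sp[2])
  a23 <- partialDeriv(u2, 3L, sp[3])
  a31 <- partialDeriv(u3, 1L, sp[1])
  a32 <- partialDeriv(u3, 2L, sp[2])
  a33 <- 1 + partialDeriv(u3, 3L, sp[3])
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  ImageGrid(det, spacing = sp, origin = field@origin)
}

#' Longitudinal Jacobian ratio
#'
#' Voxel-wise \code{J_post / J_pre}. A ratio of 1 means the voxel kept its
#' pre-RT elasticity; below 1, loss of ventilation. Voxels where the
#' pre-RT Jacobian is not positive (\code{<= eps}) are marked NA and
#' excluded from downstream statistics.
#'
#' @param jPost,jPre \linkS4class{ImageGrid} Jacobian maps on one
#'   geometry.
#' @param eps positivity floor for the denominator (default 1e-6).
#' @return \linkS4class{ImageGrid} of ratios with NA at invalid voxels.
#' @export
jacobianRatio <- function(jPost, jPre, eps = 1e-6) {
  assertSameGeometry(jPost, jPre)
  r <- jPost@values / jPre@values
  r[jPre@values <= eps] <- NA_real_
  ImageGrid(r, spacing = jPre@spacing, origin = jPre@origin)
}

#' Damaged-voxel fraction at a Jacobian-ratio threshold
#'
#' The fraction of valid in-mask voxels whose Jacobian ratio is
#' \code{<=} the threshold (inclusive: a ratio of exactly 0.95 counts as
#' damaged, per the "0.95 or lower" criterion).
#'
#' @param ratio \linkS4class{ImageGrid} from \code{\link{jacobianRatio}}.
#' @param mask non-empty \linkS4class{BinaryMask}.
#' @param threshold damage threshold (default 0.95).
#' @param label bin label carried into the summary.
#' @param timepoint timepoint label.
#' @return one-row data.frame: \code{bin}, \code{timepoint},
#'   \code{fraction_damaged}, \code{n_voxels} (valid in-mask voxels),
#'   \code{n_invalid}, \code{threshold}.
#' @export
damagedFraction <- function(ratio, mask, threshold = 0.95, label = "roi",
                            timepoint = NA_character_) {
  assertSameGeometry(ratio, mask)
  idx <- mask@values
  if (!any(idx)) stop("empty mask")
  v <- ratio@values[idx]
  bad <- is.na(v)
  v <- v[!bad]
  if (length(v) == 0L) stop("no valid voxels in mask")
  data.frame(bin = label, timepoint = timepoint,
             fraction_damaged = mean(v <= threshold),
             n_voxels = length(v), n_invalid = sum(bad),
             threshold = threshold, stringsAsFactors = FALSE)
}

#' Select inhale/exhale phases by equivalent tidal volume
#'
#' Among all ordered phase pairs, picks the (larger, smaller)-volume pair
#' whose volume difference is closest to the target tidal volume;
#' selecting phases by equivalent tidal volume rather than by nominal
#' phase label improves longitudinal repeatability of the ventilation
#' measurement. Ties are broken toward the pair containing the global
#' end-exhale (minimum-volume) phase, then toward the pair listed first.
#'
#' @param phaseVolumes data.frame with columns \code{phase} (label) and
#'   \code{volume} (lung volume, L).
#' @param targetTidal target tidal volume, L.
#' @return list with \code{inhale}, \code{exhale} (phase labels) and
#'   \code{delta} (achieved volume difference, L).
#' @export
selectPhasesEtv <- function(phaseVolumes, targetTidal) {
  if (nrow(phaseVolumes) < 2L) stop("need at least 2 phases")
  v <- phaseVolumes$volume
  ph <- as.character(phaseVolumes$phase)
  exhalePhase <- ph[which.min(v)]
  best <- NULL
  for (i in seq_along(v)) {
    for (j in seq_along(v)) {
      if (v[i] <= v[j]) next   # i = inhale candidate (larger volume)
      err <- abs((v[i] - v[j]) - targetTidal)
      cand <- list(inhale = ph[i], exhale = ph[j], delta = v[i] - v[j],
                   err = err,
                   hasExhale = ph[i] == exhalePhase | ph[j] == exhalePhase)
      if (is.null(best) || err < best$err - 1e-12 ||
          (abs(err - best$err) <= 1e-12 && cand$hasExhale && !best$hasExhale))
        best <- cand
    }
  }
  if (is.null(best)) stop("no pair with distinct volumes")
  best[c("inhale", "exhale", "delta")]
}

#' Relate per-bin ventilation damage to percent HU change
#'
#' Joins damaged-voxel fractions and HU-change statistics on bin label
#' and fits damaged-percent (y) against percent HU change (x). A slope
#' near zero with dose-linear HU change and dose-flat damage indicates
#' that HU change carries information ventilation metrics do not.
#'
#' @param damage data.frame from \code{\link{damagedFraction}} rows (or
#'   any with \code{bin} and \code{fraction_damaged}).
#' @param huStats data.frame with \code{bin} and \code{mean_delta_pct}
#'   (e.g. from \code{\link{binStatistics}}).
#' @return list with \code{table} (per-bin pairs, damage in percent) and
#'   \code{fit} (a \linkS4class{LinearFit} of damaged-\% vs delta-HU-\%).
#' @export
damageVsHu <- function(damage, huStats) {
  common <- intersect(damage$bin, huStats$bin)
  if (length(common) == 0L) stop("no common bins between damage and HU stats")
  tab <- data.frame(
    bin = common,
    delta_hu_pct = huStats$mean_delta_pct[match(common, huStats$bin)],
    damaged_pct = 100 * damage$fraction_damaged[match(common, damage$bin)],
    stringsAsFactors = FALSE)
  list(table = tab, fit = linearFit(tab$delta_hu_pct, tab$damaged_pct))
}
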