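## Synthetic thorax and radiation-response generator. Produces every input
## the pipeline consumes -- anatomy, dynamic contrast series, dose grid,
## post-RT response, breathing displacement fields -- with ground truth,
## emulating the statistical structure the analysis assumes: a bimodal
## in-lung HU histogram, a gamma-variate first-pass contrast bolus, an
## SBRT-like dose distribution with >= 30 cc per 10 Gy bin and an
## unirradiated contralateral lung, a linear percent-HU-change vs EQD2
## response, vascular peak-contrast loss linearly coupled to extravascular
## HU gain, and dose-flat ventilation damage.

# evaluate expr under a temporary RNG seed, restoring global RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Phantom configuration
#'
#' Bundles every generative parameter of the synthetic thorax. The two
#' presets encode the study conditions of the emulated cohorts:
#' \code{"swine"} (60 Gy in 5 fractions to one lung, dynamic
#' contrast-enhanced series, response measured at 3 months) and
#' \code{"human"} (50 Gy in 5 fractions, static exhale volumes with two
#' replicate scans per timepoint, response scaled per timepoint).
#'
#' Selected defaults and their rationale:
#' \itemize{
#'   \item Grid 96 x 96 x 64 at 2 mm isotropic: large enough that every
#'     10 Gy bin holds >= 30 cc, small enough for minutes-scale runs.
#'   \item HU model: parenchyma mode -850 HU (sd 50), soft-tissue/blood
#'     mode +40 HU (sd 40), per-scan additive noise 10 HU. Modes separated
#'     by far more than 4 combined sd, so bimodal detection is well-posed.
#'   \item Contrast bolus: gamma-variate pulse (standard first-pass
#'     kinetics), amplitude 300 HU, injected after 4 pre-contrast frames;
#'     32 frames at 2 s spacing.
#'   \item Response: 0.167 %/Gy-EQD2 density slope; 15% systemic peak
#'     contrast reduction (the reported reduction is significant but
#'     unquantified, so the magnitude is a free parameter); in/out
#'     coupling slope -0.87; leak accounting above 25 Gy physical dose.
#'   \item Human timepoint scaling 0.785 / 0.588 / 0.955 at 3 / 6 / 12
#'     months relative to the swine 3-month response.
#'   \item Ventilation: pre-RT expansion Jacobian about 1.16; damage
#'     multiplier depth 0.12 on a damaged fraction of 0.45 per bin
#'     (dose-independent, mid-band of the observed 30-60%).
#' }
#'
#' @param preset \code{"swine"} or \code{"human"}.
#' @param seed integer seed; every generator output is a pure function of
#'   (config, seed).
#' @param ... named overrides of any top-level default listed above
#'   (e.g. \code{gridShape}, \code{hu}, \code{response}); sub-lists are
#'   merged element-wise.
#' @return A list of class \code{"PhantomConfig"}.
#' @export
phantomConfig <- function(preset = c("swine", "human"), seed = 1L, ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    seed = as.integer(seed),
    gridShape = c(96L, 96L, 64L),
    spacing = c(2, 2, 2),
    lung = list(semiAxesMm = c(32, 56, 46), sepMm = 74,
                centerYMm = 94, centerZMm = 62),
    vessels = list(nBranches = 60L, radiusRangeMm = c(1.2, 3.0),
                   hilumOffsetMm = 20),
    hu = list(mu1 = -850, sigma1 = 50, mu2 = 40, sigma2 = 40,
              sigmaNoise = 10),
    kinetics = list(amplitude = 300, t0 = 8, shape = 3, scale = 4,
                    nFrames = 32L, dt = 2, nPrecontrast = 4L),
    dose = list(rx = if (preset == "swine") 60 else 50,
                nFractions = 5, alphaBeta = 3,
                edges = if (preset == "swine") seq(5, 65, 10)
                        else seq(5, 55, 10),
                targetBinCc = 40, targetLung = "left",
                anisoMm = c(14, 40, 34), gateTauMm = 3, minCc = 30),
    response = list(slopePctPerGy = 0.167, systemicPeakReduction = 0.15,
                    cLeak = -0.87, leakOnsetGy = 25,
                    timepointScale = if (preset == "swine") c("3" = 1)
                                     else c("3" = 0.785, "6" = 0.588,
                                            "12" = 0.955)),
    damage = list(fraction = 0.45, rampWidth = 0.01, depth = 0.12,
                  blobSigmaMm = 8, minEqd2 = 20),
    breathing = list(expansion = 0.05, modAmp = 0.03),
    nReplicates = 2L)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      for (k in names(dots[[nm]])) cfg[[nm]][[k]] <- dots[[nm]][[k]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  stopifnot(cfg$hu$mu1 < cfg$hu$mu2,
            cfg$kinetics$nPrecontrast < cfg$kinetics$nFrames,
            all(cfg$damage$fraction > 0), all(cfg$damage$fraction < 1))
  sep <- cfg$hu$mu2 - cfg$hu$mu1
  if (sep <= 4 * (cfg$hu$sigma1 + cfg$hu$sigma2))
    stop("HU modes must be separated by more than 4 combined sd")
  class(cfg) <- "PhantomConfig"
  cfg
}

#' @export
print.PhantomConfig <- function(x, ...) {
  cat(sprintf(
    "PhantomConfig (%s preset, seed %d): grid %s @ %s mm, Rx %g Gy / %g fx\n",
    x$preset, x$seed, paste(x$gridShape, collapse = "x"),
    paste(x$spacing, collapse = "x"), x$dose$rx, x$dose$nFractions))
  invisible(x)
}

phantomScheme <- function(config) {
  FractionationScheme(config$dose$rx, config$dose$nFractions,
                      config$dose$alphaBeta)
}

# world coordinate vectors of voxel centres (origin 0)
gridCoords <- function(config) {
  list(x = (seq_len(config$gridShape[1]) - 1) * config$spacing[1],
       y = (seq_len(config$gridShape[2]) - 1) * config$spacing[2],
       z = (seq_len(config$gridShape[3]) - 1) * config$spacing[3])
}

lungCenters <- function(config) {
  co <- gridCoords(config)
  midX <- (co$x[1] + co$x[length(co$x)]) / 2
  list(left = c(midX - config$lung$sepMm / 2, config$lung$centerYMm,
                config$lung$centerZMm),
       right = c(midX + config$lung$sepMm / 2, config$lung$centerYMm,
                 config$lung$centerZMm),
       midX = midX)
}

ellipsoidMask <- function(co, center, semi) {
  ex <- ((co$x - center[1]) / semi[1])^2
  ey <- ((co$y - center[2]) / semi[2])^2
  ez <- ((co$z - center[3]) / semi[3])^2
  outer(outer(ex, ey, "+"), ez, "+") <= 1
}

# rasterize a vessel tree of line segments radiating from the hilum
rasterizeVessels <- function(config, center, semi, hilum) {
  d <- config$gridShape
  sp <- config$spacing
  out <- array(FALSE, d)
  rr <- config$vessels$radiusRangeMm
  for (b in seq_len(config$vessels$nBranches)) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    r <- stats::runif(1)^(1 / 3)
    end <- center + 0.85 * semi * r * u
    radius <- stats::runif(1, rr[1], rr[2])
    len <- sqrt(sum((end - hilum)^2))
    nStep <- max(2L, ceiling(len))  # ~1 mm steps
    tt <- seq(0, 1, length.out = nStep)
    pts <- cbind(hilum[1] + tt * (end[1] - hilum[1]),
                 hilum[2] + tt * (end[2] - hilum[2]),
                 hilum[3] + tt * (end[3] - hilum[3]))
    i0 <- cbind(round(pts[, 1] / sp[1]), round(pts[, 2] / sp[2]),
                round(pts[, 3] / sp[3])) + 1L
    rad <- ceiling(radius / sp)
    for (di in -rad[1]:rad[1]) for (dj in -rad[2]:rad[2])
      for (dk in -rad[3]:rad[3]) {
        if (sum((c(di, dj, dk) * sp)^2) > radius^2 + 1e-9) next
        idx <- cbind(i0[, 1] + di, i0[, 2] + dj, i0[, 3] + dk)
        ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
              idx[, 2] >= 1 & idx[, 2] <= d[2] &
              idx[, 3] >= 1 & idx[, 3] <= d[3]
        if (any(ok)) out[idx[ok, , drop = FALSE]] <- TRUE
      }
  }
  out
}

#' Generate the thorax anatomy and its ground truth
#'
#' Two ellipsoidal lungs in a soft-tissue background, with a vessel tree
#' radiating from each hilum. Parenchyma voxels draw from the aerated
#' mode (mu1), vessel and background voxels from the soft-tissue/blood
#' mode (mu2), so the in-lung histogram is bimodal by construction.
#' Deterministic given (config, seed).
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return list with \code{preRT} (an \linkS4class{ImageGrid}, the
#'   unenhanced baseline anatomy without scan noise) and \code{truth}
#'   (lung/vessel masks and bookkeeping, grown by later generator stages).
#' @export
generateAnatomy <- function(config) {
  withSeed(config$seed * 7L + 1L, {
    d <- config$gridShape
    co <- gridCoords(config)
    ctr <- lungCenters(config)
    semi <- config$lung$semiAxesMm
    lungL <- ellipsoidMask(co, ctr$left, semi)
    lungR <- ellipsoidMask(co, ctr$right, semi)
    if (!any(lungL) || !any(lungR))
      stop("lungs not constructible at the requested grid size")
    lung <- lungL | lungR
    hoff <- config$vessels$hilumOffsetMm
    vessel <- rasterizeVessels(config, ctr$left, semi,
                               ctr$left + c(hoff, 0, 0)) |
              rasterizeVessels(config, ctr$right, semi,
                               ctr$right - c(hoff, 0, 0))
    vessel <- vessel & lung
    if (!any(vessel))
      stop("vessel tree not constructible at the requested grid size")
    n <- prod(d)
    tex <- stats::rnorm(n)
    base <- array(config$hu$mu2 + config$hu$sigma2 * tex, d)
    paren <- lung & !vessel
    base[paren] <- config$hu$mu1 + config$hu$sigma1 * tex[paren]
    geom <- function(v) BinaryMask(v, spacing = config$spacing)
    truth <- list(
      lungLeft = geom(lungL), lungRight = geom(lungR), lung = geom(lung),
      vessel = geom(vessel), seed = config$seed)
    list(preRT = ImageGrid(base, spacing = config$spacing), truth = truth)
  })
}

# gamma-variate first-pass bolus, normalized to peak 1 at t0 + shape*scale
gammaVariate <- function(t, t0, shape, scale) {
  tp <- shape * scale
  trel <- t - t0
  g <- numeric(length(t))
  pos <- trel > 0
  g[pos] <- (trel[pos] / tp)^shape * exp(shape * (1 - trel[pos] / tp))
  g
}

makeDynamicSeries <- function(base, vesselMask, amp, config, seed) {
  withSeed(seed, {
    k <- config$kinetics
    times <- k$dt * (seq_len(k$nFrames) - 1)
    if (k$t0 < times[k$nPrecontrast])
      stop(sprintf(
        "contrast injection at t0 = %g s precedes pre-contrast frame %d (t = %g s)",
        k$t0, k$nPrecontrast, times[k$nPrecontrast]))
    g <- gammaVariate(times, k$t0, k$shape, k$scale)
    vIdx <- which(vesselMask)
    ampV <- if (length(amp) == 1L) rep(amp, length(vIdx)) else amp[vIdx]
    n <- length(base)
    d <- dim(base)
    frames <- vector("list", k$nFrames)
    for (i in seq_len(k$nFrames)) {
      vals <- base
      if (g[i] > 0) vals[vIdx] <- vals[vIdx] + ampV * g[i]
      if (config$hu$sigmaNoise > 0)
        vals <- vals + array(stats::rnorm(n, 0, config$hu$sigmaNoise), d)
      frames[[i]] <- ImageGrid(vals, spacing = config$spacing)
    }
    DynamicSeries(frames, times = times, nPrecontrast = k$nPrecontrast)
  })
}

#' Generate the pre-RT dynamic contrast-enhanced series
#'
#' Frames before injection carry no enhancement; thereafter, in-vessel HU
#' follows baseline + amplitude times a gamma-variate pulse normalized to
#' peak 1 (rise then fall), out-of-vessel voxels are unchanged, and every
#' frame receives independent additive scan noise.
#'
#' @param preRT baseline anatomy from \code{\link{generateAnatomy}}.
#' @param truth its truth list.
#' @param config the \code{\link{phantomConfig}}.
#' @return A \linkS4class{DynamicSeries}.
#' @export
generateDynamicSeries <- function(preRT, truth, config) {
  makeDynamicSeries(preRT@values, truth$vessel@values,
                    config$kinetics$amplitude, config,
                    config$seed * 7L + 2L)
}

#' Generate the planned dose distribution
#'
#' An SBRT-like dose field centred on a target in one lung: a monotone
#' decreasing profile of an anisotropic scaled distance u, with the
#' profile's isodose anchors placed at in-lung u-quantiles so that each
#' 10 Gy bin intersected with the irradiated lung holds a fixed target
#' volume (default 40 cc, comfortably above the 30 cc statistics floor)
#' for every seed. A logistic gate beyond the mid-sagittal plane enforces
#' the steep medial gradient of a plan designed to spare the contralateral
#' lung, which is verified to receive under 5 Gy everywhere.
#'
#' @param config the \code{\link{phantomConfig}}.
#' @param truth truth list from \code{\link{generateAnatomy}}; returned
#'   updated with the dose grid and per-voxel bin index.
#' @return list with \code{dose} (\linkS4class{ImageGrid}, Gy) and the
#'   updated \code{truth}.
#' @export
generateDose <- function(config, truth) {
  d <- config$gridShape
  co <- gridCoords(config)
  ctr <- lungCenters(config)
  side <- config$dose$targetLung
  target <- if (side == "left") ctr$left else ctr$right
  # snap the target to the nearest voxel centre so the prescription dose
  # is realized exactly at one voxel
  target <- round(target / config$spacing) * config$spacing
  ipsi <- if (side == "left") truth$lungLeft@values else truth$lungRight@values
  contra <- if (side == "left") truth$lungRight@values else truth$lungLeft@values
  an <- config$dose$anisoMm
  ux <- ((co$x - target[1]) / an[1])^2
  uy <- ((co$y - target[2]) / an[2])^2
  uz <- ((co$z - target[3]) / an[3])^2
  u <- sqrt(outer(outer(ux, uy, "+"), uz, "+"))
  edges <- config$dose$edges
  nb <- length(edges) - 1L
  voxCc <- prod(config$spacing) / 1000
  nPerBin <- round(config$dose$targetBinCc / voxCc)
  uLung <- sort(u[ipsi])
  if (length(uLung) < nb * nPerBin)
    stop("cannot satisfy the per-bin volume constraint: irradiated lung ",
         "holds only ", round(length(uLung) * voxCc), " cc")
  anchorsU <- uLung[seq_len(nb) * nPerBin]
  anchorsD <- rev(edges[-length(edges)])           # 55, 45, ..., 5
  tailU <- anchorsU[nb] + 2 * (anchorsU[nb] - anchorsU[nb - 1L])
  profU <- c(0, anchorsU, tailU)
  profD <- c(config$dose$rx, anchorsD, 0)
  dose <- array(stats::approx(profU, profD, xout = as.numeric(u),
                              rule = 2)$y, d)
  # medial gate: exactly 1 up to the mid-sagittal plane, logistic beyond
  sgn <- if (side == "left") 1 else -1
  gate <- pmin(1, 2 / (1 + exp(sgn * (co$x - ctr$midX) /
                                 config$dose$gateTauMm)))
  dose <- dose * rep(gate, times = d[2] * d[3])
  if (max(dose[contra]) >= 5)
    stop("contralateral lung receives >= 5 Gy: dose model misconfigured")
  lungV <- truth$lung@values
  binIdx <- array(0L, d)
  for (i in seq_len(nb)) {
    top <- i == nb
    sel <- lungV & dose >= edges[i] &
      (if (top) dose <= edges[i + 1L] else dose < edges[i + 1L])
    vol <- sum(sel) * voxCc
    if (vol < config$dose$minCc)
      stop(sprintf("dose bin [%g,%g) holds %.1f cc < %g cc",
                   edges[i], edges[i + 1L], vol, config$dose$minCc))
    binIdx[sel] <- i
  }
  doseGrid <- ImageGrid(dose, spacing = config$spacing)
  truth$dose <- doseGrid
  truth$binIdx <- binIdx
  truth$binMid <- (edges[-length(edges)] + edges[-1]) / 2
  truth$binLabels <- sprintf("%gGy", truth$binMid)
  list(dose = doseGrid, truth = truth)
}

# density response shared by swine and human paths: out-of-vessel voxels
# in bin b gain slope*EQD2(b)/100*|baseline|; sub-5 Gy voxels unchanged
applyDensityResponse <- function(base, truth, config, scale) {
  sch <- phantomScheme(config)
  gPct <- scale * config$response$slopePctPerGy * binEqd2(truth$binMid, sch)
  post <- base
  idx <- which(truth$lung@values & !truth$vessel@values & truth$binIdx > 0L)
  b <- truth$binIdx[idx]
  post[idx] <- post[idx] + gPct[b] / 100 * abs(post[idx])
  list(post = post, gPct = gPct)
}

#' Apply the radiation response and generate the post-RT series
#'
#' Encodes the measured post-RT structure: (i) out-of-vessel voxels in
#' dose bin b gain \code{slope * EQD2(b) / 100 * |baseline|}; (ii) the
#' in-vessel peak enhancement is reduced systemically (both lungs) by the
#' configured fraction; (iii) across irradiated bins the in-vessel peak
#' percent change follows \code{-systemic + cLeak * outOfVesselPct}, the
#' linear coupling of vascular contrast loss to extravascular gain; for
#' bins above the leak-onset dose the truth ledger attributes to leakage
#' exactly the HU volume removed from the vessel pool, conserving
#' contrast-attributable HU x volume between compartments; (iv) voxels
#' below 5 Gy receive zero density response.
#'
#' @param preRT baseline anatomy grid.
#' @param seriesPre pre-RT dynamic series (geometry reference).
#' @param dose dose grid from \code{\link{generateDose}}.
#' @param truth truth list (after \code{generateDose}).
#' @param config the \code{\link{phantomConfig}}.
#' @param timepoint months post-RT as character (\code{"3"}, \code{"6"},
#'   \code{"12"}); must have a configured response scaling.
#' @return list with \code{postRT} (\linkS4class{ImageGrid}),
#'   \code{seriesPost} (\linkS4class{DynamicSeries}) and updated
#'   \code{truth} carrying the per-bin true out-of-vessel percent change
#'   (\code{trueOutDeltaPct}), true in-vessel peak percent change
#'   (\code{truePeakDeltaPct}) and the leak conservation ledger.
#' @export
applyRadiationResponse <- function(preRT, seriesPre, dose, truth, config,
                                   timepoint = "3") {
  ts <- config$response$timepointScale
  if (!timepoint %in% names(ts))
    stop("no response scaling configured for timepoint '", timepoint, "'")
  f <- ts[[timepoint]]
  assertSameGeometry(preRT, dose)
  dr <- applyDensityResponse(preRT@values, truth, config, f)
  post <- dr$post
  gPct <- dr$gPct
  sysPct <- 100 * config$response$systemicPeakReduction * f
  nb <- length(truth$binMid)
  peakPct <- -sysPct + config$response$cLeak * gPct   # irradiated bins
  A <- config$kinetics$amplitude
  vessel <- truth$vessel@values
  amp <- array(A, dim(post))
  voxCc <- prod(config$spacing) / 1000
  leakOut <- rep(0, nb)
  for (b in seq_len(nb)) {
    vb <- vessel & truth$binIdx == b
    if (!any(vb)) next
    peakPre <- mean(post[vb]) + A    # vessel baseline is unchanged post-RT
    amp[vb] <- A + peakPre * peakPct[b] / 100
    if (truth$binMid[b] > config$response$leakOnsetGy)
      leakOut[b] <- -(config$response$cLeak * gPct[b]) / 100 * peakPre *
        sum(vb) * voxCc
  }
  v0 <- vessel & truth$binIdx == 0L
  if (any(v0)) {
    peakPre0 <- mean(post[v0]) + A
    amp[v0] <- A + peakPre0 * (-sysPct) / 100
  }
  seriesPost <- makeDynamicSeries(post, vessel, amp, config,
                                  config$seed * 7L + 3L)
  truth$ampPost <- amp   # kept so replicate scans can be regenerated
  truth$timepoint <- timepoint
  truth$responseScale <- f
  truth$trueOutDeltaPct <- gPct
  truth$truePeakDeltaPct <- peakPct
  truth$leakOutHuCc <- leakOut
  truth$leakInDeficitHuCc <- sum(leakOut)
  list(postRT = ImageGrid(post, spacing = config$spacing),
       seriesPost = seriesPost, truth = truth)
}

# separable Gaussian smoothing by shift-weighted sums
gaussSmooth3d <- function(a, sigmaVox) {
  rad <- max(1L, ceiling(3 * sigmaVox))
  w <- stats::dnorm(-rad:rad, sd = sigmaVox)
  w <- w / sum(w)
  d <- dim(a)
  for (axis in 1:3) {
    out <- array(0, d)
    n <- d[axis]
    for (k in -rad:rad) {
      src <- pmin(pmax(seq_len(n) + k, 1L), n)  # replicate-pad edges
      sl <- switch(axis, a[src, , , drop = FALSE],
                   a[, src, , drop = FALSE], a[, , src, drop = FALSE])
      out <- out + w[k + rad + 1L] * sl
    }
    a <- out
  }
  a
}

# x-displacement whose interior central differences reproduce target
# d(ux)/dx = a exactly: v[i+1] = v[i-1] + 2h a[i]
chainIntegrateX <- function(a, h) {
  d <- dim(a)
  v <- array(0, d)
  v[2, , ] <- h * a[1, , ]
  for (i in 2:(d[1] - 1L)) v[i + 1L, , ] <- v[i - 1L, , ] + 2 * h * a[i, , ]
  v
}

#' Generate breathing displacement fields (and the damage pattern)
#'
#' The pre-RT inhale-to-exhale field is a smooth expansion (Jacobian
#' about 1.16 within the lung, modulated a few percent spatially). The
#' post-RT field multiplies the local Jacobian by a damage factor
#' \code{1 - depth} (default 0.88) on a damaged-voxel mask that covers
#' the configured fraction of every irradiated bin above the minimum
#' EQD2, leaving other voxels unchanged: radiation stiffens damaged
#' tissue, so its Jacobian ratio drops below the 0.95 damage criterion
#' while undamaged tissue stays within 2\% of its pre-RT elasticity.
#' The damaged regions are spatially coherent blobs (thresholded smoothed
#' noise); a narrow transition ramp (1\% of each bin's voxels) keeps the
#' displacement integrable. The damage factor is realized through an
#' x-displacement constructed so that interior central differences of
#' the field reproduce the target Jacobian exactly.
#'
#' @param truth truth list (after \code{\link{generateDose}}; the
#'   \code{"post"} epoch adds \code{damagedMask} to it).
#' @param config the \code{\link{phantomConfig}}.
#' @param epoch \code{"pre"} or \code{"post"}.
#' @return list with \code{field} (a \linkS4class{VectorField}),
#'   \code{phaseVolumes} (data.frame of per-phase lung volumes in L,
#'   supporting equivalent-tidal-volume phase selection) and the updated
#'   \code{truth}.
#' @export
generateBreathingFields <- function(truth, config, epoch = c("pre", "post")) {
  epoch <- match.arg(epoch)
  d <- config$gridShape
  sp <- config$spacing
  co <- gridCoords(config)
  ctr <- lungCenters(config)
  cen <- c(ctr$midX, config$lung$centerYMm, config$lung$centerZMm)
  gam <- config$breathing$expansion
  LX <- co$x[d[1]]; LY <- co$y[d[2]]; LZ <- co$z[d[3]]
  delta <- config$breathing$modAmp *
    outer(outer(sin(2 * pi * co$x / LX), sin(2 * pi * co$y / LY)),
          sin(2 * pi * co$z / LZ))
  m <- array(1, d)
  if (epoch == "post") {
    if (is.null(truth$binIdx))
      stop("post-RT fields need the dose bins: run generateDose first")
    sch <- phantomScheme(config)
    binE <- binEqd2(truth$binMid, sch)
    frac <- rep(config$damage$fraction, length.out = length(truth$binMid))
    blob <- withSeed(config$seed * 7L + 4L, {
      gaussSmooth3d(array(stats::rnorm(prod(d)), d),
                    config$damage$blobSigmaMm / sp[1])
    })
    damaged <- array(FALSE, d)
    for (b in seq_along(truth$binMid)) {
      if (binE[b] <= config$damage$minEqd2) next
      idx <- which(truth$binIdx == b)
      if (length(idx) < 10L) next
      vals <- blob[idx]
      q <- frac[b]
      tHi <- stats::quantile(vals, 1 - q, type = 1, names = FALSE)
      tLo <- stats::quantile(vals, max(0, 1 - q - config$damage$rampWidth),
                             type = 1, names = FALSE)
      if (tHi <= tLo) tLo <- tHi - 1e-9
      g <- pmin(1, pmax(0, (vals - tLo) / (tHi - tLo)))
      m[idx] <- 1 - config$damage$depth * g
      damaged[idx[vals > tHi]] <- TRUE
    }
    truth$damagedMask <- BinaryMask(damaged, spacing = sp)
    truth$damagedFracTarget <- frac
  }
  # det(I + grad u) = (1+gam)^2 (1 + gam + dvx/dx) with
  # dvx/dx = (1+gam)((1+delta) m - 1)  =>  J = (1+gam)^3 (1+delta) m
  a <- (1 + gam) * ((1 + delta) * m - 1)
  v <- chainIntegrateX(a, sp[1])
  X <- array(rep(co$x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(co$y, each = d[1]), times = d[3]), d)
  Z <- array(rep(co$z, each = d[1] * d[2]), d)
  u <- array(0, c(d, 3L))
  u[, , , 1] <- gam * (X - cen[1]) + v
  u[, , , 2] <- gam * (Y - cen[2])
  u[, , , 3] <- gam * (Z - cen[3])
  field <- VectorField(u, spacing = sp)
  lungL <- maskVolumeCc(truth$lung) / 1000
  jMean <- (1 + gam)^3 * mean((1 + delta[truth$lung@values]) *
                                m[truth$lung@values])
  phases <- data.frame(
    phase = c("0%in", "25%", "50%", "75%", "100%ex"),
    volume = lungL * (1 + (jMean - 1) * c(1, 0.8, 0.45, 0.15, 0)))
  list(field = field, phaseVolumes = phases, truth = truth)
}

#' Simulate one swine subject end to end
#'
#' Anatomy, planned dose, pre-RT dynamic series, 3-month post-RT response
#' with its dynamic series, and pre/post breathing fields, all on one
#' geometry and deterministic given (config, seed).
#'
#' @param seed subject seed.
#' @param config optional \code{\link{phantomConfig}} (swine preset built
#'   from \code{seed} when omitted).
#' @return list: \code{config}, \code{preRT}, \code{postRT},
#'   \code{seriesPre}, \code{seriesPost}, \code{dose}, \code{fieldPre},
#'   \code{fieldPost}, \code{phaseVolumes}, \code{truth}.
#' @export
simulateSwineSubject <- function(seed, config = NULL) {
  if (is.null(config)) config <- phantomConfig("swine", seed = seed)
  an <- generateAnatomy(config)
  dg <- generateDose(config, an$truth)
  seriesPre <- generateDynamicSeries(an$preRT, dg$truth, config)
  rr <- applyRadiationResponse(an$preRT, seriesPre, dg$dose, dg$truth,
                               config, timepoint = "3")
  fp <- generateBreathingFields(rr$truth, config, epoch = "pre")
  fq <- generateBreathingFields(fp$truth, config, epoch = "post")
  list(config = config, preRT = an$preRT, postRT = rr$postRT,
       seriesPre = seriesPre, seriesPost = rr$seriesPost, dose = dg$dose,
       fieldPre = fp$field, fieldPost = fq$field,
       phaseVolumes = fp$phaseVolumes, truth = fq$truth)
}

#' Simulate one human subject (static exhale volumes, replicate scans)
#'
#' Humans receive no contrast-enhanced series: the HU analysis runs on
#' exhalation-phase volumes, two replicate scans per timepoint (acquired
#' minutes apart, modeled as independent noise draws of one state). The
#' post-RT density response is the swine relation scaled by the
#' configured per-timepoint factor.
#'
#' @param seed subject seed.
#' @param timepoint \code{"3"}, \code{"6"} or \code{"12"} (months).
#' @param config optional \code{\link{phantomConfig}} (human preset built
#'   from \code{seed} when omitted).
#' @return list: \code{config}, \code{scansPre}, \code{scansPost} (lists
#'   of \linkS4class{ImageGrid} replicates), \code{dose},
#'   \code{fieldPre}, \code{fieldPost}, \code{phaseVolumes},
#'   \code{truth}.
#' @export
simulateHumanSubject <- function(seed, timepoint = "12", config = NULL) {
  if (is.null(config)) config <- phantomConfig("human", seed = seed)
  ts <- config$response$timepointScale
  if (!timepoint %in% names(ts))
    stop("no response scaling configured for timepoint '", timepoint, "'")
  an <- generateAnatomy(config)
  dg <- generateDose(config, an$truth)
  truth <- dg$truth
  dr <- applyDensityResponse(an$preRT@values, truth, config, ts[[timepoint]])
  truth$timepoint <- timepoint
  truth$responseScale <- ts[[timepoint]]
  truth$trueOutDeltaPct <- dr$gPct
  d <- config$gridShape
  snap <- function(base, seed) withSeed(seed, {
    lapply(seq_len(config$nReplicates), function(i) {
      ImageGrid(base + array(stats::rnorm(prod(d), 0, config$hu$sigmaNoise),
                             d),
                spacing = config$spacing)
    })
  })
  scansPre <- snap(an$preRT@values, config$seed * 7L + 5L)
  scansPost <- snap(dr$post, config$seed * 7L + 6L)
  fp <- generateBreathingFields(truth, config, epoch = "pre")
  fq <- generateBreathingFields(fp$truth, config, epoch = "post")
  list(config = config, scansPre = scansPre, scansPost = scansPost,
       dose = dg$dose, fieldPre = fp$field, fieldPost = fq$field,
       phaseVolumes = fp$phaseVolumes, truth = fq$truth)
}
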