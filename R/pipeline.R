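## End-to-end orchestration: run the segmentation -> dose-bin -> HU-change
## -> ventilation -> cross-cohort chain on phantom subjects and aggregate
## cohort-level statistics.

#' Build irradiated and mirrored-control dose bins for a subject
#'
#' @param dose dose grid, Gy.
#' @param truth truth list holding the lung masks.
#' @param config the subject's \code{\link{phantomConfig}}.
#' @return list with \code{irradiated} and \code{control} DoseBin lists.
#' @export
binsForSubject <- function(dose, truth, config) {
  scheme <- phantomScheme(config)
  bins <- makeDoseBins(dose, truth$lung, edges = config$dose$edges,
                       minCc = config$dose$minCc, scheme = scheme)
  controls <- mirrorContours(bins, truth$lungLeft, truth$lungRight, dose)
  list(irradiated = bins, control = controls)
}

measureBin <- function(series, mask, label) {
  tr <- extractTrace(series, mask, label = label)
  c(baseline = baselineHu(tr), peak = peakHu(tr))
}

#' Analyze one swine subject: segmentation, bins, per-contour measurements
#'
#' Runs the full measurement chain on a simulated swine: fits the bimodal
#' histogram of the pre-contrast frame, derives the vessel threshold,
#' segments vessels on the MIP of the pre-RT series, subtracts them to
#' get parenchyma, builds the 10 Gy dose bins plus mirrored contralateral
#' controls, and records baseline (and, for vessels, peak) HU per
#' contour, compartment and timepoint. Vessel and parenchyma contours
#' are derived once from the pre-RT series and carried to the co-registered
#' post-RT series.
#'
#' @param subject output of \code{\link{simulateSwineSubject}}.
#' @param subjectId label for the subject column.
#' @param dilate vessel dilation in voxels before subtraction (default 0).
#' @return data.frame with columns subject, timepoint (\code{"pre"} /
#'   months), bin, laterality, compartment, eqd2, volume_cc, n_voxels,
#'   baseline_hu, peak_hu, plus attributes \code{modeFit},
#'   \code{threshold}, \code{vessels} and \code{dice} (Dice coefficient
#'   of the segmentation against the phantom's true vessel mask).
#' @export
analyzeSwineSubject <- function(subject, subjectId = "s1", dilate = 0L) {
  truth <- subject$truth
  config <- subject$config
  fit <- fitBimodalHistogram(seriesFrame(subject$seriesPre, 1L), truth$lung)
  thr <- vesselThreshold(fit)
  mip <- buildMip(subject$seriesPre)
  vessels <- segmentVessels(mip, truth$lung, thr)
  paren <- parenchymaMask(truth$lung, vessels, dilate = dilate)
  bb <- binsForSubject(subject$dose, truth, config)
  allBins <- c(bb$irradiated, bb$control)
  rows <- list()
  for (b in allBins) {
    for (comp in c("parenchyma", "vessel")) {
      cm <- if (comp == "parenchyma") paren else vessels
      m <- BinaryMask(b@mask@values & cm@values, reference = b@mask)
      nv <- sum(m@values)
      if (nv == 0L) next
      for (tp in c("pre", truth$timepoint)) {
        ser <- if (tp == "pre") subject$seriesPre else subject$seriesPost
        v <- measureBin(ser, m, b@label)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subjectId, timepoint = tp, bin = b@label,
          laterality = b@laterality, compartment = comp, eqd2 = b@eqd2,
          volume_cc = b@volumeCc, n_voxels = nv,
          baseline_hu = v[["baseline"]], peak_hu = v[["peak"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tv <- truth$vessel@values
  sv <- vessels@values
  attr(out, "dice") <- 2 * sum(tv & sv) / (sum(tv) + sum(sv))
  attr(out, "modeFit") <- fit
  attr(out, "threshold") <- thr
  attr(out, "vessels") <- vessels
  out
}

#' Per-bin percent HU changes for one cohort measurement table
#'
#' Parenchyma change uses the pre-contrast baseline HU; vessel change
#' uses the peak (contrast-maximum) HU.
#'
#' @param measurements per-subject measurement data.frame (one row per
#'   subject/timepoint/bin/compartment, replicates already averaged).
#' @param timepointPost post-RT timepoint label.
#' @param convention percent-change convention
#'   (\code{\link{deltaHuPercent}}).
#' @return data.frame: subject, bin, laterality, compartment, eqd2,
#'   delta_pct.
#' @export
cohortDeltas <- function(measurements, timepointPost,
                         convention = "magnitude") {
  pre <- measurements[measurements$timepoint == "pre", , drop = FALSE]
  post <- measurements[measurements$timepoint == timepointPost, ,
                       drop = FALSE]
  key <- function(d) paste(d$subject, d$bin, d$laterality, d$compartment)
  i <- match(key(pre), key(post))
  ok <- !is.na(i)
  pre <- pre[ok, , drop = FALSE]
  post <- post[i[ok], , drop = FALSE]
  val <- ifelse(pre$compartment == "vessel", pre$peak_hu, pre$baseline_hu)
  valPost <- ifelse(post$compartment == "vessel", post$peak_hu,
                    post$baseline_hu)
  data.frame(subject = pre$subject, bin = pre$bin,
             laterality = pre$laterality, compartment = pre$compartment,
             eqd2 = pre$eqd2,
             delta_pct = deltaHuPercent(val, valPost, convention),
             stringsAsFactors = FALSE)
}

#' Run and aggregate a swine cohort
#'
#' Simulates one swine per seed, runs \code{\link{analyzeSwineSubject}}
#' on each, and aggregates: per-bin cohort means of the out-of-vessel
#' percent HU change and the in-vessel peak percent change, the
#' dose-response fit of out-of-vessel change against bin EQD2, the
#' in/out coupling fit, the contralateral-control summary, and the
#' per-bin paired statistics.
#'
#' @param seeds integer vector, one subject per seed.
#' @param configFn function(seed) returning the subject's
#'   \code{\link{phantomConfig}}; defaults to the swine preset.
#' @return list: \code{measurements}, \code{deltas}, \code{perBin}
#'   (irradiated bins: \code{out_pct}, \code{in_pct}, \code{eqd2}),
#'   \code{doseResponseFit} (\linkS4class{LinearFit}), \code{coupling}
#'   (fit + reduction correlation), \code{controlPerBin},
#'   \code{controlMaxAbsPct}, \code{binStats}, \code{dice} (per
#'   subject).
#' @export
runSwineCohort <- function(seeds = 1:5, configFn = NULL) {
  if (is.null(configFn))
    configFn <- function(seed) phantomConfig("swine", seed = seed)
  meas <- list()
  dice <- numeric(0)
  tp <- NULL
  for (s in seeds) {
    subj <- simulateSwineSubject(s, configFn(s))
    m <- analyzeSwineSubject(subj, subjectId = sprintf("swine%02d", s))
    dice <- c(dice, attr(m, "dice"))
    tp <- subj$truth$timepoint
    meas[[length(meas) + 1L]] <- m
    rm(subj)
  }
  measurements <- do.call(rbind, meas)
  deltas <- cohortDeltas(measurements, timepointPost = tp)
  irr <- deltas[deltas$laterality == "irradiated", , drop = FALSE]
  perBin <- aggregateBins(irr)
  ctl <- deltas[deltas$laterality == "control" &
                  deltas$compartment == "parenchyma", , drop = FALSE]
  ctlBin <- stats::aggregate(delta_pct ~ bin + eqd2, data = ctl, FUN = mean)
  fit <- linearFit(perBin$eqd2, perBin$out_pct)
  coupling <- vesselCouplingFit(perBin$out_pct, perBin$in_pct)
  stats <- binStatistics(measurements, timepointPre = "pre",
                         timepointPost = tp, compartment = "parenchyma")
  list(measurements = measurements, deltas = deltas, perBin = perBin,
       doseResponseFit = fit, coupling = coupling,
       controlPerBin = ctlBin,
       controlMaxAbsPct = max(abs(ctlBin$delta_pct)),
       binStats = stats, dice = dice, timepoint = tp)
}

aggregateBins <- function(irrDeltas) {
  out <- stats::aggregate(delta_pct ~ bin + eqd2,
                          data = irrDeltas[irrDeltas$compartment ==
                                             "parenchyma", ], FUN = mean)
  names(out)[names(out) == "delta_pct"] <- "out_pct"
  ves <- stats::aggregate(delta_pct ~ bin,
                          data = irrDeltas[irrDeltas$compartment ==
                                             "vessel", ], FUN = mean)
  out$in_pct <- ves$delta_pct[match(out$bin, ves$bin)]
  out[order(out$eqd2), , drop = FALSE]
}

#' Analyze one human subject (exhale volumes, replicate averaging)
#'
#' Humans have no contrast series and no vessel subtraction: the
#' measurement is the mean HU of each dose contour on the
#' exhalation-phase volume, averaged over the two replicate scans of
#' each timepoint.
#'
#' @param subject output of \code{\link{simulateHumanSubject}}.
#' @param subjectId label.
#' @return data.frame with one row per timepoint and bin (compartment
#'   \code{"lung"}), replicates averaged.
#' @export
analyzeHumanSubject <- function(subject, subjectId = "h1") {
  truth <- subject$truth
  config <- subject$config
  bins <- binsForSubject(subject$dose, truth, config)$irradiated
  rows <- list()
  scans <- list(pre = subject$scansPre)
  scans[[truth$timepoint]] <- subject$scansPost
  for (b in bins) {
    idx <- which(b@mask@values)
    for (tp in names(scans)) {
      for (r in seq_along(scans[[tp]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subjectId, timepoint = tp, bin = b@label,
          laterality = b@laterality, compartment = "lung", eqd2 = b@eqd2,
          volume_cc = b@volumeCc, replicate = r,
          baseline_hu = mean(scans[[tp]][[r]]@values[idx]),
          stringsAsFactors = FALSE)
      }
    }
  }
  averageReplicates(do.call(rbind, rows))
}

#' Run and aggregate a human cohort at one timepoint
#'
#' @param seeds integer vector, one subject per seed.
#' @param timepoint \code{"3"}, \code{"6"} or \code{"12"} months.
#' @param configFn function(seed) returning the subject's config;
#'   defaults to the human preset.
#' @return list: \code{measurements}, \code{deltas}, \code{perBin} (bin,
#'   eqd2, mean percent change), \code{doseResponseFit},
#'   \code{binStats}, \code{timepoint}.
#' @export
runHumanCohort <- function(seeds = 1:11, timepoint = "12",
                           configFn = NULL) {
  if (is.null(configFn))
    configFn <- function(seed) phantomConfig("human", seed = seed)
  meas <- list()
  for (s in seeds) {
    subj <- simulateHumanSubject(s, timepoint, configFn(s))
    meas[[length(meas) + 1L]] <-
      analyzeHumanSubject(subj, subjectId = sprintf("human%02d", s))
    rm(subj)
  }
  measurements <- do.call(rbind, meas)
  deltas <- cohortDeltas(measurements, timepointPost = timepoint)
  perBin <- stats::aggregate(delta_pct ~ bin + eqd2, data = deltas,
                             FUN = mean)
  perBin <- perBin[order(perBin$eqd2), , drop = FALSE]
  stats <- binStatistics(measurements, timepointPre = "pre",
                         timepointPost = timepoint, compartment = "lung")
  list(measurements = measurements, deltas = deltas, perBin = perBin,
       doseResponseFit = linearFit(perBin$eqd2, perBin$delta_pct),
       binStats = stats, timepoint = timepoint)
}

#' Swine-human comparison from cohort results
#'
#' Builds the EQD2-matched adjusted swine dataset from the swine
#' dose-response fit and regresses the human per-bin changes on it.
#'
#' @param swine result of \code{\link{runSwineCohort}}.
#' @param human result of \code{\link{runHumanCohort}}.
#' @return list: \code{adjusted} (data.frame), \code{fit}
#'   (\linkS4class{LinearFit} of human vs adjusted swine).
#' @export
compareCohorts <- function(swine, human) {
  adj <- adjustedSwine(swine$doseResponseFit, human$perBin$eqd2)
  adj$human_pct <- human$perBin$delta_pct
  list(adjusted = adj,
       fit = crossCohortCorrelation(adj$swine_pred, adj$human_pct))
}

#' Per-bin ventilation damage for one subject
#'
#' Jacobian maps of the pre and post breathing fields, their ratio, and
#' the damaged-voxel fraction (ratio <= threshold) per irradiated dose
#' bin.
#'
#' @param subject a simulated subject carrying \code{fieldPre},
#'   \code{fieldPost}, \code{dose}, \code{truth}, \code{config}.
#' @param threshold Jacobian-ratio damage threshold (default 0.95).
#' @return data.frame of \code{\link{damagedFraction}} rows, one per
#'   irradiated bin, plus an \code{eqd2} column.
#' @export
measureVentilationDamage <- function(subject, threshold = 0.95) {
  jPre <- jacobianMap(subject$fieldPre)
  jPost <- jacobianMap(subject$fieldPost)
  ratio <- jacobianRatio(jPost, jPre)
  bins <- binsForSubject(subject$dose, subject$truth,
                         subject$config)$irradiated
  rows <- lapply(bins, function(b) {
    r <- damagedFraction(ratio, b@mask, threshold = threshold,
                         label = b@label,
                         timepoint = subject$truth$timepoint)
    r$eqd2 <- b@eqd2
    r
  })
  do.call(rbind, rows)
}

#' Regenerate the scan-noise realization of a swine subject
#'
#' Re-draws the additive scan noise of both dynamic series with a new
#' seed while keeping anatomy, dose and response fixed: a replicate
#' acquisition of the same physical state, used to characterize
#' measurement repeatability.
#'
#' @param subject output of \code{\link{simulateSwineSubject}}.
#' @param replicateSeed seed for the new noise draws.
#' @return the subject with \code{seriesPre}/\code{seriesPost} replaced.
#' @export
regenerateScanNoise <- function(subject, replicateSeed) {
  config <- subject$config
  truth <- subject$truth
  subject$seriesPre <- makeDynamicSeries(
    subject$preRT@values, truth$vessel@values, config$kinetics$amplitude,
    config, replicateSeed * 2L + 1L)
  subject$seriesPost <- makeDynamicSeries(
    subject$postRT@values, truth$vessel@values, truth$ampPost,
    config, replicateSeed * 2L + 2L)
  subject
}
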