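test_that("generators are deterministic given (config, seed)", {
  cfg <- tinyConfig("swine", seed = 3)
  a1 <- generateAnatomy(cfg)
  a2 <- generateAnatomy(cfg)
  expect_identical(gridValues(a1$preRT), gridValues(a2$preRT))
  expect_identical(gridValues(a1$truth$vessel), gridValues(a2$truth$vessel))
  s1 <- generateDynamicSeries(a1$preRT, a1$truth, cfg)
  s2 <- generateDynamicSeries(a2$preRT, a2$truth, cfg)
  expect_identical(gridValues(seriesFrame(s1, 7)),
                   gridValues(seriesFrame(s2, 7)))
  # a different seed changes the realization
  a3 <- generateAnatomy(tinyConfig("swine", seed = 4))
  expect_false(identical(gridValues(a1$preRT), gridValues(a3$preRT)))
})

test_that("noiseless degenerate anatomy puts every parenchyma voxel exactly at mu1", {
  cfg <- tinyConfig("swine", seed = 1,
                    hu = list(sigma1 = 0, sigma2 = 0, sigmaNoise = 0))
  an <- generateAnatomy(cfg)
  paren <- gridValues(an$truth$lung) & !gridValues(an$truth$vessel)
  expect_true(all(gridValues(an$preRT)[paren] == cfg$hu$mu1))
  expect_true(all(gridValues(an$preRT)[gridValues(an$truth$vessel)] ==
                    cfg$hu$mu2))
})

test_that("pre-contrast frames carry no enhancement and the bolus peaks at baseline + amplitude", {
  subj <- tinySwine(1)
  cfg <- subj$config
  vtr <- extractTrace(subj$seriesPre, subj$truth$vessel)
  base <- mean(gridValues(subj$preRT)[gridValues(subj$truth$vessel)])
  nv <- sum(gridValues(subj$truth$vessel))
  tol <- 6 * cfg$hu$sigmaNoise / sqrt(nv)
  # frames up to nPrecontrast sit at baseline
  expect_true(all(abs(traceMeanHu(vtr)[1:cfg$kinetics$nPrecontrast] - base)
                  < tol))
  # the gamma-variate peak is sampled on the frame grid: peak = base + A
  expect_equal(peakHu(vtr), base + cfg$kinetics$amplitude,
               tolerance = tol / abs(base))
  # trace rises after injection then falls
  mh <- traceMeanHu(vtr)
  expect_gt(max(mh), mh[1] + 0.5 * cfg$kinetics$amplitude)
  expect_lt(mh[length(mh)], max(mh) - 0.5 * cfg$kinetics$amplitude)
})

test_that("zero bolus amplitude leaves all frames at the anatomy within noise", {
  cfg <- tinyConfig("swine", seed = 2,
                    kinetics = list(amplitude = 0, nFrames = 8L))
  an <- generateAnatomy(cfg)
  ser <- generateDynamicSeries(an$preRT, an$truth, cfg)
  lungIdx <- which(gridValues(an$truth$lung))
  for (i in c(1L, 5L, 8L)) {
    dv <- gridValues(seriesFrame(ser, i))[lungIdx] -
      gridValues(an$preRT)[lungIdx]
    expect_lt(abs(mean(dv)), 6 * cfg$hu$sigmaNoise / sqrt(length(lungIdx)))
    expect_lt(abs(sd(dv) - cfg$hu$sigmaNoise), 1)
  }
})

test_that("injection before the last pre-contrast frame is rejected", {
  cfg <- tinyConfig("swine", seed = 1, kinetics = list(t0 = 2))
  an <- generateAnatomy(cfg)
  expect_error(generateDynamicSeries(an$preRT, an$truth, cfg), "precedes")
})

test_that("dose model: prescription at the target, clean contralateral lung, full-volume bins", {
  subj <- tinySwine(1)
  cfg <- subj$config
  dv <- gridValues(subj$dose)
  expect_equal(max(dv), cfg$dose$rx)
  # the maximum sits at the target centre voxel
  expect_equal(dv[which.max(dv)], cfg$dose$rx)
  expect_lt(max(dv[gridValues(subj$truth$lungRight)]), 5)
  voxCc <- prod(cfg$spacing) / 1000
  for (b in seq_along(subj$truth$binMid)) {
    vol <- sum(subj$truth$binIdx == b) * voxCc
    expect_gte(vol, cfg$dose$minCc)
  }
  # monotone falloff along the +y ray from the target centre
  ctrIdx <- which(dv == cfg$dose$rx, arr.ind = TRUE)[1, ]
  ray <- dv[ctrIdx[1], ctrIdx[2]:dim(dv)[2], ctrIdx[3]]
  expect_true(all(diff(ray) <= 1e-9))
})

test_that("radiation response: per-bin truth follows slope * EQD2 and conserves leaked contrast", {
  subj <- tinySwine(1)
  truth <- subj$truth
  # swine bins are 10..60 Gy midpoints, EQD2 = 3x, slope 0.167 %/Gy
  expect_equal(truth$trueOutDeltaPct, 0.167 * 3 * truth$binMid)
  expect_equal(truth$trueOutDeltaPct[2], 10.02)   # 0.167 * 60
  # in-vessel peak change: systemic reduction plus linear coupling
  expect_equal(truth$truePeakDeltaPct,
               -15 - 0.87 * truth$trueOutDeltaPct)
  # conservation ledger: out-of-vessel leak equals the vessel-pool deficit
  expect_gt(sum(truth$leakOutHuCc), 0)
  expect_lt(abs(sum(truth$leakOutHuCc) - truth$leakInDeficitHuCc) /
              truth$leakInDeficitHuCc, 0.01)
  # leak attribution only above the 25 Gy onset (bins 10 and 20 Gy excluded)
  expect_equal(truth$leakOutHuCc[truth$binMid <= 25], c(0, 0))
  # voxels outside the bins (including the whole contralateral lung) are
  # untouched by the density response
  un <- gridValues(truth$lung) & !gridValues(truth$vessel) &
    truth$binIdx == 0L
  expect_identical(gridValues(subj$postRT)[un], gridValues(subj$preRT)[un])
  # unknown timepoint is refused
  expect_error(applyRadiationResponse(subj$preRT, subj$seriesPre,
                                      subj$dose, truth, subj$config,
                                      timepoint = "9"),
               "timepoint")
})

test_that("breathing fields: expansion in range, exact damage fractions, sharp ratio contrast", {
  subj <- tinySwine(1)
  jPre <- jacobianMap(subj$fieldPre)
  lungv <- gridValues(subj$truth$lung)
  expect_true(all(gridValues(jPre)[lungv] > 1.05))
  expect_true(all(gridValues(jPre)[lungv] < 1.25))
  jPost <- jacobianMap(subj$fieldPost)
  ratio <- jacobianRatio(jPost, jPre)
  dm <- gridValues(subj$truth$damagedMask)
  expect_true(all(dm <= lungv))                   # damaged subset of lung
  # >= 99% of truth-damaged voxels fall below the 0.95 criterion
  expect_gte(mean(gridValues(ratio)[dm] < 0.95), 0.99)
  # undamaged voxels keep their pre-RT elasticity within 2% (transition
  # ramp voxels, ~1% of each bin, are the only exceptions)
  und <- lungv & !dm
  expect_gte(mean(abs(gridValues(ratio)[und] - 1) <= 0.02), 0.98)
  # per-bin damaged fraction matches the configured target
  for (b in seq_along(subj$truth$binMid)) {
    inBin <- subj$truth$binIdx == b
    expect_equal(sum(dm & inBin) / sum(inBin),
                 subj$truth$damagedFracTarget[b], tolerance = 0.01)
  }
  # phase volumes span exhale..inhale for ETV selection
  pv <- subj$phaseVolumes
  expect_equal(nrow(pv), 5L)
  expect_true(all(diff(pv$volume) <= 0))
})

test_that("phantom truth invariants hold across a 20-seed sweep", {
  for (s in 1:20) {
    cfg <- tinyConfig("swine", seed = 100 + s)
    an <- generateAnatomy(cfg)
    expect_true(all(gridValues(an$truth$vessel) <=
                      gridValues(an$truth$lung)))
    dg <- generateDose(cfg, an$truth)
    contra <- gridValues(dg$truth$lungRight)
    expect_lt(max(gridValues(dg$dose)[contra]), 5)
    expect_equal(max(gridValues(dg$dose)), cfg$dose$rx)
  }
})
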