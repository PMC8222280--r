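test_that("EQD2 evaluates the linear-quadratic conversion and its anchors", {
  expect_equal(eqd2(60, 12, 3), 180)
  expect_equal(eqd2(2, 2, 3), 2)       # 2 Gy in one 2 Gy fraction
  expect_equal(eqd2(15, 10, 3), 39)
  expect_equal(eqd2(5, 10, 3), 13)
  expect_error(eqd2(-1, 2, 3), "positive")
  expect_error(eqd2(10, 0, 3), "positive")
  # linear in D at fixed d; strictly increasing in d at fixed D
  expect_equal(eqd2(40, 8, 3), 2 * eqd2(20, 8, 3))
  expect_true(eqd2(20, 10, 3) > eqd2(20, 8, 3))
})

test_that("bin EQD2 conventions: prescription-fraction reproduces the printed edge mapping", {
  human <- FractionationScheme(50, 5)
  expect_equal(binEqd2(c(5, 15), human), c(13, 39))
  swine <- FractionationScheme(60, 5)
  expect_equal(binEqd2(20, swine), 60)          # 20*(12+3)/5
  # the swine scheme maps every bin dose by a factor 3
  mids <- c(10, 20, 30, 40, 50, 60)
  expect_equal(binEqd2(mids, swine), 3 * mids)
  expect_equal(binEqd2(5, swine, convention = "bin_fraction"), 4)  # 5*(1+3)/5
})

test_that("dose bins partition the >= 5 Gy in-lung region, disjointly, with half-open edges", {
  set.seed(21)
  d <- c(24, 24, 16)
  dose <- ImageGrid(array(runif(prod(d), 0, 64), d), spacing = c(2, 2, 2))
  lung <- BinaryMask(array(runif(prod(d)) > 0.4, d), spacing = c(2, 2, 2))
  bins <- makeDoseBins(dose, lung, minCc = 0)
  un <- array(FALSE, d)
  tot <- 0L
  for (b in bins) {
    expect_false(any(un & gridValues(binMask(b))))  # pairwise disjoint
    un <- un | gridValues(binMask(b))
    tot <- tot + sum(gridValues(binMask(b)))
  }
  target <- gridValues(lung) & gridValues(dose) >= 5 & gridValues(dose) <= 65
  expect_identical(un, target)
  # uniform zero dose gives no bins
  zero <- ImageGrid(array(0, d), spacing = c(2, 2, 2))
  expect_length(makeDoseBins(zero, lung), 0L)
})

test_that("bins at the 30 cc boundary: 29.9 cc excluded with warning, 30.0 cc retained", {
  d <- c(50, 50, 24)
  dose <- array(0, d)
  dose[seq_len(29900)] <- 10
  dose[seq(30001, 60000)] <- 20
  doseG <- ImageGrid(dose, spacing = c(1, 1, 1))   # 0.001 cc per voxel
  lung <- BinaryMask(array(TRUE, d), spacing = c(1, 1, 1))
  expect_warning(bins <- makeDoseBins(doseG, lung, edges = c(5, 15, 25)),
                 "29.9 cc")
  expect_length(bins, 1L)
  expect_equal(binLabel(bins[[1]]), "20Gy")
  expect_equal(binVolumeCc(bins[[1]]), 30)
})

test_that("mirrored controls are near-involutive, verified clean, and guarded against contamination", {
  cfg <- tinyConfig("swine", seed = 2)
  an <- generateAnatomy(cfg)
  dg <- generateDose(cfg, an$truth)
  truth <- dg$truth
  bins <- makeDoseBins(dg$dose, truth$lung, minCc = cfg$dose$minCc,
                       scheme = FractionationScheme(60, 5))
  ctl <- mirrorContours(bins, truth$lungLeft, truth$lungRight, dg$dose)
  expect_equal(length(ctl), length(bins))
  expect_true(all(vapply(ctl, binLaterality, "") == "control"))
  for (cb in ctl)
    expect_lt(max(gridValues(dg$dose)[gridValues(binMask(cb))]), 5)
  # mirror of a mirror overlaps the original with Dice >= 0.95
  zeroDose <- ImageGrid(array(0, cfg$gridShape), spacing = cfg$spacing)
  back <- mirrorContours(ctl, truth$lungLeft, truth$lungRight, zeroDose)
  for (i in seq_along(back)) {
    a <- gridValues(binMask(bins[[i]]))
    b <- gridValues(binMask(back[[i]]))
    dice <- 2 * sum(a & b) / (sum(a) + sum(b))
    expect_gte(dice, 0.95)
  }
  # a control landing on >= 5 Gy raises a contamination error naming the bin
  hot <- ImageGrid(array(30, cfg$gridShape), spacing = cfg$spacing)
  expect_error(mirrorContours(bins[1], truth$lungLeft, truth$lungRight, hot),
               "contaminated")
})

test_that("a mirrored contour that misses the contralateral lung is dropped with a warning", {
  d <- c(30, 12, 12)
  left <- array(FALSE, d); left[2:12, 2:11, 2:11] <- TRUE
  # contralateral lung only in a corner the mirror cannot reach
  right <- array(FALSE, d); right[26:29, 2:4, 2:4] <- TRUE
  dose <- array(0, d); dose[3:6, 5:8, 5:8] <- 20
  doseG <- ImageGrid(dose, spacing = c(2, 2, 2))
  lungs <- list(BinaryMask(left, spacing = c(2, 2, 2)),
                BinaryMask(right, spacing = c(2, 2, 2)))
  bins <- makeDoseBins(doseG, lungs[[1]], edges = c(15, 25), minCc = 0)
  expect_warning(
    ctl <- mirrorContours(bins, lungs[[1]], lungs[[2]], doseG),
    "misses")
  expect_length(ctl, 0L)
})
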