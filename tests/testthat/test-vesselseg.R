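test_that("MIP equals the identical frame, dominates shifted frames, and bounds every frame", {
  set.seed(11)
  a <- array(rnorm(64, -800, 50), c(4, 4, 4))
  ser <- constantSeries(list(a, a))
  expect_identical(gridValues(buildMip(ser)), a)
  ser2 <- constantSeries(list(a, a + 100))
  expect_equal(gridValues(buildMip(ser2)), a + 100)
  frames <- lapply(1:5, function(i) array(rnorm(64, -800, 80), c(4, 4, 4)))
  ser3 <- constantSeries(frames)
  mip <- gridValues(buildMip(ser3))
  for (f in frames) expect_true(all(mip >= f))
})

test_that("a dense unit-sigma Gaussian mode yields FWHM/sigma = 2.35 within 0.01", {
  # deterministic dense sampling of two well-separated Gaussian modes;
  # the second has sigma exactly 1 HU
  n <- 200000L
  v1 <- qnorm(ppoints(n), mean = -850, sd = 1)
  v2 <- qnorm(ppoints(n), mean = 0, sd = 1)
  vol <- ImageGrid(array(c(v1, v2), c(100, 100, 40)))
  lung <- BinaryMask(array(TRUE, c(100, 100, 40)))
  fit <- fitBimodalHistogram(vol, lung, binWidth = 0.02,
                             range = c(-900, 50))
  expect_equal(fit@mode2Fwhm, 2.35, tolerance = 0.01 / 2.35)
  expect_equal(fit@mode2Sigma, fit@mode2Fwhm / 2.35)
  expect_equal(fit@mode2Mean, 0, tolerance = 0.02)
  expect_equal(fit@mode1Mean, -850, tolerance = 0.02)
})

test_that("a unimodal histogram raises the not-bimodal error", {
  set.seed(5)
  vol <- ImageGrid(array(rnorm(4096, -850, 40), c(16, 16, 16)))
  lung <- BinaryMask(array(TRUE, c(16, 16, 16)))
  expect_error(fitBimodalHistogram(vol, lung), "not bimodal")
})

test_that("the phantom's first frame recovers the configured modes", {
  subj <- tinySwine(1)
  fit <- fitBimodalHistogram(seriesFrame(subj$seriesPre, 1),
                             subj$truth$lung)
  cfg <- subj$config
  expect_lt(abs(fit@mode1Mean - cfg$hu$mu1), 10)
  expect_lt(abs(fit@mode2Mean - cfg$hu$mu2), 10)
  # measured mode-2 spread includes the scan noise on top of the tissue sd
  expected <- sqrt(cfg$hu$sigma2^2 + cfg$hu$sigmaNoise^2)
  expect_lt(abs(fit@mode2Sigma - expected) / expected, 0.15)
  # threshold clears the pre-contrast in-lung HU distribution
  thr <- vesselThreshold(fit)
  pre <- gridValues(seriesFrame(subj$seriesPre, 1))[gridValues(subj$truth$lung)]
  expect_gt(thr, quantile(pre, 0.99))
})

test_that("vessel threshold is mode2 + 2 sigma with sigma = FWHM/2.35", {
  fit <- new("ModeFit", mode1Mean = -850, mode2Mean = -100,
             mode2Fwhm = 94, mode2Sigma = 94 / 2.35,
             histogram = data.frame())
  expect_equal(vesselThreshold(fit), -100 + 2 * 40)
  fit2 <- new("ModeFit", mode1Mean = -850, mode2Mean = 40,
              mode2Fwhm = 1e-4, mode2Sigma = 1e-4 / 2.35,
              histogram = data.frame())
  expect_equal(vesselThreshold(fit2), 40, tolerance = 1e-4)
})

test_that("segmentation thresholds strictly, saturates at the extremes, and is monotone in threshold", {
  set.seed(7)
  mip <- ImageGrid(array(rnorm(4096, -500, 300), c(16, 16, 16)))
  lung <- BinaryMask(array(runif(4096) > 0.3, c(16, 16, 16)))
  hi <- segmentVessels(mip, lung, max(gridValues(mip)))
  expect_false(any(gridValues(hi)))
  lo <- segmentVessels(mip, lung, min(gridValues(mip)) - 1)
  expect_identical(gridValues(lo), gridValues(lung))
  t1 <- segmentVessels(mip, lung, -400)
  t2 <- segmentVessels(mip, lung, -100)
  expect_true(all(gridValues(t2) <= gridValues(t1)))  # t2 subset of t1
  # strict inequality at the threshold value itself
  mip2 <- ImageGrid(array(0, c(8, 8, 8)))
  all8 <- BinaryMask(array(TRUE, c(8, 8, 8)))
  expect_false(any(gridValues(segmentVessels(mip2, all8, 0))))
})

test_that("parenchyma = lung minus vessels: partition at k=0, shrinkage under dilation", {
  lung <- BinaryMask(array(TRUE, c(10, 10, 10)))
  ves <- array(FALSE, c(10, 10, 10)); ves[4:6, 4:6, 4:6] <- TRUE
  vessels <- BinaryMask(ves)
  par0 <- parenchymaMask(lung, vessels)
  expect_identical(gridValues(par0) | gridValues(vessels),
                   gridValues(lung))
  expect_false(any(gridValues(par0) & gridValues(vessels)))
  par1 <- parenchymaMask(lung, vessels, dilate = 1L)
  expect_lt(sum(gridValues(par1)), sum(gridValues(par0)))
  expect_identical(gridValues(parenchymaMask(lung, lung)),
                   array(FALSE, c(10, 10, 10)))
  empty <- BinaryMask(array(FALSE, c(10, 10, 10)))
  expect_identical(gridValues(parenchymaMask(lung, empty)),
                   gridValues(lung))
})
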