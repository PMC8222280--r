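test_that("linear fit: exact lines, the 3-point oracle, and degenerate inputs", {
  x <- c(0, 1, 2, 3)
  f <- linearFit(x, 2 * x + 1)
  expect_equal(f@slope, 2); expect_equal(f@intercept, 1)
  expect_equal(f@rSquared, 1)
  expect_equal(linearFit(x, -x)@pearsonR, -1)
  # closed-form OLS on {1,2,3} vs {1,2,4}: slope = 1.5,
  # r = 1.5 / sqrt(7/3) = 0.98198...
  g <- linearFit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g@slope, 1.5)
  expect_equal(g@pearsonR, 1.5 / sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(g@rSquared, g@pearsonR^2)
  expect_error(linearFit(c(2, 2, 2), 1:3), "constant")
  expect_error(linearFit(1, 1), "2 points")
})

test_that("Pearson r is invariant to positive affine rescaling of either axis", {
  set.seed(17)
  x <- rnorm(20); y <- 0.8 * x + rnorm(20, 0, 0.3)
  r0 <- linearFit(x, y)@pearsonR
  expect_equal(linearFit(3 * x + 5, y)@pearsonR, r0)
  expect_equal(linearFit(x, 0.1 * y - 7)@pearsonR, r0)
})

test_that("adjusted swine dataset evaluates the fit at human EQD2 values, affinely", {
  fit <- new("LinearFit", slope = 0.167, intercept = 0, rSquared = 1,
             pearsonR = 1, pValue = 0, n = 6L)
  adj <- adjustedSwine(fit, c(13, 39))
  expect_equal(adj$swine_pred, c(2.171, 6.513))
  flat <- new("LinearFit", slope = 0, intercept = 4.2, rSquared = 0,
              pearsonR = 0, pValue = 1, n = 6L)
  expect_equal(adjustedSwine(flat, c(10, 20, 30))$swine_pred, rep(4.2, 3))
  # affine in eqd2: second differences vanish on an arithmetic grid
  adj2 <- adjustedSwine(fit, c(10, 20, 30, 40))
  expect_equal(diff(diff(adj2$swine_pred)), c(0, 0))
  expect_error(adjustedSwine(fit, numeric(0)), "empty")
  expect_error(adjustedSwine(fit, c(30, 20)), "increasing")
})

test_that("cross-cohort regression recovers identity and proportional scalings", {
  sw <- c(2, 6, 10, 14, 18)
  f1 <- crossCohortCorrelation(sw, sw)
  expect_equal(f1@slope, 1); expect_equal(f1@pearsonR, 1)
  f2 <- crossCohortCorrelation(sw, 0.5 * sw)
  expect_equal(f2@slope, 0.5); expect_equal(f2@pearsonR, 1)
  expect_error(crossCohortCorrelation(sw[1:2], sw[1:2]), "3 paired")
})

test_that("cross-cohort slope is recovered under noise across a 20-seed sweep", {
  slopes <- vapply(1:20, function(s) {
    set.seed(s)
    sw <- seq(3, 25, length.out = 6)
    human <- 0.7 * sw + 1 + rnorm(6, 0, 0.3)
    crossCohortCorrelation(sw, human)@slope
  }, numeric(1))
  expect_equal(mean(slopes), 0.7, tolerance = 0.05)
  expect_true(all(abs(slopes - 0.7) < 0.15))
})

test_that("vessel coupling fit reports the negative slope and the out/in-reduction correlation", {
  x <- c(5, 10, 15, 20, 25, 30)
  r <- vesselCouplingFit(x, -x)
  expect_equal(r$fit@slope, -1)
  expect_equal(r$reductionCor, 1)
  r2 <- vesselCouplingFit(x, -15 - 0.87 * x)
  expect_equal(r2$fit@slope, -0.87)
  expect_equal(r2$reductionCor, 1)
  set.seed(23)
  r3 <- vesselCouplingFit(rnorm(50), rnorm(50))
  expect_lt(abs(r3$fit@pearsonR), 0.3)
  expect_error(vesselCouplingFit(1:2, 1:2), "3 bins")
})

test_that("report writer emits deterministic tidy CSV and JSON", {
  m <- data.frame(subject = rep(c("s2", "s1"), each = 2),
                  timepoint = "3", bin = c("20Gy", "10Gy"),
                  compartment = "parenchyma", laterality = "irradiated",
                  eqd2 = c(60, 30), baseline_hu = c(-700, -800, -710, -790),
                  peak_hu = c(-600, -700, -610, -690))
  fits <- list(doseResponse = linearFit(c(30, 60, 90), c(5, 10, 15)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- writeReport(m, fits, d1)
  p2 <- writeReport(m, fits, d2)
  expect_identical(readLines(p1[["csv"]]), readLines(p2[["csv"]]))
  expect_identical(readLines(p1[["json"]]), readLines(p2[["json"]]))
  tidy <- read.csv(p1[["csv"]])
  # rows = ids x metrics (baseline, peak, n/volume columns excluded here)
  expect_equal(nrow(tidy), 4 * 2)
  expect_equal(names(tidy),
               c("subject", "timepoint", "bin", "compartment",
                 "metric", "value"))
  js <- jsonlite::read_json(p1[["json"]], simplifyVector = TRUE)
  expect_equal(js$doseResponse$slope, 1 / 6, tolerance = 1e-12)
  # empty input: header-only CSV
  empty <- m[0, ]
  p3 <- writeReport(empty, list(), withr::local_tempdir())
  expect_equal(nrow(read.csv(p3[["csv"]])), 0)
})
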