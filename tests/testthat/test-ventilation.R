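coordArrays <- function(d, sp) {
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  z <- (seq_len(d[3]) - 1) * sp[3]
  list(X = array(rep(x, times = d[2] * d[3]), d),
       Y = array(rep(rep(y, each = d[1]), times = d[3]), d),
       Z = array(rep(z, each = d[1] * d[2]), d))
}

affineField <- function(A, d = c(10, 9, 8), sp = c(2, 2, 2)) {
  co <- coordArrays(d, sp)
  u <- array(0, c(d, 3))
  for (i in 1:3)
    u[, , , i] <- A[i, 1] * co$X + A[i, 2] * co$Y + A[i, 3] * co$Z
  VectorField(u, spacing = sp)
}

test_that("Jacobian oracles: identity, translation, linear stretch, isotropic dilation", {
  d <- c(10, 9, 8)
  zero <- VectorField(array(0, c(d, 3)), spacing = c(2, 2, 2))
  expect_equal(gridValues(jacobianMap(zero)), array(1, d))
  # rigid translation: J identically 1
  tr <- VectorField(array(rep(c(3, -2, 7), each = prod(d)), c(d, 3)),
                    spacing = c(2, 2, 2))
  expect_equal(gridValues(jacobianMap(tr)), array(1, d))
  # u = (0.05 x, 0, 0): J = 1.05 everywhere (one-sided diffs exact on linear)
  lin <- affineField(diag(c(0.05, 0, 0)))
  expect_equal(gridValues(jacobianMap(lin)), array(1.05, d))
  # uniform 5% dilation: J = 1.05^3 = 1.157625
  dil <- affineField(diag(c(0.05, 0.05, 0.05)))
  expect_equal(gridValues(jacobianMap(dil)), array(1.157625, d))
})

test_that("Jacobian matches the analytic determinant for a general affine field", {
  A <- matrix(c(0.03, 0.01, 0.00,
                0.02, -0.02, 0.01,
                0.00, 0.01, 0.04), 3, 3, byrow = TRUE)
  f <- affineField(A)
  expect_equal(gridValues(jacobianMap(f)),
               array(det(diag(3) + A), c(10, 9, 8)), tolerance = 1e-12)
  expect_error(jacobianMap(VectorField(array(0, c(2, 5, 5, 3)))),
               "degenerate")
})

test_that("Jacobian ratio divides voxelwise and marks non-positive denominators invalid", {
  d <- c(5, 5, 5)
  jPre <- ImageGrid(array(1, d))
  jPost <- ImageGrid(array(0.9, d))
  r <- jacobianRatio(jPost, jPre)
  expect_equal(gridValues(r), array(0.9, d))
  expect_equal(gridValues(jacobianRatio(jPre, jPre)), array(1, d))
  bad <- jPre; bad@values[1, 1, 1] <- 0
  r2 <- jacobianRatio(jPost, bad)
  expect_true(is.na(gridValues(r2)[1, 1, 1]))
  expect_false(anyNA(gridValues(r2)[-1]))
})

test_that("damaged fraction uses an inclusive threshold and is monotone in it", {
  d <- c(3, 1, 1)
  r <- ImageGrid(array(c(0.94, 0.95, 1.02), d))
  m <- BinaryMask(array(TRUE, d))
  expect_equal(damagedFraction(r, m)$fraction_damaged, 2 / 3)
  ones <- ImageGrid(array(1, c(4, 4, 4)))
  m4 <- BinaryMask(array(TRUE, c(4, 4, 4)))
  expect_equal(damagedFraction(ones, m4)$fraction_damaged, 0)
  set.seed(13)
  rr <- ImageGrid(array(runif(64, 0.8, 1.1), c(4, 4, 4)))
  fr <- vapply(c(0.85, 0.9, 0.95, 1.0, 1.05),
               function(t) damagedFraction(rr, m4, threshold = t)$fraction_damaged,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  # invalid voxels are excluded from the denominator
  rna <- rr; rna@values[1:8] <- NA_real_
  expect_equal(damagedFraction(rna, m4)$n_voxels, 56L)
  expect_equal(damagedFraction(rna, m4)$n_invalid, 8L)
})

test_that("ETV phase selection matches a brute-force minimizer, with exhale-favouring ties", {
  pv <- data.frame(phase = c("a", "b", "c"), volume = c(4.0, 4.6, 5.0))
  sel <- selectPhasesEtv(pv, 1.0)
  expect_equal(sel$inhale, "c"); expect_equal(sel$exhale, "a")
  expect_equal(sel$delta, 1.0)
  two <- data.frame(phase = c("p", "q"), volume = c(3.8, 4.9))
  sel2 <- selectPhasesEtv(two, 0.2)
  expect_equal(sel2$inhale, "q"); expect_equal(sel2$exhale, "p")
  sel3 <- selectPhasesEtv(data.frame(phase = c("a", "b", "c"),
                                     volume = c(4.0, 4.4, 5.1)), 1.0)
  expect_equal(sel3$inhale, "c"); expect_equal(sel3$exhale, "a")
  # brute force oracle over random volume sets
  set.seed(31)
  for (k in 1:10) {
    v <- round(runif(5, 3, 6), 3)
    tgt <- runif(1, 0.2, 2)
    pv <- data.frame(phase = letters[1:5], volume = v)
    got <- selectPhasesEtv(pv, tgt)
    pairs <- expand.grid(i = 1:5, j = 1:5)
    pairs <- pairs[v[pairs$i] > v[pairs$j], ]
    err <- abs((v[pairs$i] - v[pairs$j]) - tgt)
    expect_equal(got$delta, (v[pairs$i] - v[pairs$j])[which.min(err)])
  }
  expect_error(selectPhasesEtv(data.frame(phase = "a", volume = 4), 1),
               "2 phases")
})

test_that("damage-vs-HU relation: unit slope for identical vectors, zero for constant damage", {
  dmg <- data.frame(bin = c("10Gy", "20Gy", "30Gy"),
                    fraction_damaged = c(0.10, 0.20, 0.30))
  hu <- data.frame(bin = c("10Gy", "20Gy", "30Gy"),
                   mean_delta_pct = c(10, 20, 30))
  r <- damageVsHu(dmg, hu)
  expect_equal(r$fit@slope, 1)
  expect_equal(r$fit@pearsonR, 1)
  flat <- dmg; flat$fraction_damaged <- 0.45
  r2 <- damageVsHu(flat, hu)
  expect_equal(r2$fit@slope, 0)
  expect_error(damageVsHu(dmg, data.frame(bin = "99Gy", mean_delta_pct = 1)),
               "common bins")
})
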