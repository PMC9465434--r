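test_that("optimized gamma equals the exhaustive oracle on random pairs", {
  for (s in 1:20) {
    R <- smoothField(12, seed = s)
    E <- withr::with_seed(100 + s, R + matrix(rnorm(144, 0, 0.04), 12, 12))
    E[E < 0] <- 0
    g <- gammaMap(mkDose(R), mkDose(E),
                  gammaCriteria(3, 2, searchRadiusMm = 6, subsample = 1L))
    oracle <- bruteGamma(R, E, 3, 2, 6)
    expect_lt(max(abs(channels(g)[, , 1] - oracle)), 1e-9)
  }
})

test_that("gamma is signed by the local dose difference and bounded by pure DD", {
  R <- smoothField(16, seed = 3)
  E <- withr::with_seed(33, R * (1 + matrix(rnorm(256, 0, 0.05), 16, 16)))
  E[E < 0] <- 0
  g <- channels(gammaMap(mkDose(R), mkDose(E), gammaCriteria(3, 2)))[, , 1]
  expect_equal(sign(g)[E != R], sign(E - R)[E != R])
  pureDD <- abs(E - R) / max(R) / 0.03
  expect_true(all(abs(g) <= pureDD + 1e-12))
})

test_that("loosening either gamma criterion never increases the index", {
  R <- smoothField(14, seed = 5)
  E <- withr::with_seed(55, R + matrix(rnorm(196, 0, 0.05), 14, 14))
  E[E < 0] <- 0
  ref <- mkDose(R)
  ev <- mkDose(E)
  base <- abs(channels(gammaMap(ref, ev, gammaCriteria(2, 1, 6, 2L)))[, , 1])
  looseDD <- abs(channels(gammaMap(ref, ev, gammaCriteria(4, 1, 6, 2L)))[, , 1])
  looseDTA <- abs(channels(gammaMap(ref, ev, gammaCriteria(2, 2, 6, 2L)))[, , 1])
  expect_true(all(looseDD <= base + 1e-12))
  expect_true(all(looseDTA <= base + 1e-12))
})

test_that("a one-pixel shift is absorbed by the DTA part of gamma", {
  n <- 40
  prof <- pnorm(((1:n) - 10) * 0.8 / 1.5) - pnorm(((1:n) - 31) * 0.8 / 1.5)
  R <- outer(prof, prof)
  E <- cbind(R[, 1], R[, 1:(n - 1)]) # shift +1 column = +0.8 mm
  interior <- 5:(n - 5)
  g31 <- channels(gammaMap(mkDose(R), mkDose(E),
                           gammaCriteria(3, 1, subsample = 4L)))[, , 1]
  expect_lte(max(abs(g31[interior, interior])), 0.8 + 1e-9)
  g13 <- channels(gammaMap(mkDose(R), mkDose(E),
                           gammaCriteria(1, 3, subsample = 4L)))[, , 1]
  expect_lte(max(abs(g13[interior, interior])), 0.8 / 3 + 1e-9)
})

test_that("ratio maps scale and fall back to 1 outside the field", {
  R <- smoothField(10, seed = 2)
  expect_true(all(channels(ratioMap(mkDose(R), mkDose(2 * R))) == 2))
  Rb <- R
  Rb[1, ] <- 0 # zero border
  r <- channels(ratioMap(mkDose(Rb), mkDose(Rb * 1.5)))[, , 1]
  expect_true(all(r[1, ] == 1))
  expect_true(all(abs(r[-1, ] - 1.5) < 1e-12))
})

test_that("dose-difference maps are exact arithmetic", {
  R <- smoothField(10, seed = 4)
  E <- R + 0.03 * max(R)
  rel <- channels(ddMap(mkDose(R), mkDose(E), relative = TRUE))[, , 1]
  expect_equal(rel, matrix(0.03, 10, 10))
  # antisymmetry up to the normalization swap
  E2 <- withr::with_seed(8, R * (1 + matrix(rnorm(100, 0, 0.1), 10, 10)))
  E2[E2 < 0] <- 1e-3
  a <- channels(ddMap(mkDose(R), mkDose(E2), relative = TRUE))[, , 1]
  b <- channels(ddMap(mkDose(E2), mkDose(R), relative = TRUE))[, , 1]
  expect_equal(a, -b * max(E2) / max(R))
})

test_that("dta maps recover translations and saturate without crossings", {
  n <- 40
  prof <- pnorm(((1:n) - 12) * 0.8 / 3) - pnorm(((1:n) - 30) * 0.8 / 3)
  R <- outer(prof, prof)
  E <- cbind(R[, 1], R[, 1], R[, 1:(n - 2)]) # +2 px along x
  dmap <- channels(dtaMap(mkDose(R), mkDose(E)))
  penumbra <- abs(R - 0.5 * max(R)) < 0.35 * max(R)
  med <- median(dmap[, , 1][penumbra])
  expect_lt(abs(med - 1.6) / 1.6, 0.10)
  # in the y-penumbra of x-plateau columns the column profiles are nearly
  # unchanged, so dta_y stays near 0 (flat regions are excluded: distance
  # to a matching dose is ill-conditioned where profiles are flat)
  yPen <- outer(prof > 0.2 & prof < 0.8, prof > 0.97)
  expect_lt(median(abs(dmap[, , 2][yPen])), 0.2)

  # constant offset on flat fields: no crossing anywhere, saturation at W
  F1 <- matrix(1, 12, 12)
  dflat <- channels(dtaMap(mkDose(F1), mkDose(F1 + 0.2)))
  W <- 12 * 0.8 / 2
  expect_true(all(abs(dflat) == W))
})

test_that("ssim matches closed forms and stays within [-1, 1]", {
  pars <- ssimParams(9L, dynamicRange = 1)
  A <- matrix(0.4, 9, 9)
  B <- matrix(0.7, 9, 9)
  s <- channels(ssimMap(mkDose(A), mkDose(B), pars))[5, 5, 1]
  C1 <- (0.01 * 1)^2
  expect_equal(s, (2 * 0.4 * 0.7 + C1) / (0.4^2 + 0.7^2 + C1))

  # affine eval with a > 0: structure correlation is perfect but SSIM < 1
  R <- smoothField(15, seed = 6)
  E <- 1.3 * R + 0.05
  s2 <- channels(ssimMap(mkDose(R), mkDose(E), ssimParams(5L)))[, , 1]
  expect_true(all(s2 < 1))
  expect_true(all(s2 >= -1))

  # self-similarity is exactly 1
  s3 <- channels(ssimMap(mkDose(R), mkDose(R), ssimParams(5L)))[, , 1]
  expect_equal(max(abs(s3 - 1)), 0)

  expect_error(ssimMap(mkDose(R), mkDose(R), ssimParams(17L)), "window")
})

test_that("sobel gradients respond analytically to ramps and rotations", {
  R <- matrix(1, 12, 12)
  slope <- 0.05
  E <- R + outer(rep(1, 12), (1:12) * slope) * max(R)
  g <- channels(gradientMap(mkDose(R), mkDose(E)))
  inner <- 3:10
  expect_equal(g[inner, inner, 1], matrix(8 * slope, 8, 8))
  expect_equal(g[inner, inner, 2], matrix(0, 8, 8))

  # rotating the DD pattern by a quarter turn preserves the gradient
  # magnitude field (rotated along) and turns directions by pi/2
  D <- withr::with_seed(7, matrix(runif(144), 12, 12))
  rot <- t(D)[12:1, ] # counter-clockwise quarter turn of the matrix
  gA <- channels(gradientMap(mkDose(R), mkDose(R + D * max(R))))
  gB <- channels(gradientMap(mkDose(R), mkDose(R + rot * max(R))))
  magA <- t(gA[, , 1])[12:1, ]
  expect_equal(gB[inner, inner, 1], magA[inner, inner])
  dirA <- t(gA[, , 2])[12:1, ]
  dd <- (gB[inner, inner, 2] - dirA[inner, inner]) %% (2 * pi)
  expect_true(all(abs(dd - pi / 2) < 1e-9 | abs(dd - 3 * pi / 2) < 1e-9))
})

test_that("every method returns its neutral map on identical images", {
  R <- smoothField(24, seed = 9)
  ref <- mkDose(R)
  for (m in comparisonMethods()) {
    ci <- compareDose(ref, ref, m, gammaSubsample = 2L,
                      ssimPar = ssimParams(11L))
    neutral <- switch(m, ratio = 1, ssim = 1, 0)
    expect_equal(max(abs(channels(ci) - neutral)), 0, info = m)
    expect_equal(dim(channels(ci))[3],
                 switch(m, dta = 2L, gradient = 2L, ddDta = 3L, 1L),
                 info = m)
  }
  expect_length(unique(comparisonMethods()), 12L)
})

test_that("mismatched image pairs are rejected", {
  a <- mkDose(matrix(1, 4, 4))
  b <- mkDose(matrix(1, 5, 5))
  expect_error(ddMap(a, b), "shape")
  z <- mkDose(matrix(0, 4, 4))
  expect_error(gammaMap(z, z, gammaCriteria(3, 3)), "positive")
  expect_error(ddMap(z, z, relative = TRUE), "positive")
})
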