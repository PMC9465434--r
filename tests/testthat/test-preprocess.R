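test_that("cropping keeps everything above threshold and boxes plateaus", {
  R <- smoothField(20, seed = 1) + 1 # everywhere above 10% of max
  ref <- mkDose(R)
  comp <- ddMap(ref, ref)
  expect_equal(dim(channels(cropToField(comp, ref)))[1:2], c(20L, 20L))

  # rectangular plateau with narrow penumbra: box within 2 px per side
  n <- 60
  px <- pnorm(((1:n) - 15) * 0.8 / 1) - pnorm(((1:n) - 45) * 0.8 / 1)
  R2 <- outer(px, px)
  ref2 <- mkDose(R2)
  cr <- cropToField(ddMap(ref2, ref2), ref2)
  box <- cr@meta$cropBox
  expect_lt(abs((box[2] - box[1] + 1) - 31), 5) # plateau 15..45
  expect_error(cropToField(ddMap(ref2, ref2), mkDose(R2[1:10, 1:10])),
               "shape")
})

test_that("crop boxes reflect the modality field sizes", {
  ext <- lapply(c("VMAT", "SBRT"), function(mod) {
    cfg <- simConfig(mod, seed = 3L)
    d <- renderDose(generatePlan(cfg), cfg, arc = 1)
    cr <- cropToField(ddMap(d, d), d)
    dim(channels(cr))[1:2] * cfg@pixelPitchMm
  })
  expect_true(all(ext[[1]] > ext[[2]])) # VMAT fields are larger
  expect_lt(max(abs(ext[[1]] - rev(simConfig("VMAT")@targetFieldMm)) /
                rev(simConfig("VMAT")@targetFieldMm)), 0.15)
})

test_that("dataset statistics pool pixels per channel", {
  imgs <- withr::with_seed(11, lapply(1:20, function(i)
    portalQA:::.comparisonImage(matrix(rnorm(900), 30, 30), "relDD",
                                "rel_dd")))
  st <- computeDatasetStats(imgs)
  npx <- 20 * 900
  expect_lt(abs(st@mean), 3 / sqrt(npx))
  expect_lt(abs(st@sd - 1), 3 / sqrt(2 * npx))
  expect_equal(st@clipMin, st@mean - 2 * st@sd)

  two <- list(portalQA:::.comparisonImage(matrix(0, 5, 5), "relDD", "rel_dd"),
              portalQA:::.comparisonImage(matrix(1, 5, 5), "relDD", "rel_dd"))
  expect_equal(computeDatasetStats(two)@mean, 0.5)
  flat <- list(two[[1]], two[[1]])
  expect_error(computeDatasetStats(flat), "variance")
})

test_that("normalization hits its analytically forced values", {
  st <- new("DatasetStats", mean = 2, sd = 0.5, clipMin = 1, clipMax = 3)
  img <- portalQA:::.comparisonImage(
    matrix(c(2, 2 + 3 * 0.5, 2 - 3 * 0.5, 2.5), 2, 2), "relDD", "rel_dd")
  mm <- channels(normalizeImage(img, st, "minmax"))[, , 1]
  expect_equal(mm[1, 1], 0.5)  # dataset mean maps to 0.5
  expect_equal(mm[2, 1], 1.0)  # mean + 3 sd clips to 1
  expect_equal(mm[1, 2], 0.0)  # mean - 3 sd clips to 0
  ms <- channels(normalizeImage(img, st, "meanstd"))[, , 1]
  expect_equal(ms[1, 1], 0)
  expect_equal(ms[2, 2], 1)    # (2.5 - 2) / 0.5
  # ordering preserved by meanstd
  expect_equal(order(ms), order(channels(img)[, , 1]))
})

test_that("meanstd self-normalization re-centres the training pool", {
  imgs <- withr::with_seed(12, lapply(1:10, function(i)
    portalQA:::.comparisonImage(matrix(rnorm(400, 5, 3), 20, 20), "relDD",
                                "rel_dd")))
  st <- computeDatasetStats(imgs)
  pooled <- unlist(lapply(imgs, function(im)
    channels(normalizeImage(im, st, "meanstd"))))
  expect_lt(abs(mean(pooled)), 1e-9)
  expect_lt(abs(sqrt(mean(pooled^2) - mean(pooled)^2) - 1), 1e-9)
})

test_that("square resizing is idempotent, constant-preserving and convex", {
  img <- portalQA:::.comparisonImage(
    withr::with_seed(13, matrix(runif(64 * 64), 64, 64)), "relDD", "rel_dd")
  same <- resizeSquare(img, 64L)
  expect_lt(max(abs(channels(same) - channels(img))), 1e-12)

  const <- portalQA:::.comparisonImage(matrix(0.7, 57, 68), "relDD", "rel_dd")
  expect_equal(max(abs(channels(resizeSquare(const, 128L)) - 0.7)), 0)

  rect <- portalQA:::.comparisonImage(
    withr::with_seed(14, matrix(runif(57 * 68), 57, 68)), "relDD", "rel_dd")
  up <- channels(resizeSquare(rect, 128L))
  expect_gte(min(up), min(channels(rect)))
  expect_lte(max(up), max(channels(rect)))
  expect_equal(resizeSquare(rect, 32L), resizeSquare(rect, 32L))
  # anisotropic pitch is recorded
  expect_equal(resizeSquare(rect, 32L)@meta$pitchAfterMm,
               c(57, 68) * 0.8 / 32)
})

test_that("reported pixel pitches reproduce the tabulated arithmetic", {
  # VMAT row: 118 x 121 cropped pixels at 0.8 mm
  expect_equal(reportPixelPitch(118, 0.8, 32), 2.9)
  expect_equal(reportPixelPitch(121, 0.8, 32), 3.0)
  expect_equal(reportPixelPitch(118, 0.8, 64), 1.4)
  expect_equal(reportPixelPitch(121, 0.8, 64), 1.5)
  expect_equal(reportPixelPitch(118, 0.8, 128), 0.7)
  expect_equal(reportPixelPitch(121, 0.8, 128), 0.7)
  # SBRT row: 57 x 68
  expect_equal(reportPixelPitch(57, 0.8, 32), 1.4)
  expect_equal(reportPixelPitch(68, 0.8, 32), 1.7)
  expect_equal(reportPixelPitch(57, 0.8, 64), 0.7)
  expect_equal(reportPixelPitch(68, 0.8, 64), 0.8)
  expect_equal(reportPixelPitch(57, 0.8, 128), 0.3)
  expect_equal(reportPixelPitch(68, 0.8, 128), 0.4)
  # identity-scale case
  expect_equal(reportPixelPitch(64, 0.8, 64), 0.8)
})

test_that("the pipeline is deterministic and leak-free by construction", {
  cfg <- tinySimConfig(20L)
  ds <- simulateErrorDataset(cfg, nPlans = 2L, samplesPerType = 1L,
                             types = c("collimator", "mu_systematic"),
                             seed = 20L)
  comps <- buildComparisonSet(ds, "relDD")
  refs <- ds$refs[ds$refIdx]
  a <- preprocessDataset(comps, refs, preprocessConfig(side = 32L),
                         trainIdx = 1:2)
  b <- preprocessDataset(comps, refs, preprocessConfig(side = 32L),
                         trainIdx = 1:2)
  expect_identical(a$x, b$x)
  # statistics come from the declared training subset only
  c2 <- preprocessDataset(comps, refs, preprocessConfig(side = 32L),
                          trainIdx = 3:4)
  expect_false(identical(a$stats@mean, c2$stats@mean))
})
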