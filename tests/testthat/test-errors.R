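test_that("magnitude grids match the tabulated ranges and steps", {
  for (ty in errorTypes()) {
    g <- magnitudeGrid(ty)
    expect_length(g, 20L)
    expect_false(any(g == 0))
    expect_equal(sort(-g), sort(g)) # symmetric under negation
  }
  expect_equal(magnitudeGrid("collimator"),
               c(seq(-2, -0.2, by = 0.2), seq(0.2, 2, by = 0.2)))
  expect_equal(magnitudeGrid("mu_systematic"), c(-10:-1, 1:10))
  # step doubling halves each grid
  expect_length(magnitudeGrid("mlc_random", stepFactor = 2), 10L)
})

test_that("relevance labels follow the per-type thresholds, inclusively", {
  expect_equal(level2Label("collimator", 0.2), "irrelevant")
  expect_equal(level2Label("collimator", -1.2), "relevant")
  expect_equal(level2Label("mlc_random", -0.6), "relevant")
  expect_equal(level2Label("mlc_random", 0.4), "irrelevant")
  expect_equal(level2Label("mu_systematic", 5), "relevant") # boundary
  expect_equal(level2Label("mu_random", 3), "relevant")     # boundary
  expect_equal(level2Label("mlc_systematic", 1), "relevant")
  expect_error(level2Label("nonsense", 1), "unknown")
  # both relevance classes are populated on every grid
  for (ty in errorTypes()) {
    lab <- level2Label(ty, magnitudeGrid(ty))
    expect_setequal(unique(lab), c("relevant", "irrelevant"))
  }
})

test_that("systematic errors apply exactly and invert with the opposite sign", {
  cfg <- tinySimConfig(5L)
  p <- generatePlan(cfg)
  ang0 <- vapply(arcs(p)[[1]], slot, numeric(1), "collimator")

  pc <- applyError(p, errorSpec("collimator", 2))
  expect_equal(vapply(arcs(pc)[[1]], slot, numeric(1), "collimator"),
               ang0 + 2)
  back <- applyError(pc, errorSpec("collimator", -2))
  expect_equal(vapply(arcs(back)[[1]], slot, numeric(1), "collimator"), ang0)

  pm <- applyError(p, errorSpec("mu_systematic", 10))
  expect_equal(totalMU(pm), 1.10 * totalMU(p))

  ps <- applyError(p, errorSpec("mlc_systematic", 1.5, banksAffected = "both"))
  expect_equal(arcs(ps)[[1]][[1]]@bankA, arcs(p)[[1]][[1]]@bankA + 1.5)
  expect_equal(arcs(ps)[[1]][[1]]@bankB, arcs(p)[[1]][[1]]@bankB + 1.5)
  backs <- applyError(ps, errorSpec("mlc_systematic", -1.5,
                                    banksAffected = "both"))
  expect_equal(arcs(backs)[[1]][[1]]@bankA, arcs(p)[[1]][[1]]@bankA)

  # single-bank sign convention: positive opens the field
  pa <- applyError(p, errorSpec("mlc_systematic", 0.8, banksAffected = "A"))
  expect_equal(arcs(pa)[[1]][[1]]@bankA, arcs(p)[[1]][[1]]@bankA - 0.8)
  expect_equal(arcs(pa)[[1]][[1]]@bankB, arcs(p)[[1]][[1]]@bankB)

  # the original plan is never modified
  expect_equal(totalMU(p), totalMU(generatePlan(cfg)))
})

test_that("random errors record the realized mean of their per-unit draws", {
  cfg <- tinySimConfig(6L)
  p <- generatePlan(cfg)
  for (ty in c("mlc_random", "mu_random")) {
    for (m in c(-1.4, 0.6)) {
      mag <- if (ty == "mu_random") m * 5 else m
      spec <- sampleErrorSpec(ty, mag, p, seed = 42L)
      expect_lt(abs(mean(spec@perUnitDraws) - spec@magnitude), 1e-12)
      expect_gt(length(spec@perUnitDraws), 1L)
    }
  }
  # mu_random scales each segment by its own draw
  spec <- sampleErrorSpec("mu_random", 5, p, seed = 9L)
  pr <- applyError(p, spec)
  mu0 <- vapply(arcs(p)[[1]], slot, numeric(1), "mu")
  mu1 <- vapply(arcs(pr)[[1]], slot, numeric(1), "mu")
  expect_equal(mu1, mu0 * (1 + spec@perUnitDraws[seq_along(mu0)] / 100))
})

test_that("overlapping leaf pairs are clamped to a zero gap", {
  nl <- 6L
  p <- treatmentPlan(list(list(
    segment(rep(-0.2, nl), rep(0.2, nl), 0, 10))), "SBRT")
  shut <- applyError(p, errorSpec("mlc_systematic", -0.5, banksAffected = "A"))
  seg <- arcs(shut)[[1]][[1]]
  expect_true(all(seg@bankA <= seg@bankB))
  expect_equal(attr(shut, "clampedLeafPairs"), nl)
})

test_that("dose perturbation grows monotonically with systematic magnitude", {
  cfg <- tinySimConfig(8L)
  p <- generatePlan(cfg)
  ref <- pixels(renderDose(p, cfg))
  for (ty in c("collimator", "mlc_systematic", "mu_systematic")) {
    mags <- c(0.2, 1, 2)
    if (ty == "mu_systematic") mags <- c(1, 5, 10)
    dev <- vapply(mags, function(m) {
      spec <- errorSpec(ty, m, banksAffected = "both")
      max(abs(pixels(renderDose(applyError(p, spec), cfg)) - ref))
    }, numeric(1))
    expect_true(all(diff(dev) > 0), info = ty)
    expect_gt(dev[1], 0)
  }
})

test_that("error specs outside the tabulated range are rejected", {
  expect_error(errorSpec("collimator", 2.5), "range")
  expect_error(errorSpec("collimator", 0), "non-zero")
  expect_error(errorSpec("mu_systematic", 12), "range")
})
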