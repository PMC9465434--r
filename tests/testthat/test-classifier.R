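# Tiny separable image set: class decided by overall brightness.
toySet <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    x <- array(0, c(8, 8, 1, n))
    half <- n / 2
    x[, , 1, 1:half] <- array(rnorm(64 * half, 1, 0.3), c(8, 8, half))
    x[, , 1, (half + 1):n] <- array(rnorm(64 * half, -1, 0.3), c(8, 8, half))
    list(x = x, y = rep(c("hot", "cold"), each = half))
  })
}

test_that("the stratified split matches the 70/10/20 contract", {
  y <- rep(letters[1:5], each = 20)
  sp <- splitDataset(y, seed = 5L)
  expect_equal(sum(sp == "train"), 70L)
  expect_equal(sum(sp == "val"), 10L)
  expect_equal(sum(sp == "test"), 20L)
  expect_identical(sp, splitDataset(y, seed = 5L))
  expect_false(identical(sp, splitDataset(y, seed = 6L)))
  # per-class proportions within one item of the global fractions
  for (cl in letters[1:5]) {
    tab <- table(factor(sp[y == cl], levels = c("train", "val", "test")))
    expect_true(all(abs(tab - c(14, 2, 4)) <= 1))
  }
  # exhaustive and disjoint by construction
  expect_true(all(sp %in% c("train", "val", "test")))
  expect_error(splitDataset(c("a", "a", "b")), "at least 3")
})

test_that("uneven class sizes still split within one item per class", {
  y <- rep(c("a", "b", "c"), times = c(13, 27, 41))
  sp <- splitDataset(y, seed = 2L)
  for (cl in unique(y)) {
    n <- sum(y == cl)
    tab <- table(factor(sp[y == cl], levels = c("train", "val", "test")))
    expect_true(all(abs(tab - n * c(0.7, 0.1, 0.2)) <= 1))
  }
})

test_that("a linearly separable toy problem is learned perfectly", {
  toy <- toySet()
  sp <- splitDataset(toy$y, seed = 3L)
  m <- trainModel(toy$x, toy$y, sp,
                  arch = architectureSpec(8, 1, 2, nBlocks = 1, filters = 4,
                                          denseUnits = 8),
                  cfg = trainConfig(maxEpochs = 20L, seed = 5L))
  acc <- evaluateAccuracy(m, toy$x[, , , sp == "test", drop = FALSE],
                          toy$y[sp == "test"])
  expect_equal(acc, 100)
  expect_lte(nrow(m@history), 20L)

  # outputs are probability vectors
  p <- predictProb(m, toy$x[, , , 1:7, drop = FALSE])
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, 7))
})

test_that("permuted labels train to chance-level accuracy", {
  toy <- toySet(n = 160, seed = 9)
  yPerm <- withr::with_seed(77, sample(toy$y))
  sp <- splitDataset(yPerm, seed = 4L)
  m <- trainModel(toy$x, yPerm, sp,
                  arch = architectureSpec(8, 1, 2, nBlocks = 1, filters = 4,
                                          denseUnits = 8),
                  cfg = trainConfig(maxEpochs = 10L, seed = 6L))
  nTest <- sum(sp == "test")
  acc <- evaluateAccuracy(m, toy$x[, , , sp == "test", drop = FALSE],
                          yPerm[sp == "test"])
  se <- 100 * sqrt(0.5 * 0.5 / nTest)
  expect_lt(abs(acc - 50), 3 * se)
})

test_that("zero patience stops at the first non-improving epoch", {
  toy <- toySet(n = 60, seed = 2)
  sp <- splitDataset(toy$y, seed = 1L)
  m <- trainModel(toy$x, toy$y, sp,
                  arch = architectureSpec(8, 1, 2, nBlocks = 1, filters = 2,
                                          denseUnits = 4),
                  cfg = trainConfig(maxEpochs = 30L, patience = 0L,
                                    seed = 8L))
  v <- m@history$valLoss
  # with zero patience every recorded epoch but the last must improve on
  # the running best, i.e. the head of the loss trace is strictly decreasing
  expect_true(length(v) <= 1L || all(diff(head(v, -1)) < 0))
  stopped <- nrow(m@history) < 30L
  expect_true(!stopped || v[length(v)] >= min(head(v, -1)))
})

test_that("accuracy is the percentage of correct classifications", {
  toy <- toySet()
  sp <- splitDataset(toy$y, seed = 3L)
  m <- trainModel(toy$x, toy$y, sp,
                  arch = architectureSpec(8, 1, 2, nBlocks = 1, filters = 2,
                                          denseUnits = 4),
                  cfg = trainConfig(maxEpochs = 3L, seed = 5L))
  idx <- which(sp == "test")
  p <- predictProb(m, toy$x[, , , idx, drop = FALSE])
  pred <- m@classes[max.col(p, ties.method = "first")]
  acc <- evaluateAccuracy(m, toy$x[, , , idx, drop = FALSE], toy$y[idx])
  expect_equal(acc, 100 * mean(pred == toy$y[idx]))
  # accuracy equals class-size-weighted mean of per-class recalls
  recalls <- vapply(unique(toy$y[idx]), function(cl)
    mean(pred[toy$y[idx] == cl] == cl), numeric(1))
  sizes <- table(toy$y[idx])[names(recalls)]
  expect_equal(acc, 100 * sum(recalls * sizes) / sum(sizes))
  expect_error(evaluateAccuracy(m, toy$x[, , , 0, drop = FALSE],
                                character()), "empty")
})

test_that("hyperparameter search is seeded, prefix-stable and monotone", {
  toy <- toySet(n = 60, seed = 5)
  sp <- splitDataset(toy$y, seed = 2L)
  runTune <- function(nTrials) tuneHyperparameters(
    toy$x, toy$y, sp,
    hpoConfig(nTrials = nTrials, maxEpochs = 2L, pruning = FALSE,
              blockChoices = 1L, filterChoices = c(2L, 4L),
              denseChoices = c(4L, 8L), seed = 11L))
  t1 <- runTune(1L)
  expect_equal(nrow(t1$trials), 1L)
  t1b <- runTune(1L)
  expect_equal(t1$trials, t1b$trials) # reproducible trial stream
  t2 <- runTune(2L)
  t3 <- runTune(3L)
  expect_equal(t2$trials[1, ], t1$trials[1, ]) # prefix property
  # best validation loss is a non-increasing envelope over the trial stream
  expect_lte(min(t2$trials$valLoss), min(t1$trials$valLoss))
  expect_lte(min(t3$trials$valLoss), min(t2$trials$valLoss))
})

test_that("the bayesian sampler runs and returns a completed best trial", {
  toy <- toySet(n = 60, seed = 6)
  sp <- splitDataset(toy$y, seed = 2L)
  tn <- tuneHyperparameters(
    toy$x, toy$y, sp,
    hpoConfig(nTrials = 4L, sampler = "bayesian", maxEpochs = 2L,
              blockChoices = 1L, filterChoices = c(2L, 4L),
              denseChoices = 4L, seed = 3L))
  expect_equal(nrow(tn$trials), 4L)
  expect_true(is.finite(tn$best$valLoss))
  expect_s4_class(tn$model, "CnnClassifier")
})
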