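# Shared fixtures and independent oracles used across the suite.

mkDose <- function(m, pitch = c(0.8, 0.8)) doseImage(m, pitchMm = pitch)

# Smooth positive random field (penumbra-like) for comparison tests.
smoothField <- function(n, seed = 1, sigmaMm = 2, pitch = 0.8) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * n), n, n)
    k <- portalQA:::.gaussKernel(sigmaMm, pitch)
    portalQA:::.convSeparable(x, k, k) + 0.2
  })
}

# Exhaustive brute-force gamma oracle: per-pixel search over all integer
# pixel offsets within the radius. Independent of the package's search.
bruteGamma <- function(R, E, ddPercent, dtaMm, radMm, pitch = 0.8) {
  maxref <- max(R)
  ddA <- ddPercent / 100 * maxref
  ny <- nrow(R)
  nx <- ncol(R)
  out <- matrix(0, ny, nx)
  rpx <- floor(radMm / pitch)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    best <- Inf
    for (di in -rpx:rpx) for (dj in -rpx:rpx) {
      d2 <- (di * pitch)^2 + (dj * pitch)^2
      if (d2 > radMm^2 + 1e-12) next
      ii <- i + di
      jj <- j + dj
      if (ii < 1 || ii > ny || jj < 1 || jj > nx) next
      cost <- d2 / dtaMm^2 + ((E[ii, jj] - R[i, j]) / ddA)^2
      if (cost < best) best <- cost
    }
    out[i, j] <- sqrt(best) * sign(E[i, j] - R[i, j])
  }
  out
}

# A small, fast rendering configuration for tests that need dose images.
tinySimConfig <- function(seed = 1L) {
  simConfig("SBRT", nArcs = 1L, nSegmentsPerArc = 6L,
            targetFieldMm = c(30, 30), gridShape = c(72L, 72L),
            nLeaves = 14L, leafWidthMm = 2.5, penumbraSigmaMm = 2,
            muMean = 300, muSd = 30, seed = seed)
}

# A deterministic rectangular one-segment plan on the tiny grid.
rectPlan <- function(config, halfX = 12, mu = 100, collimator = 0) {
  nl <- config@nLeaves
  centres <- (seq_len(nl) - (nl + 1) / 2) * config@leafWidthMm
  open <- abs(centres) + config@leafWidthMm / 2 <= config@targetFieldMm[2] / 2
  A <- rep(0, nl)
  B <- rep(0, nl)
  A[open] <- -halfX
  B[open] <- halfX
  treatmentPlan(list(list(segment(A, B, collimator, mu))),
                modality = config@modality)
}
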