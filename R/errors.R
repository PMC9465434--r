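#' The five mechanical error types
#'
#' Collimator rotation, systematic and random multileaf-collimator (MLC)
#' shifts, and systematic and random monitor-unit (MU) scaling.
#'
#' @return character vector of the five type identifiers, in canonical order.
#' @export
errorTypes <- function() {
  c("collimator", "mlc_systematic", "mlc_random", "mu_systematic", "mu_random")
}

# Magnitude range, grid step and relevance threshold per error type.
.errorTable <- function(errorType) {
  switch(errorType,
    collimator     = list(range = 2,  step = 0.2, threshold = 1,   unit = "deg"),
    mlc_systematic = list(range = 2,  step = 0.2, threshold = 1,   unit = "mm"),
    mlc_random     = list(range = 2,  step = 0.2, threshold = 0.5, unit = "mm"),
    mu_systematic  = list(range = 10, step = 1,   threshold = 5,   unit = "%"),
    mu_random      = list(range = 10, step = 1,   threshold = 3,   unit = "%"),
    stop(sprintf("unknown error type '%s'", errorType))
  )
}

.magnitudeRange <- function(errorType) {
  tab <- tryCatch(.errorTable(errorType), error = function(e) NULL)
  # random draws around grid endpoints can overshoot the nominal range a bit
  if (is.null(tab)) NULL
  else if (errorType %in% c("mlc_random", "mu_random")) 2 * tab$range
  else tab$range
}

#' Signed magnitude grid of an error type
#'
#' The symmetric grid of target magnitudes, from minus to plus the range at
#' the tabulated step, zero excluded: 20 values for every type (collimator
#' \eqn{\pm 2°} step 0.2, systematic/random MLC \eqn{\pm 2} mm step 0.2,
#' systematic/random MU \eqn{\pm 10\%} step 1).
#'
#' @param errorType one of [errorTypes()].
#' @param stepFactor multiply the tabulated step (e.g. 2 halves the grid for
#'   reduced desk-scale studies).
#' @return numeric vector of signed magnitudes, ascending, without zero.
#' @export
magnitudeGrid <- function(errorType, stepFactor = 1) {
  tab <- .errorTable(errorType)
  step <- tab$step * stepFactor
  n <- floor(tab$range / step + 1e-9)
  pos <- seq_len(n) * step
  c(-rev(pos), pos)
}

#' Relevance threshold of an error type
#'
#' @inheritParams magnitudeGrid
#' @return the absolute-magnitude threshold separating relevant from
#'   irrelevant errors (collimator 1 deg, systematic MLC 1 mm, random MLC
#'   0.5 mm, systematic MU 5\%, random MU 3\%).
#' @export
errorThreshold <- function(errorType) .errorTable(errorType)$threshold

#' Error-relevance (Level 2) label
#'
#' An error is labelled relevant when its absolute magnitude reaches the
#' type's threshold; the comparison is inclusive, so a magnitude exactly at
#' the threshold is relevant.
#'
#' @inheritParams magnitudeGrid
#' @param magnitude signed, non-zero magnitude.
#' @return "relevant" or "irrelevant".
#' @export
level2Label <- function(errorType, magnitude) {
  stopifnot(length(magnitude) >= 1, all(magnitude != 0))
  ifelse(abs(magnitude) >= .errorTable(errorType)$threshold,
         "relevant", "irrelevant")
}

#' Draw an error specification
#'
#' For the three systematic types this simply wraps the target magnitude
#' (sampling the affected bank(s) for systematic MLC shifts). For the two
#' random types, per-unit signed values are drawn uniformly on
#' \code{[magnitude - s, magnitude + s]} (s = half the type's range) — one
#' per segment for MU errors, one per leaf and segment for MLC errors — and
#' the realized signed mean of the draws is recorded as the label magnitude.
#'
#' @param errorType one of [errorTypes()].
#' @param magnitude target signed magnitude from the type's grid.
#' @param plan the [TreatmentPlan-class] the error will be applied to (used
#'   to size the per-unit draws).
#' @param seed RNG seed for the draws and the bank selection.
#' @return an [ErrorSpec-class].
#' @export
sampleErrorSpec <- function(errorType, magnitude, plan, seed = 1L) {
  stopifnot(magnitude != 0)
  tab <- .errorTable(errorType)
  withSeed(seed, {
    if (errorType %in% c("collimator", "mu_systematic")) {
      errorSpec(errorType, magnitude)
    } else if (errorType == "mlc_systematic") {
      bank <- sample(c("A", "B", "both"), 1)
      errorSpec(errorType, magnitude, banksAffected = bank)
    } else {
      nseg <- sum(vapply(plan@arcs, length, integer(1)))
      nUnit <- if (errorType == "mlc_random") {
        nLeaves <- length(plan@arcs[[1]][[1]]@bankA)
        nseg * nLeaves * 2L # every leaf of both banks
      } else nseg
      s <- tab$range / 2
      draws <- runif(nUnit, magnitude - s, magnitude + s)
      errorSpec(errorType, mean(draws), perUnitDraws = draws)
    }
  })
}

#' Apply a mechanical error to a plan
#'
#' Returns a perturbed copy of the plan; the input plan is not modified.
#'
#' \itemize{
#'   \item collimator: the magnitude (degrees) is added to every segment's
#'     collimator angle.
#'   \item mlc_systematic: the selected bank(s) are shifted as a whole on
#'     every segment. With both banks the aperture translates by the
#'     magnitude along +x; with a single bank a positive magnitude opens the
#'     field (bank A moves towards -x, bank B towards +x).
#'   \item mlc_random: each leaf of each bank of each segment receives its
#'     own signed shift from \code{perUnitDraws}.
#'   \item mu_systematic: every segment MU is scaled by
#'     (1 + magnitude/100).
#'   \item mu_random: segment s is scaled by (1 + draw_s/100).
#' }
#'
#' MLC shifts that would make a leaf pair overlap are clamped to a zero gap
#' at the pair midpoint; the number of clamped pairs is recorded in the
#' \code{clampedLeafPairs} attribute of the returned plan.
#'
#' @param plan a [TreatmentPlan-class].
#' @param spec an [ErrorSpec-class] (see [sampleErrorSpec()]).
#' @return the perturbed [TreatmentPlan-class]; attribute
#'   \code{clampedLeafPairs} counts leaf pairs clamped to zero gap.
#' @export
applyError <- function(plan, spec) {
  stopifnot(is(plan, "TreatmentPlan"), is(spec, "ErrorSpec"))
  validObject(spec)
  clamped <- 0L
  fixOverlap <- function(A, B) {
    bad <- A > B
    if (any(bad)) {
      clamped <<- clamped + sum(bad)
      mid <- (A[bad] + B[bad]) / 2
      A[bad] <- mid
      B[bad] <- mid
    }
    list(A = A, B = B)
  }
  segIdx <- 0L
  nLeaves <- length(plan@arcs[[1]][[1]]@bankA)
  newArcs <- lapply(plan@arcs, function(arc) lapply(arc, function(seg) {
    segIdx <<- segIdx + 1L
    switch(spec@errorType,
      collimator = {
        seg@collimator <- seg@collimator + spec@magnitude
        seg
      },
      mlc_systematic = {
        m <- spec@magnitude
        A <- seg@bankA
        B <- seg@bankB
        if (spec@banksAffected == "both") {
          A <- A + m
          B <- B + m
        } else if (spec@banksAffected == "A") {
          A <- A - m # positive magnitude opens the field
        } else {
          B <- B + m
        }
        fx <- fixOverlap(A, B)
        seg@bankA <- fx$A
        seg@bankB <- fx$B
        seg
      },
      mlc_random = {
        off <- (segIdx - 1L) * nLeaves * 2L
        dA <- spec@perUnitDraws[off + seq_len(nLeaves)]
        dB <- spec@perUnitDraws[off + nLeaves + seq_len(nLeaves)]
        fx <- fixOverlap(seg@bankA + dA, seg@bankB + dB)
        seg@bankA <- fx$A
        seg@bankB <- fx$B
        seg
      },
      mu_systematic = {
        seg@mu <- seg@mu * (1 + spec@magnitude / 100)
        seg
      },
      mu_random = {
        seg@mu <- seg@mu * (1 + spec@perUnitDraws[segIdx] / 100)
        seg
      },
      stop(sprintf("unknown error type '%s'", spec@errorType))
    )
  }))
  out <- treatmentPlan(newArcs, modality = plan@modality)
  attr(out, "clampedLeafPairs") <- clamped
  out
}

#' Level-1 / Level-2 label pair for an error
#'
#' @param spec an [ErrorSpec-class].
#' @return list with \code{level1} (the error type) and \code{level2}
#'   ("relevant"/"irrelevant" from the realized magnitude).
#' @export
labelPair <- function(spec) {
  list(level1 = spec@errorType,
       level2 = level2Label(spec@errorType, spec@magnitude))
}
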