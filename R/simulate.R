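#' Generate a synthetic arc treatment plan
#'
#' Draws one plan from the cohort described by a [SimConfig-class]: per-arc
#' monitor units from the configured normal distribution (clipped below at
#' 1 MU), a per-arc collimator angle, and per-segment apertures whose union
#' over the arc approximates the target field size. Each segment perturbs the
#' nominal rectangular field with per-leaf edge jitter and occasional deeper
#' leaf intrusions, giving the modulated, segment-varying apertures typical
#' of arc deliveries.
#'
#' Deterministic given \code{seed}: the same seed yields a bit-identical
#' plan.
#'
#' @param config a [SimConfig-class].
#' @param seed RNG seed; defaults to the seed recorded in \code{config}.
#' @return a [TreatmentPlan-class].
#' @export
generatePlan <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(seed, {
    fx <- config@targetFieldMm[1]
    fy <- config@targetFieldMm[2]
    nl <- config@nLeaves
    # leaves not fully inside the target field height stay closed
    leafCentres <- (seq_len(nl) - (nl + 1) / 2) * config@leafWidthMm
    open <- abs(leafCentres) + config@leafWidthMm / 2 <= fy / 2 + 1e-9
    arcs <- lapply(seq_len(config@nArcs), function(a) {
      arcMU <- max(1, rnorm(1, config@muMean, config@muSd))
      w <- runif(config@nSegmentsPerArc, 0.2, 1)
      segMU <- arcMU * w / sum(w)
      coll <- runif(1, -config@collimatorMaxDeg, config@collimatorMaxDeg)
      lapply(seq_len(config@nSegmentsPerArc), function(s) {
        A <- rep(0, nl)
        B <- rep(0, nl)
        # leaf travel limited to the field plus 3 jitter SDs, which keeps
        # the aperture provably inside the dose grid under the defaults
        lim <- fx / 2 + 3 * config@edgeJitterSdMm
        A[open] <- pmax(-lim, -fx / 2 + rnorm(sum(open), 0, config@edgeJitterSdMm))
        B[open] <- pmin(lim, fx / 2 + rnorm(sum(open), 0, config@edgeJitterSdMm))
        intr <- open & (runif(nl) < config@intrusionProb)
        if (any(intr)) {
          depth <- runif(sum(intr), 0, config@intrusionMaxFrac * fx)
          fromA <- runif(sum(intr)) < 0.5
          A[intr][fromA] <- A[intr][fromA] + depth[fromA]
          B[intr][!fromA] <- B[intr][!fromA] - depth[!fromA]
        }
        bad <- A > B
        if (any(bad)) {
          mid <- (A[bad] + B[bad]) / 2
          A[bad] <- mid
          B[bad] <- mid
        }
        segment(A, B, collimator = coll, mu = segMU[s])
      })
    })
    treatmentPlan(arcs, modality = config@modality)
  })
}

#' Generate a cohort of plans
#'
#' @param config a [SimConfig-class].
#' @param nPlans number of plans.
#' @param seed base seed; plan p uses \code{seed + p}.
#' @return list of [TreatmentPlan-class].
#' @export
generateCohort <- function(config, nPlans, seed = config@seed) {
  lapply(seq_len(nPlans), function(p) generatePlan(config, seed = seed + p))
}

# Fractional-coverage aperture mask of one segment (before collimator
# rotation): leaves run along y, leaf travel along x; each pixel holds the
# fraction of its area inside the aperture.
.apertureMask <- function(seg, config) {
  ny <- config@gridShape[1]; nx <- config@gridShape[2]
  py <- config@pixelPitchMm[1]; px <- config@pixelPitchMm[2]
  nl <- length(seg@bankA)
  lw <- config@leafWidthMm
  # pixel edges in mm (grid centre at 0)
  xe <- (seq_len(nx + 1) - 1 - nx / 2) * px
  ye <- (seq_len(ny + 1) - 1 - ny / 2) * py
  leafLo <- (seq_len(nl) - 1 - nl / 2) * lw
  leafHi <- leafLo + lw
  # y-coverage Y[i, l]: fraction of pixel row i covered by leaf l
  Y <- pmax(outer(ye[-1], leafHi, pmin) -
            outer(ye[-length(ye)], leafLo, pmax), 0) / py
  # x-coverage X[l, j]: fraction of pixel column j inside [A_l, B_l]
  X <- pmax(outer(seg@bankB, xe[-1], pmin) -
            outer(seg@bankA, xe[-length(xe)], pmax), 0) / px
  Y %*% X
}

# Geometry guard: the open aperture (plus penumbra tails and rotation) must
# stay inside the dose grid.
.checkAperture <- function(seg, config) {
  openIdx <- which(seg@bankB - seg@bankA > 1e-9)
  if (!length(openIdx)) return(invisible(TRUE))
  nl <- config@nLeaves
  lw <- config@leafWidthMm
  ymax <- max(abs((openIdx - 1 - nl / 2) * lw), abs((openIdx - nl / 2) * lw))
  xmax <- max(abs(seg@bankA[openIdx]), abs(seg@bankB[openIdx]))
  th <- seg@collimator * pi / 180
  rx <- abs(cos(th)) * xmax + abs(sin(th)) * ymax # rotated bounding box
  ry <- abs(sin(th)) * xmax + abs(cos(th)) * ymax
  margin <- 2 * config@penumbraSigmaMm
  halfX <- config@gridShape[2] * config@pixelPitchMm[2] / 2
  halfY <- config@gridShape[1] * config@pixelPitchMm[1] / 2
  if (rx + margin > halfX || ry + margin > halfY)
    stop("aperture exceeds the dose grid")
  invisible(TRUE)
}

#' Render the surrogate time-integrated portal dose of an arc or plan
#'
#' For every segment a fractional-coverage aperture mask is built from the
#' leaf positions, rotated by the collimator angle about the grid centre
#' (bilinear), and weighted by the segment MU; the MU-weighted fluence is
#' summed over segments and convolved with a Gaussian penumbra kernel
#' (bin-integrated, sigma = \code{penumbraSigmaMm}). Dose is exactly linear
#' in MU.
#'
#' This is a surrogate for a fitted portal-dose prediction model: it
#' preserves the geometric and MU structure a 2D pre-treatment dose
#' prediction provides, without modelling detector response or scatter.
#'
#' @param plan a [TreatmentPlan-class].
#' @param config the [SimConfig-class] holding the rendering geometry.
#' @param arc arc index, or NULL to integrate the whole plan.
#' @return a [DoseImage-class].
#' @seealso [renderArcDoses()] for one image per arc (the dataset unit).
#' @export
renderDose <- function(plan, config, arc = NULL) {
  stopifnot(is(plan, "TreatmentPlan"), is(config, "SimConfig"))
  segs <- if (is.null(arc)) unlist(plan@arcs, recursive = FALSE)
          else plan@arcs[[arc]]
  ny <- config@gridShape[1]; nx <- config@gridShape[2]
  fl <- matrix(0, ny, nx)
  for (seg in segs) {
    if (seg@mu == 0) next
    .checkAperture(seg, config)
    m <- .apertureMask(seg, config)
    if (abs(seg@collimator) > 1e-9)
      m <- rotateBilinear(m, seg@collimator)
    fl <- fl + seg@mu * m
  }
  ky <- .gaussKernel(config@penumbraSigmaMm, config@pixelPitchMm[1])
  kx <- .gaussKernel(config@penumbraSigmaMm, config@pixelPitchMm[2])
  dose <- .convSeparable(fl, ky, kx)
  dose[dose < 0] <- 0 # bilinear rotation can leave tiny negative crumbs
  doseImage(dose, pitchMm = config@pixelPitchMm, sddCm = config@sddCm,
            modality = config@modality)
}

#' @rdname renderDose
#' @return \code{renderArcDoses}: list with one [DoseImage-class] per arc.
#' @export
renderArcDoses <- function(plan, config) {
  lapply(seq_along(plan@arcs), function(a) renderDose(plan, config, arc = a))
}
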