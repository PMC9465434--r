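#' @import methods
NULL

# Image coordinate convention used throughout the package: a matrix element
# [i, j] is row i = y, column j = x; x is the leaf-travel axis. The physical
# position of a pixel centre is ((j - (nx+1)/2) * pitch_x,
# (i - (ny+1)/2) * pitch_y) mm, so the grid centre sits between pixels for
# even dimensions.

#' One aperture state of a treatment arc
#'
#' A segment (control point) holds the field-edge position of every leaf in
#' the two opposing multileaf-collimator banks, the collimator angle, and the
#' monitor units delivered while the aperture is held. Bank A is the bank on
#' the negative-x side (its position is the left field edge), bank B the
#' opposing bank; for every leaf pair the bank A position must not exceed the
#' bank B position.
#'
#' @slot bankA numeric, per-leaf field-edge position of bank A in mm.
#' @slot bankB numeric, per-leaf field-edge position of bank B in mm.
#' @slot collimator numeric(1), collimator angle in degrees.
#' @slot mu numeric(1), non-negative monitor units.
#' @exportClass Segment
setClass("Segment",
  representation(
    bankA = "numeric",
    bankB = "numeric",
    collimator = "numeric",
    mu = "numeric"
  )
)

setValidity("Segment", function(object) {
  msg <- character()
  if (length(object@bankA) != length(object@bankB))
    msg <- c(msg, "bankA and bankB must have one position per leaf pair each")
  if (any(object@bankA > object@bankB + 1e-9))
    msg <- c(msg, "bankA position must not exceed bankB position (overlapping aperture)")
  if (length(object@mu) != 1L || is.na(object@mu) || object@mu < 0)
    msg <- c(msg, "mu must be a single non-negative number")
  if (length(object@collimator) != 1L || is.na(object@collimator))
    msg <- c(msg, "collimator must be a single angle in degrees")
  if (length(msg)) msg else TRUE
})

#' @param bankA,bankB per-leaf field-edge positions in mm.
#' @param collimator collimator angle in degrees.
#' @param mu monitor units.
#' @rdname Segment-class
#' @export
segment <- function(bankA, bankB, collimator = 0, mu = 1) {
  new("Segment", bankA = as.numeric(bankA), bankB = as.numeric(bankB),
      collimator = as.numeric(collimator), mu = as.numeric(mu))
}

#' An arc treatment plan
#'
#' An ordered list of arcs, each an ordered list of [Segment] objects, plus
#' the modality tag the plan was generated under ("VMAT" or "SBRT").
#'
#' @slot modality character(1), "VMAT" or "SBRT".
#' @slot arcs list of arcs; each arc is a list of [Segment] objects.
#' @exportClass TreatmentPlan
setClass("TreatmentPlan",
  representation(
    modality = "character",
    arcs = "list"
  )
)

setValidity("TreatmentPlan", function(object) {
  msg <- character()
  if (!object@modality %in% c("VMAT", "SBRT"))
    msg <- c(msg, "modality must be 'VMAT' or 'SBRT'")
  if (length(object@arcs) < 1L)
    msg <- c(msg, "plan must contain at least one arc")
  for (arc in object@arcs) {
    if (!is.list(arc) || length(arc) < 1L) {
      msg <- c(msg, "every arc must contain at least one segment")
      break
    }
    if (!all(vapply(arc, is, logical(1), class2 = "Segment"))) {
      msg <- c(msg, "arc elements must be Segment objects")
      break
    }
  }
  if (!length(msg) && totalMU(object) <= 0)
    msg <- c(msg, "total plan MU must be positive")
  if (length(msg)) msg else TRUE
})

#' @param modality "VMAT" or "SBRT".
#' @param arcs list of arcs (each a list of [Segment]s).
#' @rdname TreatmentPlan-class
#' @export
treatmentPlan <- function(arcs, modality = "VMAT") {
  new("TreatmentPlan", modality = modality, arcs = arcs)
}

#' A 2D time-integrated portal dose image
#'
#' Non-negative scalar dose on a fixed-pitch rectangular grid at a given
#' source-detector distance.
#'
#' @slot pixels numeric matrix of dose values (row = y, column = x).
#' @slot pitchMm numeric(2), pixel pitch in mm as (y, x); default 0.8 x 0.8.
#' @slot sddCm numeric(1), source-detector distance in cm.
#' @slot modality character(1), modality tag carried from the plan.
#' @exportClass DoseImage
setClass("DoseImage",
  representation(
    pixels = "matrix",
    pitchMm = "numeric",
    sddCm = "numeric",
    modality = "character"
  ),
  prototype(pitchMm = c(0.8, 0.8), sddCm = 100, modality = "VMAT")
)

setValidity("DoseImage", function(object) {
  msg <- character()
  if (any(!is.finite(object@pixels)))
    msg <- c(msg, "dose pixels must be finite")
  else if (any(object@pixels < 0))
    msg <- c(msg, "dose pixels must be non-negative")
  if (length(object@pitchMm) != 2L || any(object@pitchMm <= 0))
    msg <- c(msg, "pitchMm must be two positive values (y, x)")
  if (length(object@sddCm) != 1L || object@sddCm <= 0)
    msg <- c(msg, "sddCm must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' @param pixels dose matrix.
#' @param pitchMm pixel pitch (y, x) in mm.
#' @param sddCm source-detector distance in cm.
#' @rdname DoseImage-class
#' @export
doseImage <- function(pixels, pitchMm = c(0.8, 0.8), sddCm = 100,
                      modality = "VMAT") {
  new("DoseImage", pixels = pixels, pitchMm = rep(as.numeric(pitchMm), length.out = 2),
      sddCm = as.numeric(sddCm), modality = modality)
}

#' Configuration of the plan/dose simulator
#'
#' Holds the geometry and sampling parameters that define a synthetic cohort:
#' arc and segment counts, the per-arc MU distribution, the target field
#' size, multileaf-collimator geometry, penumbra width, dose grid, and the
#' amount of per-segment aperture modulation.
#'
#' @slot modality character(1), "VMAT" or "SBRT".
#' @slot nArcs integer, arcs per plan.
#' @slot nSegmentsPerArc integer, segments (control points) per arc.
#' @slot muMean,muSd numeric, per-arc monitor-unit distribution.
#' @slot targetFieldMm numeric(2), target field size (x, y) in mm.
#' @slot penumbraSigmaMm numeric(1), Gaussian penumbra sigma in mm.
#' @slot leafWidthMm numeric(1), projected leaf width in mm.
#' @slot nLeaves integer, number of leaf pairs.
#' @slot gridShape integer(2), dose grid (rows, cols).
#' @slot pixelPitchMm numeric(2), pixel pitch (y, x) in mm.
#' @slot sddCm numeric(1), source-detector distance in cm.
#' @slot edgeJitterSdMm numeric(1), per-leaf, per-segment field-edge jitter SD.
#' @slot intrusionProb numeric(1), probability a leaf intrudes into the field
#'   in a given segment.
#' @slot intrusionMaxFrac numeric(1), maximum intrusion depth as a fraction of
#'   the field width.
#' @slot collimatorMaxDeg numeric(1), per-arc collimator angle drawn uniformly
#'   in +/- this bound.
#' @slot seed integer, base RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    modality = "character",
    nArcs = "integer",
    nSegmentsPerArc = "integer",
    muMean = "numeric",
    muSd = "numeric",
    targetFieldMm = "numeric",
    penumbraSigmaMm = "numeric",
    leafWidthMm = "numeric",
    nLeaves = "integer",
    gridShape = "integer",
    pixelPitchMm = "numeric",
    sddCm = "numeric",
    edgeJitterSdMm = "numeric",
    intrusionProb = "numeric",
    intrusionMaxFrac = "numeric",
    collimatorMaxDeg = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nArcs < 1L || object@nSegmentsPerArc < 1L)
    msg <- c(msg, "nArcs and nSegmentsPerArc must be positive")
  if (object@muMean <= 0 || object@muSd < 0)
    msg <- c(msg, "muMean must be positive and muSd non-negative")
  if (length(object@targetFieldMm) != 2L || any(object@targetFieldMm <= 0))
    msg <- c(msg, "targetFieldMm must be two positive values (x, y)")
  if (object@penumbraSigmaMm <= 0 || object@leafWidthMm <= 0 ||
      object@nLeaves < 1L)
    msg <- c(msg, "penumbraSigmaMm, leafWidthMm and nLeaves must be positive")
  if (length(object@gridShape) != 2L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape must be two values of at least 8 pixels")
  if (any(object@pixelPitchMm <= 0))
    msg <- c(msg, "pixelPitchMm must be positive")
  # grid must contain the field, its penumbra and the rotation margin
  if (!length(msg)) {
    halfGrid <- rev(object@gridShape) * object@pixelPitchMm[2:1] / 2
    need <- object@targetFieldMm / 2 + 4 * object@penumbraSigmaMm +
      3 * object@edgeJitterSdMm
    if (any(need > halfGrid))
      msg <- c(msg, "grid too small to contain the field plus penumbra margin")
  }
  if (length(msg)) msg else TRUE
})

#' @param modality "VMAT" or "SBRT"; selects the cohort defaults below.
#' @param nArcs,nSegmentsPerArc plan structure.
#' @param muMean,muSd per-arc MU distribution (VMAT 333/85, SBRT 1746/251).
#' @param targetFieldMm target field size (x, y) in mm.
#' @param penumbraSigmaMm Gaussian penumbra sigma (mm).
#' @param leafWidthMm,nLeaves multileaf-collimator geometry.
#' @param gridShape dose grid (rows, cols).
#' @param pixelPitchMm pixel pitch (y, x) in mm.
#' @param sddCm source-detector distance in cm.
#' @param edgeJitterSdMm,intrusionProb,intrusionMaxFrac per-segment aperture
#'   modulation parameters.
#' @param collimatorMaxDeg per-arc collimator angle bound (degrees).
#' @param seed base RNG seed.
#' @rdname SimConfig-class
#' @export
simConfig <- function(modality = c("VMAT", "SBRT"),
                      nArcs = 2L,
                      nSegmentsPerArc = 24L,
                      muMean = NULL, muSd = NULL,
                      targetFieldMm = NULL,
                      penumbraSigmaMm = NULL,
                      leafWidthMm = NULL, nLeaves = NULL,
                      gridShape = NULL,
                      pixelPitchMm = c(0.8, 0.8),
                      sddCm = 100,
                      edgeJitterSdMm = 1.5,
                      intrusionProb = 0.25,
                      intrusionMaxFrac = 0.35,
                      collimatorMaxDeg = 4,
                      seed = 1L) {
  modality <- match.arg(modality)
  if (modality == "VMAT") {
    if (is.null(muMean)) muMean <- 333
    if (is.null(muSd)) muSd <- 85
    if (is.null(targetFieldMm)) targetFieldMm <- c(95, 87)
    if (is.null(penumbraSigmaMm)) penumbraSigmaMm <- 3
    if (is.null(leafWidthMm)) leafWidthMm <- 5
    if (is.null(nLeaves)) nLeaves <- 22L
    if (is.null(gridShape)) gridShape <- c(176L, 176L)
  } else {
    if (is.null(muMean)) muMean <- 1746
    if (is.null(muSd)) muSd <- 251
    if (is.null(targetFieldMm)) targetFieldMm <- c(49, 47)
    if (is.null(penumbraSigmaMm)) penumbraSigmaMm <- 2.5
    if (is.null(leafWidthMm)) leafWidthMm <- 2.5
    if (is.null(nLeaves)) nLeaves <- 24L
    if (is.null(gridShape)) gridShape <- c(104L, 104L)
  }
  new("SimConfig", modality = modality, nArcs = as.integer(nArcs),
      nSegmentsPerArc = as.integer(nSegmentsPerArc),
      muMean = muMean, muSd = muSd,
      targetFieldMm = as.numeric(targetFieldMm),
      penumbraSigmaMm = penumbraSigmaMm,
      leafWidthMm = leafWidthMm, nLeaves = as.integer(nLeaves),
      gridShape = as.integer(gridShape),
      pixelPitchMm = rep(as.numeric(pixelPitchMm), length.out = 2),
      sddCm = sddCm,
      edgeJitterSdMm = edgeJitterSdMm, intrusionProb = intrusionProb,
      intrusionMaxFrac = intrusionMaxFrac,
      collimatorMaxDeg = collimatorMaxDeg, seed = as.integer(seed))
}

#' A mechanical delivery error specification
#'
#' @slot errorType one of "collimator", "mlc_systematic", "mlc_random",
#'   "mu_systematic", "mu_random".
#' @slot magnitude signed magnitude (degrees, mm or percent). For random
#'   types this is the realized signed mean of the per-unit draws.
#' @slot perUnitDraws numeric, the per-segment (or per-leaf) signed draws for
#'   random types; empty for systematic types.
#' @slot banksAffected "A", "B" or "both" (systematic MLC shifts only).
#' @exportClass ErrorSpec
setClass("ErrorSpec",
  representation(
    errorType = "character",
    magnitude = "numeric",
    perUnitDraws = "numeric",
    banksAffected = "character"
  ),
  prototype(perUnitDraws = numeric(), banksAffected = "both")
)

setValidity("ErrorSpec", function(object) {
  msg <- character()
  if (!object@errorType %in% errorTypes())
    msg <- c(msg, sprintf("unknown error type '%s'", object@errorType))
  if (length(object@magnitude) != 1L || !is.finite(object@magnitude) ||
      object@magnitude == 0)
    msg <- c(msg, "magnitude must be a single non-zero finite value")
  else {
    rng <- .magnitudeRange(object@errorType)
    if (!is.null(rng) && abs(object@magnitude) > rng + 1e-9)
      msg <- c(msg, sprintf("|magnitude| exceeds the %s range of %g",
                            object@errorType, rng))
  }
  if (!object@banksAffected %in% c("A", "B", "both"))
    msg <- c(msg, "banksAffected must be 'A', 'B' or 'both'")
  if (length(object@perUnitDraws) &&
      abs(mean(object@perUnitDraws) - object@magnitude) > 1e-9)
    msg <- c(msg, "magnitude must equal the mean of perUnitDraws")
  if (length(msg)) msg else TRUE
})

#' @param errorType error type string.
#' @param magnitude signed magnitude.
#' @param perUnitDraws per-unit draws for random types.
#' @param banksAffected bank selection for systematic MLC errors.
#' @rdname ErrorSpec-class
#' @export
errorSpec <- function(errorType, magnitude, perUnitDraws = numeric(),
                      banksAffected = "both") {
  new("ErrorSpec", errorType = errorType, magnitude = as.numeric(magnitude),
      perUnitDraws = as.numeric(perUnitDraws), banksAffected = banksAffected)
}

#' A dose-comparison image
#'
#' A 1- to 3-channel float image produced by one of the twelve comparison
#' variants. Channels share one shape and are stored as a 3D array
#' (rows, cols, channels) with named channels.
#'
#' @slot channels numeric array (ny, nx, nchannel).
#' @slot method one of [comparisonMethods()].
#' @slot channelNames character, one name per channel.
#' @slot pitchMm numeric(2), pixel pitch (y, x) in mm.
#' @slot meta list, provenance metadata (e.g. the crop box).
#' @exportClass ComparisonImage
setClass("ComparisonImage",
  representation(
    channels = "array",
    method = "character",
    channelNames = "character",
    pitchMm = "numeric",
    meta = "list"
  ),
  prototype(pitchMm = c(0.8, 0.8), meta = list())
)

setValidity("ComparisonImage", function(object) {
  msg <- character()
  d <- dim(object@channels)
  if (length(d) != 3L)
    msg <- c(msg, "channels must be a 3D array (rows, cols, channels)")
  else {
    if (d[3] < 1L || d[3] > 3L)
      msg <- c(msg, "between 1 and 3 channels are supported")
    if (length(object@channelNames) != d[3])
      msg <- c(msg, "channelNames must name every channel")
    expected <- .methodChannelCount(object@method)
    if (!is.na(expected) && d[3] != expected)
      msg <- c(msg, sprintf("method '%s' must have %d channel(s)",
                            object@method, expected))
  }
  if (any(!is.finite(object@channels)))
    msg <- c(msg, "all channel values must be finite")
  if (!object@method %in% comparisonMethods())
    msg <- c(msg, sprintf("unknown comparison method '%s'", object@method))
  if (length(msg)) msg else TRUE
})

.comparisonImage <- function(channels, method, channelNames,
                             pitchMm = c(0.8, 0.8), meta = list()) {
  if (is.matrix(channels))
    channels <- array(channels, c(dim(channels), 1L))
  new("ComparisonImage", channels = channels, method = method,
      channelNames = channelNames, pitchMm = pitchMm, meta = meta)
}

#' Gamma-analysis criteria
#'
#' Global gamma: the dose-difference criterion is a percentage of the maximum
#' dose of the reference distribution.
#'
#' @slot ddPercent numeric(1), dose-difference criterion (% of max ref dose).
#' @slot dtaMm numeric(1), distance-to-agreement criterion in mm.
#' @slot searchRadiusMm numeric(1), candidate search radius in mm.
#' @slot subsample integer(1), candidate grid refinement factor (candidate
#'   spacing = pixel pitch / subsample); 1 restricts candidates to pixel
#'   centres.
#' @exportClass GammaCriteria
setClass("GammaCriteria",
  representation(
    ddPercent = "numeric",
    dtaMm = "numeric",
    searchRadiusMm = "numeric",
    subsample = "integer"
  )
)

setValidity("GammaCriteria", function(object) {
  msg <- character()
  if (object@ddPercent <= 0 || object@dtaMm <= 0)
    msg <- c(msg, "ddPercent and dtaMm must be positive")
  if (object@searchRadiusMm < object@dtaMm)
    msg <- c(msg, "searchRadiusMm must be at least dtaMm")
  if (object@subsample < 1L)
    msg <- c(msg, "subsample must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' @param ddPercent dose-difference criterion in percent of max reference dose.
#' @param dtaMm distance-to-agreement criterion in mm.
#' @param searchRadiusMm search radius; default 3 x dtaMm.
#' @param subsample candidate-grid refinement factor; default 4.
#' @rdname GammaCriteria-class
#' @export
gammaCriteria <- function(ddPercent, dtaMm, searchRadiusMm = 3 * dtaMm,
                          subsample = 4L) {
  new("GammaCriteria", ddPercent = as.numeric(ddPercent),
      dtaMm = as.numeric(dtaMm), searchRadiusMm = as.numeric(searchRadiusMm),
      subsample = as.integer(subsample))
}

#' Structural-similarity parameters
#'
#' @slot windowSidePx odd integer, sliding-window side.
#' @slot k1,k2 small positive stabilisation constants.
#' @slot dynamicRange numeric(1), luminance dynamic range L; if NA, the
#'   maximum of the reference image is used.
#' @exportClass SsimParams
setClass("SsimParams",
  representation(
    windowSidePx = "integer",
    k1 = "numeric",
    k2 = "numeric",
    dynamicRange = "numeric"
  ),
  prototype(windowSidePx = 11L, k1 = 0.01, k2 = 0.03, dynamicRange = NA_real_)
)

setValidity("SsimParams", function(object) {
  msg <- character()
  if (object@windowSidePx < 3L || object@windowSidePx %% 2L == 0L)
    msg <- c(msg, "windowSidePx must be an odd integer >= 3")
  if (object@k1 <= 0 || object@k2 <= 0)
    msg <- c(msg, "k1 and k2 must be positive")
  if (length(msg)) msg else TRUE
})

#' @param windowSidePx window side in pixels (odd).
#' @param k1,k2 stabilisation constants.
#' @param dynamicRange dynamic range L (NA = max reference dose).
#' @rdname SsimParams-class
#' @export
ssimParams <- function(windowSidePx = 11L, k1 = 0.01, k2 = 0.03,
                       dynamicRange = NA_real_) {
  new("SsimParams", windowSidePx = as.integer(windowSidePx), k1 = k1, k2 = k2,
      dynamicRange = as.numeric(dynamicRange))
}

#' Per-channel dataset statistics used for normalization
#'
#' Mean and standard deviation pooled over all pixels of all training images,
#' with clip bounds at mean +/- 2 standard deviations.
#'
#' @slot mean,sd per-channel pooled statistics.
#' @slot clipMin,clipMax per-channel clip bounds (mean -/+ 2 sd).
#' @exportClass DatasetStats
setClass("DatasetStats",
  representation(mean = "numeric", sd = "numeric",
                 clipMin = "numeric", clipMax = "numeric")
)

setValidity("DatasetStats", function(object) {
  msg <- character()
  n <- length(object@mean)
  if (length(object@sd) != n || length(object@clipMin) != n ||
      length(object@clipMax) != n)
    msg <- c(msg, "all statistic vectors must have one value per channel")
  if (any(object@sd <= 0))
    msg <- c(msg, "per-channel standard deviation must be positive")
  if (any(object@clipMin >= object@clipMax))
    msg <- c(msg, "clipMin must be below clipMax")
  if (length(msg)) msg else TRUE
})
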