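#' @name accessors
#' @title Accessors for the core classes
#' @description Slot accessors for [TreatmentPlan-class], [DoseImage-class]
#'   and [ComparisonImage-class] objects.
#' @param x an object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("totalMU", function(x) standardGeneric("totalMU"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("pitchMm", function(x) standardGeneric("pitchMm"))

#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("comparisonMethod", function(x) standardGeneric("comparisonMethod"))

#' @rdname accessors
#' @export
setMethod("arcs", "TreatmentPlan", function(x) x@arcs)

#' @rdname accessors
#' @export
setMethod("modality", "TreatmentPlan", function(x) x@modality)

#' @rdname accessors
#' @export
setMethod("modality", "DoseImage", function(x) x@modality)

#' @rdname accessors
#' @export
setMethod("totalMU", "TreatmentPlan", function(x)
  sum(vapply(x@arcs, function(arc)
    sum(vapply(arc, slot, numeric(1), name = "mu")), numeric(1))))

#' @rdname accessors
#' @export
setMethod("pixels", "DoseImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pitchMm", "DoseImage", function(x) x@pitchMm)

#' @rdname accessors
#' @export
setMethod("pitchMm", "ComparisonImage", function(x) x@pitchMm)

#' @rdname accessors
#' @export
setMethod("channels", "ComparisonImage", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("channelNames", "ComparisonImage", function(x) x@channelNames)

#' @rdname accessors
#' @export
setMethod("comparisonMethod", "ComparisonImage", function(x) x@method)

setMethod("show", "Segment", function(object) {
  cat(sprintf("Segment: %d leaf pairs, collimator %.1f deg, %.1f MU\n",
              length(object@bankA), object@collimator, object@mu))
})

setMethod("show", "TreatmentPlan", function(object) {
  nseg <- vapply(object@arcs, length, integer(1))
  cat(sprintf("TreatmentPlan (%s-like): %d arc(s), %s segments, total %.1f MU\n",
              object@modality, length(object@arcs),
              paste(nseg, collapse = "+"), totalMU(object)))
})

setMethod("show", "DoseImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "DoseImage (%s-like): %d x %d px @ %.2g x %.2g mm, SDD %g cm, max %.3g\n",
    object@modality, d[1], d[2], object@pitchMm[1], object@pitchMm[2],
    object@sddCm, max(object@pixels)))
})

setMethod("show", "ComparisonImage", function(object) {
  d <- dim(object@channels)
  cat(sprintf("ComparisonImage [%s]: %d x %d px, %d channel(s): %s\n",
              object@method, d[1], d[2], d[3],
              paste(object@channelNames, collapse = ", ")))
})

setMethod("show", "ErrorSpec", function(object) {
  unit <- switch(object@errorType,
    collimator = "deg", mlc_systematic = "mm", mlc_random = "mm",
    mu_systematic = "%", mu_random = "%")
  extra <- if (length(object@perUnitDraws))
    sprintf(" (mean of %d draws)", length(object@perUnitDraws)) else ""
  cat(sprintf("ErrorSpec: %s %+g %s%s\n", object@errorType,
              object@magnitude, unit, extra))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig (%s-like): %d arcs x %d segments, MU ~ N(%g, %g), field %g x %g mm\n",
    object@modality, object@nArcs, object@nSegmentsPerArc, object@muMean,
    object@muSd, object@targetFieldMm[1], object@targetFieldMm[2]))
})
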