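# File interfaces: 32-bit float TIFF with a JSON sidecar for images (the
# TIFF writer stores samples in [0, 1], so an affine offset/scale per
# channel is recorded in the sidecar), and a YAML document for plans.

.sidecarPath <- function(path) paste0(path, ".json")

.writeChannelsTiff <- function(chlist, path) {
  scales <- lapply(chlist, function(ch) {
    lo <- min(ch)
    hi <- max(ch)
    sc <- if (hi > lo) hi - lo else 1
    list(offset = lo, scale = sc)
  })
  pages <- mapply(function(ch, s) (ch - s$offset) / s$scale, chlist, scales,
                  SIMPLIFY = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  scales
}

.readChannelsTiff <- function(path, scales) {
  pages <- tiff::readTIFF(path, all = TRUE)
  mapply(function(ch, s) ch * s$scale + s$offset, pages, scales,
         SIMPLIFY = FALSE)
}

#' Write / read a dose image as float TIFF plus JSON sidecar
#'
#' The sidecar records the affine intensity scale, the pixel pitch, the
#' source-detector distance and the modality tag; the round trip is exact
#' up to 32-bit float precision.
#'
#' @param img a [DoseImage-class].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return \code{writeDoseImage}: the path, invisibly. \code{readDoseImage}:
#'   the [DoseImage-class].
#' @export
writeDoseImage <- function(img, path) {
  stopifnot(is(img, "DoseImage"))
  scales <- .writeChannelsTiff(list(img@pixels), path)
  jsonlite::write_json(
    list(type = "DoseImage", pitchMm = img@pitchMm, sddCm = img@sddCm,
         modality = img@modality, channels = scales),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDoseImage
#' @export
readDoseImage <- function(path) {
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  ch <- .readChannelsTiff(path, list(as.list(meta$channels[1, ])))
  px <- ch[[1]]
  px[px < 0] <- 0 # float32 rounding can graze below zero
  doseImage(px, pitchMm = unlist(meta$pitchMm), sddCm = meta$sddCm,
            modality = meta$modality)
}

#' Write / read a comparison image as multi-channel float TIFF
#'
#' One TIFF page per channel; channel names, the method and the per-channel
#' affine scales live in the JSON sidecar.
#'
#' @param img a [ComparisonImage-class].
#' @param path TIFF file path.
#' @return \code{writeComparisonImage}: the path, invisibly.
#'   \code{readComparisonImage}: the [ComparisonImage-class].
#' @export
writeComparisonImage <- function(img, path) {
  stopifnot(is(img, "ComparisonImage"))
  nch <- dim(img@channels)[3]
  chlist <- lapply(seq_len(nch), function(c) img@channels[, , c])
  scales <- .writeChannelsTiff(chlist, path)
  jsonlite::write_json(
    list(type = "ComparisonImage", method = img@method,
         channelNames = img@channelNames, pitchMm = img@pitchMm,
         channels = scales),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeComparisonImage
#' @export
readComparisonImage <- function(path) {
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  scales <- lapply(seq_len(nrow(meta$channels)),
                   function(i) as.list(meta$channels[i, ]))
  ch <- .readChannelsTiff(path, scales)
  arr <- array(unlist(ch), c(dim(ch[[1]]), length(ch)))
  .comparisonImage(arr, meta$method, unlist(meta$channelNames),
                   pitchMm = unlist(meta$pitchMm))
}

#' Write / read a treatment plan as a structured text document
#'
#' YAML with one record per segment (leaf banks, collimator angle, MU),
#' grouped by arc.
#'
#' @param plan a [TreatmentPlan-class].
#' @param path file path.
#' @return \code{writePlan}: the path, invisibly. \code{readPlan}: the
#'   [TreatmentPlan-class].
#' @export
writePlan <- function(plan, path) {
  stopifnot(is(plan, "TreatmentPlan"))
  doc <- list(modality = plan@modality,
              arcs = lapply(plan@arcs, function(arc)
                lapply(arc, function(s)
                  list(bankA = s@bankA, bankB = s@bankB,
                       collimator = s@collimator, mu = s@mu))))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname writePlan
#' @export
readPlan <- function(path) {
  doc <- yaml::read_yaml(path)
  treatmentPlan(lapply(doc$arcs, function(arc)
    lapply(arc, function(s)
      segment(s$bankA, s$bankB, s$collimator, s$mu))),
    modality = doc$modality)
}
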