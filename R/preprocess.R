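#' Crop a comparison image to the radiation field
#'
#' The crop box is the bounding box of reference-dose pixels at or above
#' \code{threshold} times the maximum reference dose (the 10\% low-dose
#' threshold by default). The mask is defined on the error-free reference
#' dose — the radiation field is a dose concept, and comparison images can
#' be signed — and all channels are cropped to the same box.
#'
#' @param comp a [ComparisonImage-class] (or [DoseImage-class]).
#' @param ref the reference [DoseImage-class], same shape.
#' @param threshold low-dose threshold as a fraction of max reference dose.
#' @return the cropped object; the box is recorded in \code{meta$cropBox}
#'   as (row0, row1, col0, col1) for comparison images.
#' @export
cropToField <- function(comp, ref, threshold = 0.1) {
  stopifnot(is(ref, "DoseImage"), threshold > 0, threshold < 1)
  R <- ref@pixels
  mask <- R >= threshold * max(R)
  if (!any(mask)) stop("empty field mask: no pixel reaches the threshold")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  box <- c(rows[1], rows[2], cols[1], cols[2])
  if (is(comp, "DoseImage")) {
    if (!identical(dim(comp@pixels), dim(R)))
      stop("comparison and reference images must share one shape")
    out <- comp
    out@pixels <- comp@pixels[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    return(out)
  }
  stopifnot(is(comp, "ComparisonImage"))
  if (!identical(dim(comp@channels)[1:2], dim(R)))
    stop("comparison and reference images must share one shape")
  ch <- comp@channels[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  meta <- comp@meta
  meta$cropBox <- box
  .comparisonImage(ch, comp@method, comp@channelNames,
                   pitchMm = comp@pitchMm, meta = meta)
}

#' Pooled per-channel dataset statistics
#'
#' Mean and standard deviation pooled over all pixels of all supplied
#' (training-split) images, per channel, with clip bounds at
#' mean \eqn{\pm} 2 standard deviations. Images may differ in shape (crop
#' boxes vary between plans); every pixel contributes equally.
#'
#' @param images list of [ComparisonImage-class] with a common channel count.
#' @return a [DatasetStats-class].
#' @export
computeDatasetStats <- function(images) {
  stopifnot(length(images) >= 2)
  nch <- dim(images[[1]]@channels)[3]
  n <- 0
  s1 <- numeric(nch)
  s2 <- numeric(nch)
  for (img in images) {
    ch <- img@channels
    stopifnot(dim(ch)[3] == nch)
    npx <- prod(dim(ch)[1:2])
    for (c in seq_len(nch)) {
      v <- ch[, , c]
      s1[c] <- s1[c] + sum(v)
      s2[c] <- s2[c] + sum(v * v)
    }
    n <- n + npx
  }
  mu <- s1 / n
  va <- pmax(s2 / n - mu^2, 0)
  if (any(va <= 0))
    stop("zero variance in at least one channel: statistics are degenerate")
  sd <- sqrt(va)
  new("DatasetStats", mean = mu, sd = sd,
      clipMin = mu - 2 * sd, clipMax = mu + 2 * sd)
}

#' Normalize a comparison image with dataset statistics
#'
#' \code{minmax}: clip each channel to (mean \eqn{\mp} 2 sd) and rescale to
#' \code{[0, 1]}. \code{meanstd}: subtract the dataset mean and divide by
#' the dataset standard deviation (unbounded). Statistics must come from the
#' training split only and are reused unchanged for validation and test
#' images.
#'
#' @param img a [ComparisonImage-class].
#' @param stats a [DatasetStats-class] computed with [computeDatasetStats()].
#' @param mode "minmax" or "meanstd".
#' @return the normalized [ComparisonImage-class].
#' @export
normalizeImage <- function(img, stats, mode = c("minmax", "meanstd")) {
  mode <- match.arg(mode)
  validObject(stats)
  ch <- img@channels
  for (c in seq_len(dim(ch)[3])) {
    v <- ch[, , c]
    if (mode == "minmax") {
      lo <- stats@clipMin[c]
      hi <- stats@clipMax[c]
      v <- (pmin(pmax(v, lo), hi) - lo) / (hi - lo)
    } else {
      v <- (v - stats@mean[c]) / stats@sd[c]
    }
    ch[, , c] <- v
  }
  .comparisonImage(ch, img@method, img@channelNames, pitchMm = img@pitchMm,
                   meta = img@meta)
}

#' Resize a comparison image to a square side
#'
#' Each channel is resampled independently to side x side by bilinear
#' interpolation. The aspect ratio is not preserved — a rectangular crop is
#' mapped directly onto the square, so the resulting pixel pitch is
#' anisotropic and is recorded in the returned image.
#'
#' @param img a [ComparisonImage-class].
#' @param side target side in pixels: 32, 64 or 128.
#' @return the resized [ComparisonImage-class]; \code{meta$pitchAfterMm}
#'   holds the anisotropic (y, x) pitch of the square image.
#' @export
resizeSquare <- function(img, side) {
  side <- as.integer(side)
  stopifnot(side %in% c(32L, 64L, 128L))
  ch <- img@channels
  d <- dim(ch)
  out <- array(0, c(side, side, d[3]))
  for (c in seq_len(d[3]))
    out[, , c] <- resizeBilinear(ch[, , c], side, side)
  meta <- img@meta
  meta$pitchAfterMm <- c(d[1] * img@pitchMm[1], d[2] * img@pitchMm[2]) / side
  .comparisonImage(out, img@method, img@channelNames, pitchMm = img@pitchMm,
                   meta = meta)
}

#' Reported pixel size after square resizing
#'
#' The physical pixel size of a cropped image resized to a square:
#' cropped pixels times original pitch divided by the target side, reported
#' truncated toward zero at one decimal — the convention consistent with
#' every tabulated cell (e.g. 118 px at 0.8 mm resized to 32 gives
#' 2.95 -> 2.9 mm).
#'
#' @param croppedPx cropped image size in pixels along one axis.
#' @param originalPitchMm original pixel pitch in mm.
#' @param side square target side in pixels.
#' @return pixel size in mm, truncated at one decimal.
#' @export
reportPixelPitch <- function(croppedPx, originalPitchMm, side) {
  stopifnot(croppedPx > 0, originalPitchMm > 0, side > 0)
  trunc(croppedPx * originalPitchMm / side * 10 + 1e-9) / 10
}

#' Preprocessing configuration
#'
#' @param cropThreshold low-dose crop threshold (fraction of max ref dose).
#' @param normalization "minmax" or "meanstd".
#' @param side square side: 32, 64 or 128.
#' @return a plain list with class "preprocessConfig".
#' @export
preprocessConfig <- function(cropThreshold = 0.1,
                             normalization = c("meanstd", "minmax"),
                             side = 64L) {
  normalization <- match.arg(normalization)
  side <- as.integer(side)
  stopifnot(cropThreshold > 0, cropThreshold < 1, side %in% c(32L, 64L, 128L))
  structure(list(cropThreshold = cropThreshold, normalization = normalization,
                 side = side), class = "preprocessConfig")
}

#' Crop, normalize and resize a set of comparison images
#'
#' Runs the full preprocessing pipeline: every comparison image is cropped
#' to its reference field, dataset statistics are computed from the cropped
#' images of the \emph{training} indices only, all images are normalized
#' with those statistics and resized to the square side. Deterministic:
#' fixed inputs give byte-identical outputs.
#'
#' @param comps list of [ComparisonImage-class].
#' @param refs list of reference [DoseImage-class], parallel to \code{comps}.
#' @param config a [preprocessConfig()].
#' @param trainIdx integer indices of the training split (statistics source).
#' @return list with \code{x} (array side x side x channels x n),
#'   \code{stats} (the [DatasetStats-class] used), and \code{config}.
#' @export
preprocessDataset <- function(comps, refs, config = preprocessConfig(),
                              trainIdx = seq_along(comps)) {
  stopifnot(length(comps) == length(refs), length(trainIdx) >= 2)
  cropped <- mapply(function(cmp, ref)
    cropToField(cmp, ref, config$cropThreshold), comps, refs,
    SIMPLIFY = FALSE)
  stats <- computeDatasetStats(cropped[trainIdx])
  nch <- dim(cropped[[1]]@channels)[3]
  x <- array(0, c(config$side, config$side, nch, length(cropped)))
  for (i in seq_along(cropped)) {
    img <- normalizeImage(cropped[[i]], stats, config$normalization)
    x[, , , i] <- resizeSquare(img, config$side)@channels
  }
  list(x = x, stats = stats, config = config)
}
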