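#' The twelve dose-comparison image variants
#'
#' Five global gamma criteria, the dose ratio, absolute and relative dose
#' difference, the signed two-channel distance-to-agreement map, the
#' three-channel DD/DTA stack, structural similarity, and the Sobel gradient
#' of the relative DD map.
#'
#' @return character vector of the 12 method identifiers.
#' @export
comparisonMethods <- function() {
  c("gamma11", "gamma22", "gamma33", "gamma31", "gamma13",
    "ratio", "absDD", "relDD", "dta", "ddDta", "ssim", "gradient")
}

.methodChannelCount <- function(method) {
  if (!length(method) || !method %in% comparisonMethods()) return(NA_integer_)
  switch(method, dta = 2L, gradient = 2L, ddDta = 3L, 1L)
}

.checkPair <- function(ref, eval) {
  stopifnot(is(ref, "DoseImage"), is(eval, "DoseImage"))
  if (!identical(dim(ref@pixels), dim(eval@pixels)))
    stop("reference and evaluated images must share one shape")
  if (max(abs(ref@pitchMm - eval@pitchMm)) > 1e-9)
    stop("reference and evaluated images must share one pixel pitch")
  invisible(TRUE)
}

#' Signed global gamma map
#'
#' For each reference pixel r, the gamma index is the minimum over candidate
#' positions e within the search radius of
#' \deqn{\sqrt{\frac{\|e-r\|^2}{\Delta d^2} +
#'       \frac{(D_e(e)-D_r(r))^2}{(\Delta D)^2}},}
#' where \eqn{\Delta d} is the DTA criterion and \eqn{\Delta D} the
#' dose-difference criterion as a percentage of the maximum reference dose
#' (global normalization). Candidate positions lie on a grid with spacing
#' pitch/\code{subsample}; the evaluated dose is interpolated bilinearly.
#' The magnitude is signed by the local dose difference
#' \eqn{D_e(r)-D_r(r)}, so overdosed regions are positive.
#'
#' @param ref,eval reference (error-free) and evaluated [DoseImage-class].
#' @param criteria a [GammaCriteria-class].
#' @return single-channel [ComparisonImage-class].
#' @export
gammaMap <- function(ref, eval, criteria) {
  .checkPair(ref, eval)
  validObject(criteria)
  R <- ref@pixels
  E <- eval@pixels
  maxref <- max(R)
  if (maxref <= 0) stop("maximum reference dose must be positive")
  ddAbs <- criteria@ddPercent / 100 * maxref
  py <- ref@pitchMm[1]; px <- ref@pitchMm[2]
  rad <- criteria@searchRadiusMm
  sub <- criteria@subsample
  # candidate displacements as exact pixel fractions k/subsample, so that
  # integer-pixel candidates shift without any interpolation residue
  kys <- 0:floor(rad * sub / py); kys <- c(-rev(kys[-1]), kys)
  kxs <- 0:floor(rad * sub / px); kxs <- c(-rev(kxs[-1]), kxs)
  g2 <- ((E - R) / ddAbs)^2 # zero-displacement candidate
  dta2 <- criteria@dtaMm^2
  for (ky in kys) {
    dy <- ky / sub * py
    for (kx in kxs) {
      if (ky == 0L && kx == 0L) next
      dx <- kx / sub * px
      d2 <- dy^2 + dx^2
      if (d2 > rad^2 + 1e-12) next
      S <- .shiftBilinear(E, -ky / sub, -kx / sub) # sample E at r + (dy, dx)
      cost <- d2 / dta2 + ((S - R) / ddAbs)^2
      smaller <- !is.na(cost) & cost < g2
      g2[smaller] <- cost[smaller]
    }
  }
  g <- sqrt(g2) * sign(E - R)
  .comparisonImage(g, .gammaMethodName(criteria), "gamma",
                   pitchMm = ref@pitchMm,
                   meta = list(ddPercent = criteria@ddPercent,
                               dtaMm = criteria@dtaMm))
}

# Canonical method tag for tabulated criteria; non-tabulated criteria fall
# back to the generic gamma33 tag, with the true criteria kept in meta.
.gammaMethodName <- function(criteria) {
  nm <- sprintf("gamma%d%d", round(criteria@ddPercent), round(criteria@dtaMm))
  if (nm %in% comparisonMethods()) nm else "gamma33"
}

.gammaCriteriaFor <- function(method, subsample = 4L) {
  dd <- as.numeric(substr(method, 6, 6))
  dta <- as.numeric(substr(method, 7, 7))
  gammaCriteria(dd, dta, subsample = subsample)
}

#' Dose-ratio map
#'
#' Pixelwise evaluated/reference dose where the reference is at least
#' \code{epsFraction} of its maximum; elsewhere the error-neutral value 1.
#'
#' @inheritParams gammaMap
#' @param epsFraction low-dose fallback threshold (fraction of max ref dose).
#' @return single-channel [ComparisonImage-class].
#' @export
ratioMap <- function(ref, eval, epsFraction = 1e-3) {
  .checkPair(ref, eval)
  R <- ref@pixels
  out <- matrix(1, nrow(R), ncol(R))
  ok <- R >= epsFraction * max(R)
  out[ok] <- eval@pixels[ok] / R[ok]
  .comparisonImage(out, "ratio", "ratio", pitchMm = ref@pitchMm)
}

#' Dose-difference map
#'
#' Absolute: evaluated minus reference dose per pixel. Relative: the same
#' divided by the maximum reference dose (global normalization).
#'
#' @inheritParams gammaMap
#' @param relative divide by max reference dose?
#' @return single-channel [ComparisonImage-class].
#' @export
ddMap <- function(ref, eval, relative = FALSE) {
  .checkPair(ref, eval)
  d <- eval@pixels - ref@pixels
  if (relative) {
    m <- max(ref@pixels)
    if (m <= 0) stop("maximum reference dose must be positive")
    d <- d / m
  }
  .comparisonImage(d, if (relative) "relDD" else "absDD",
                   if (relative) "rel_dd" else "abs_dd", pitchMm = ref@pitchMm)
}

# Signed distances (mm) from each position along a 1D profile to the nearest
# crossing of per-position target doses; saturates at +/-W when no crossing
# lies within the window.
.dta1d <- function(evalProf, targets, pitch, W) {
  m <- length(evalProf)
  pos <- seq_len(m)
  D <- outer(evalProf, targets, "-") # D[i, j] = e_i - t_j
  nseg <- m - 1L
  A <- D[seq_len(nseg), , drop = FALSE]
  B <- D[seq_len(nseg) + 1L, , drop = FALSE]
  crossing <- A * B <= 0
  den <- B - A
  frac <- ifelse(abs(den) > 0, -A / den, ifelse(abs(A) == 0, 0, NA_real_))
  crossPos <- (seq_len(nseg) + frac) # fractional pixel position of crossing
  dist <- (crossPos - rep(pos, each = nseg)) * pitch
  dim(dist) <- dim(frac)
  bad <- !crossing | is.na(frac) | abs(dist) > W
  dist[bad] <- NA_real_
  out <- numeric(m)
  absd <- abs(dist)
  for (j in seq_len(m)) {
    col <- absd[, j]
    if (all(is.na(col))) {
      # no crossing: saturate towards the side of closest dose approach
      i <- which.min(abs(D[, j]))
      s <- sign(i - j)
      out[j] <- if (s == 0) W else s * W
    } else {
      out[j] <- dist[which.min(col), j]
    }
  }
  out
}

#' Signed distance-to-agreement map
#'
#' For each pixel, channel \code{dta_x} holds the signed distance in mm from
#' the pixel to the nearest location along its row (x = column direction)
#' where the linearly interpolated evaluated profile crosses the local
#' reference dose; \code{dta_y} is the analogue along the column. When no
#' crossing exists within the half-extent window W, the channel saturates at
#' \eqn{\pm W} with the sign of the side of closest dose approach.
#'
#' @inheritParams gammaMap
#' @return two-channel [ComparisonImage-class] (dta_x, dta_y).
#' @export
dtaMap <- function(ref, eval) {
  .checkPair(ref, eval)
  R <- ref@pixels
  E <- eval@pixels
  ny <- nrow(R); nx <- ncol(R)
  py <- ref@pitchMm[1]; px <- ref@pitchMm[2]
  Wx <- nx * px / 2
  Wy <- ny * py / 2
  dtaX <- matrix(0, ny, nx)
  dtaY <- matrix(0, ny, nx)
  for (i in seq_len(ny))
    dtaX[i, ] <- .dta1d(E[i, ], R[i, ], px, Wx)
  for (j in seq_len(nx))
    dtaY[, j] <- .dta1d(E[, j], R[, j], py, Wy)
  .comparisonImage(array(c(dtaX, dtaY), c(ny, nx, 2L)), "dta",
                   c("dta_x", "dta_y"), pitchMm = ref@pitchMm)
}

#' Structural-similarity map
#'
#' Local SSIM per sliding uniform window:
#' \deqn{\mathrm{SSIM} = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)},}
#' with \eqn{C_1 = (k_1 L)^2}, \eqn{C_2 = (k_2 L)^2} and L the dynamic
#' range (max reference dose unless set in \code{params}). The luminance
#' factor compares window intensities, the contrast/structure factor their
#' variation and correlation. One value per pixel via symmetric padding.
#'
#' @inheritParams gammaMap
#' @param params an [SsimParams-class].
#' @return single-channel [ComparisonImage-class].
#' @export
ssimMap <- function(ref, eval, params = ssimParams()) {
  .checkPair(ref, eval)
  validObject(params)
  w <- params@windowSidePx
  R <- ref@pixels
  E <- eval@pixels
  if (w > min(dim(R))) stop("SSIM window larger than the image")
  L <- if (is.na(params@dynamicRange)) max(R) else params@dynamicRange
  C1 <- (params@k1 * L)^2
  C2 <- (params@k2 * L)^2
  mx <- .boxFilter(R, w)
  my <- .boxFilter(E, w)
  sxx <- .boxFilter(R * R, w) - mx^2
  syy <- .boxFilter(E * E, w) - my^2
  sxy <- .boxFilter(R * E, w) - mx * my
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
       ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  .comparisonImage(s, "ssim", "ssim", pitchMm = ref@pitchMm)
}

#' Sobel gradient map of the relative dose difference
#'
#' The relative DD map is convolved with the two 3x3 Sobel kernels
#' (replicated edges); channel 1 is the gradient magnitude
#' \eqn{\sqrt{G_x^2+G_y^2}}, channel 2 the direction atan2(Gy, Gx) in
#' radians (0 where both components vanish).
#'
#' @inheritParams gammaMap
#' @return two-channel [ComparisonImage-class] (magnitude, direction).
#' @export
gradientMap <- function(ref, eval) {
  .checkPair(ref, eval)
  dd <- ddMap(ref, eval, relative = TRUE)@channels[, , 1]
  ny <- nrow(dd); nx <- ncol(dd)
  pad <- dd[c(1, seq_len(ny), ny), c(1, seq_len(nx), nx)] # replicate edges
  shift <- function(a, b) pad[a + seq_len(ny), b + seq_len(nx)]
  # correlation with sobel kernels; x = column direction
  gx <- (shift(0, 2) - shift(0, 0)) + 2 * (shift(1, 2) - shift(1, 0)) +
        (shift(2, 2) - shift(2, 0))
  gy <- (shift(2, 0) - shift(0, 0)) + 2 * (shift(2, 1) - shift(0, 1)) +
        (shift(2, 2) - shift(0, 2))
  mag <- sqrt(gx^2 + gy^2)
  dir <- atan2(gy, gx)
  .comparisonImage(array(c(mag, dir), c(ny, nx, 2L)), "gradient",
                   c("magnitude", "direction"), pitchMm = ref@pitchMm)
}

#' Compute any of the twelve comparison variants
#'
#' Dispatches to the individual operators; \code{ddDta} stacks the relative
#' DD map with the two signed DTA channels (all components of the gamma
#' index, kept separate).
#'
#' @inheritParams gammaMap
#' @param method one of [comparisonMethods()].
#' @param gammaSubsample candidate-grid refinement for the gamma variants.
#' @param ssimPar an [SsimParams-class] for the SSIM variant.
#' @return a [ComparisonImage-class].
#' @export
compareDose <- function(ref, eval, method, gammaSubsample = 4L,
                        ssimPar = NULL) {
  method <- match.arg(method, comparisonMethods())
  if (is.null(ssimPar)) ssimPar <- ssimParams()
  if (startsWith(method, "gamma"))
    return(gammaMap(ref, eval, .gammaCriteriaFor(method, gammaSubsample)))
  switch(method,
    ratio = ratioMap(ref, eval),
    absDD = ddMap(ref, eval, relative = FALSE),
    relDD = ddMap(ref, eval, relative = TRUE),
    dta = dtaMap(ref, eval),
    ssim = ssimMap(ref, eval, ssimPar),
    gradient = gradientMap(ref, eval),
    ddDta = {
      dd <- ddMap(ref, eval, relative = TRUE)@channels[, , 1]
      dta <- dtaMap(ref, eval)@channels
      .comparisonImage(array(c(dd, dta), c(dim(dd), 3L)), "ddDta",
                       c("rel_dd", "dta_x", "dta_y"), pitchMm = ref@pitchMm)
    }
  )
}
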