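# Internal numerical helpers: seeded evaluation, bilinear resampling
# (rotation, constant shifts, square resize), separable convolution.

# Evaluate expr under a temporary RNG state; restores the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Bilinear sample of matrix img at fractional (row, col) positions.
# Positions outside the grid return `fill`.
.bilinearSample <- function(img, ri, ci, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  i0 <- floor(ri); j0 <- floor(ci)
  fy <- ri - i0; fx <- ci - j0
  out <- numeric(length(ri))
  val <- function(ii, jj) {
    ok <- ii >= 1 & ii <= ny & jj >= 1 & jj <= nx
    v <- numeric(length(ii))
    v[ok] <- img[cbind(ii[ok], jj[ok])]
    v[!ok] <- fill
    v
  }
  out <- (1 - fy) * (1 - fx) * val(i0, j0) +
         (1 - fy) * fx       * val(i0, j0 + 1) +
         fy       * (1 - fx) * val(i0 + 1, j0) +
         fy       * fx       * val(i0 + 1, j0 + 1)
  out
}

# Rotate a matrix by `deg` degrees (counter-clockwise in the x-right /
# y-up physical frame) about the grid centre, bilinear, same output size.
rotateBilinear <- function(img, deg, fill = 0) {
  if (abs(deg) < 1e-12) return(img)
  ny <- nrow(img); nx <- ncol(img)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  th <- deg * pi / 180
  co <- cos(th); si <- sin(th)
  gi <- rep(seq_len(ny), times = nx) - cy
  gj <- rep(seq_len(nx), each = ny) - cx
  # inverse map: source = R(-theta) . target (row axis points down, so the
  # sign of the rotation flips relative to the physical frame)
  sr <- co * gi - si * gj + cy
  sc <- si * gi + co * gj + cx
  matrix(.bilinearSample(img, sr, sc, fill = fill), ny, nx)
}

# Shift a matrix by a constant fractional offset (rows down, cols right),
# bilinear; output pixels whose interpolation stencil (with non-zero weight)
# falls outside the grid become NA.
.shiftBilinear <- function(img, di, dj) {
  ny <- nrow(img); nx <- ncol(img)
  ri <- seq_len(ny) - di
  ci <- seq_len(nx) - dj
  i0 <- floor(ri); fy <- ri - i0
  j0 <- floor(ci); fx <- ci - j0
  corner <- function(ii, jj) {
    iok <- ii >= 1 & ii <= ny
    jok <- jj >= 1 & jj <= nx
    v <- img[pmin(pmax(ii, 1L), ny), pmin(pmax(jj, 1L), nx), drop = FALSE]
    v[!iok, ] <- 0
    v[, !jok] <- 0
    list(v = v, ok = outer(iok, jok))
  }
  w00 <- outer(1 - fy, 1 - fx); w01 <- outer(1 - fy, fx)
  w10 <- outer(fy, 1 - fx);     w11 <- outer(fy, fx)
  a <- corner(i0, j0);      b <- corner(i0, j0 + 1L)
  d <- corner(i0 + 1L, j0); e <- corner(i0 + 1L, j0 + 1L)
  out <- w00 * a$v + w01 * b$v + w10 * d$v + w11 * e$v
  bad <- (w00 > 0 & !a$ok) | (w01 > 0 & !b$ok) |
         (w10 > 0 & !d$ok) | (w11 > 0 & !e$ok)
  out[bad] <- NA_real_
  out
}

# Bilinear resize of a matrix to ny2 x nx2. Output pixel centres are mapped
# into input pixel-centre coordinates with the half-pixel convention, which
# makes a same-size resize the exact identity.
resizeBilinear <- function(img, ny2, nx2) {
  ny <- nrow(img); nx <- ncol(img)
  sy <- ny / ny2; sx <- nx / nx2
  ri <- (seq_len(ny2) - 0.5) * sy + 0.5
  ci <- (seq_len(nx2) - 0.5) * sx + 0.5
  ri <- pmin(pmax(ri, 1), ny)
  ci <- pmin(pmax(ci, 1), nx)
  i0 <- floor(ri); fy <- ri - i0
  j0 <- floor(ci); fx <- ci - j0
  i1 <- pmin(i0 + 1, ny); j1 <- pmin(j0 + 1, nx)
  img[i0, j0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    img[i0, j1, drop = FALSE] * outer(1 - fy, fx) +
    img[i1, j0, drop = FALSE] * outer(fy, 1 - fx) +
    img[i1, j1, drop = FALSE] * outer(fy, fx)
}

# Separable 1D convolution along rows and columns with zero padding.
.convSeparable <- function(img, ky, kx) {
  ry <- (length(ky) - 1L) / 2L
  rx <- (length(kx) - 1L) / 2L
  ny <- nrow(img); nx <- ncol(img)
  pad <- matrix(0, ny + 2 * ry, nx + 2 * rx)
  pad[ry + seq_len(ny), rx + seq_len(nx)] <- img
  tmp <- matrix(0, ny, nx + 2 * rx)
  for (t in seq_along(ky))
    tmp <- tmp + ky[t] * pad[(t - 1) + seq_len(ny), , drop = FALSE]
  out <- matrix(0, ny, nx)
  for (t in seq_along(kx))
    out <- out + kx[t] * tmp[, (t - 1) + seq_len(nx), drop = FALSE]
  out
}

# Bin-integrated Gaussian kernel: weight of tap k is the Gaussian mass in
# [(k-1/2)h, (k+1/2)h]. The discrete step response then equals the analytic
# error-function profile at pixel centres up to the truncation tail.
.gaussKernel <- function(sigmaMm, pitchMm) {
  r <- max(1L, ceiling(6 * sigmaMm / pitchMm))
  k <- (-r):r
  w <- pnorm((k + 0.5) * pitchMm, sd = sigmaMm) -
       pnorm((k - 0.5) * pitchMm, sd = sigmaMm)
  w / sum(w)
}

# Uniform box filter with reflective padding, odd window side.
.boxFilter <- function(img, side) {
  r <- (side - 1L) / 2L
  ny <- nrow(img); nx <- ncol(img)
  idx <- function(n) {
    # mirror about the edge samples (requires r < n, enforced by callers)
    i <- seq.int(1L - r, n + r)
    i[i < 1L] <- 2L - i[i < 1L]
    i[i > n] <- 2L * n - i[i > n]
    pmin(pmax(i, 1L), n)
  }
  pad <- img[idx(ny), idx(nx), drop = FALSE]
  cs <- apply(pad, 2, cumsum)
  rowsum <- cs[(2 * r + 1):(ny + 2 * r), , drop = FALSE] -
    rbind(0, cs[seq_len(ny - 1) + 0L, , drop = FALSE])
  cs2 <- t(apply(rowsum, 1, cumsum))
  out <- cs2[, (2 * r + 1):(nx + 2 * r), drop = FALSE] -
    cbind(0, cs2[, seq_len(nx - 1), drop = FALSE])
  out / side^2
}
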