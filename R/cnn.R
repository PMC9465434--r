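# Internal convolutional-network engine.
#
# Activations for a batch of N images of spatial size H x W with C channels
# are stored as a (N*H*W) x C matrix whose row index runs fastest over the
# image index n, then row i (y), then column j (x). 3x3 convolutions are
# computed as nine gemms against row-shifted views of the activation matrix
# (one per kernel tap), with a shared zero row standing in for out-of-image
# samples. All randomness is drawn from the caller's seeded RNG stream.

.idxCache <- new.env(parent = emptyenv())

.convIdx <- function(H, W, N, dy, dx) {
  key <- paste("c", H, W, N, dy, dx)
  v <- .idxCache[[key]]
  if (!is.null(v)) return(v)
  ii <- rep(seq_len(H), times = W)
  jj <- rep(seq_len(W), each = H)
  si <- ii + dy
  sj <- jj + dx
  pos <- (sj - 1L) * H + si
  pos[si < 1L | si > H | sj < 1L | sj > W] <- NA_integer_
  idx <- rep((pos - 1L) * N, each = N) + seq_len(N)
  idx[is.na(idx)] <- N * H * W + 1L # the shared zero row
  .idxCache[[key]] <- idx
  idx
}

.poolIdx <- function(H, W, N, a, b) {
  key <- paste("p", H, W, N, a, b)
  v <- .idxCache[[key]]
  if (!is.null(v)) return(v)
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  i <- rep(2L * seq_len(H2) - 1L + a, times = W2)
  j <- rep(2L * seq_len(W2) - 1L + b, each = H2)
  pos <- (j - 1L) * H + i
  idx <- rep((pos - 1L) * N, each = N) + seq_len(N)
  .idxCache[[key]] <- idx
  idx
}

.convForward <- function(X, layer, H, W, N, keep = FALSE) {
  Xa <- rbind(X, 0)
  Y <- matrix(layer$b, nrow(X), length(layer$b), byrow = TRUE)
  Xs <- if (keep) vector("list", 9L) else NULL
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    S <- Xa[.convIdx(H, W, N, dy, dx), , drop = FALSE]
    Y <- Y + S %*% layer$W[[k]]
    if (keep) Xs[[k]] <- S
  }
  list(Y = Y, Xs = Xs)
}

.convBackward <- function(dY, fwd, layer, H, W, N) {
  nr <- N * H * W
  dX <- matrix(0, nr, ncol(fwd$Xs[[1]]))
  dW <- vector("list", 9L)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    dW[[k]] <- crossprod(fwd$Xs[[k]], dY)
    idx <- .convIdx(H, W, N, dy, dx)
    ok <- idx <= nr
    tmp <- tcrossprod(dY, layer$W[[k]])
    dX[idx[ok], ] <- dX[idx[ok], , drop = FALSE] + tmp[ok, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

.poolForward <- function(X, H, W, N) {
  corners <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  Y <- NULL
  arg <- NULL
  for (t in 1:4) {
    S <- X[.poolIdx(H, W, N, corners[[t]][1], corners[[t]][2]), , drop = FALSE]
    if (t == 1L) {
      Y <- S
      arg <- matrix(1L, nrow(S), ncol(S))
    } else {
      m <- S > Y
      Y[m] <- S[m]
      arg[m] <- t
    }
  }
  list(Y = Y, arg = arg)
}

.poolBackward <- function(dY, fwd, H, W, N, Cin) {
  corners <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  dX <- matrix(0, N * H * W, Cin)
  for (t in 1:4) {
    idx <- .poolIdx(H, W, N, corners[[t]][1], corners[[t]][2])
    tmp <- dY * (fwd$arg == t)
    dX[idx, ] <- dX[idx, , drop = FALSE] + tmp
  }
  dX
}

# He-normal initialisation of all parameters for an architecture spec.
.cnnInit <- function(arch) {
  layers <- list()
  Cin <- arch$nInputChannels
  H <- arch$inputSide
  for (bl in seq_len(arch$nBlocks)) {
    Cout <- arch$filters[bl]
    for (cl in 1:2) {
      sd <- sqrt(2 / (9 * Cin))
      W <- lapply(1:9, function(k) matrix(rnorm(Cin * Cout, 0, sd), Cin, Cout))
      layers[[length(layers) + 1L]] <-
        list(type = "conv", W = W, b = numeric(Cout))
      Cin <- Cout
    }
    layers[[length(layers) + 1L]] <- list(type = "pool")
    H <- H %/% 2L
  }
  nFlat <- H * H * Cin
  for (du in arch$denseUnits) {
    sd <- sqrt(2 / nFlat)
    layers[[length(layers) + 1L]] <- list(
      type = "dense", W = matrix(rnorm(nFlat * du, 0, sd), nFlat, du),
      b = numeric(du), act = "relu")
    nFlat <- du
  }
  sd <- sqrt(2 / nFlat)
  layers[[length(layers) + 1L]] <- list(
    type = "dense", W = matrix(rnorm(nFlat * arch$nClasses, 0, sd),
                               nFlat, arch$nClasses),
    b = numeric(arch$nClasses), act = "linear")
  layers
}

# Forward pass; x is an (H, W, C, N) array slice already as matrix form.
.cnnForward <- function(layers, X, H, W, N, keep = FALSE) {
  caches <- if (keep) vector("list", length(layers)) else NULL
  h <- H
  dense <- FALSE
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (ly$type == "conv") {
      fw <- .convForward(X, ly, h, h, N, keep = keep)
      A <- fw$Y
      A[A < 0] <- 0
      if (keep) caches[[li]] <- list(fwd = fw, act = A, H = h)
      X <- A
    } else if (ly$type == "pool") {
      fw <- .poolForward(X, h, h, N)
      if (keep) caches[[li]] <- list(fwd = fw, H = h, Cin = ncol(X))
      h <- h %/% 2L
      X <- fw$Y
    } else {
      if (!dense) {
        X <- matrix(as.vector(X), nrow = N) # (N*h*h) x C -> N x (h*h*C)
        dense <- TRUE
      }
      Z <- X %*% ly$W + matrix(ly$b, N, length(ly$b), byrow = TRUE)
      if (ly$act == "relu") {
        A <- Z
        A[A < 0] <- 0
      } else A <- Z
      if (keep) caches[[li]] <- list(input = X, act = A)
      X <- A
    }
  }
  list(out = X, caches = caches, hFinal = h)
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# One forward+backward pass; returns loss and gradients parallel to layers.
.cnnGrad <- function(layers, X, yIdx, H, N) {
  fw <- .cnnForward(layers, X, H, H, N, keep = TRUE)
  P <- .softmax(fw$out)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(N), yIdx)] + eps))
  dZ <- P
  dZ[cbind(seq_len(N), yIdx)] <- dZ[cbind(seq_len(N), yIdx)] - 1
  dZ <- dZ / N
  grads <- vector("list", length(layers))
  dX <- dZ
  firstDense <- min(which(vapply(layers, function(l) l$type == "dense",
                                 logical(1))))
  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]
    cc <- fw$caches[[li]]
    if (ly$type == "dense") {
      if (ly$act == "relu") dX <- dX * (cc$act > 0)
      grads[[li]] <- list(dW = crossprod(cc$input, dX), db = colSums(dX))
      dX <- tcrossprod(dX, ly$W)
      if (li == firstDense) {
        # back to spatial layout (N*h*h) x C
        hh <- fw$hFinal
        Cl <- ncol(dX) / (hh * hh)
        dX <- matrix(as.vector(dX), ncol = Cl)
      }
    } else if (ly$type == "pool") {
      dX <- .poolBackward(dX, cc$fwd, cc$H, cc$H, N, cc$Cin)
    } else {
      dX <- dX * (cc$act > 0)
      bw <- .convBackward(dX, cc$fwd, ly, cc$H, cc$H, N)
      grads[[li]] <- list(dW = bw$dW, db = bw$db)
      dX <- bw$dX
    }
  }
  list(loss = loss, grads = grads)
}

# Adam update in place over the nested parameter lists.
.adamStep <- function(layers, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  upd <- function(p, g, key) {
    m <- state$m[[key]]
    v <- state$v[[key]]
    if (is.null(m)) {
      m <- p * 0
      v <- p * 0
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    state$m[[key]] <- m
    state$v[[key]] <- v
    p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
  }
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    ly <- layers[[li]]
    if (ly$type == "conv") {
      for (k in 1:9)
        ly$W[[k]] <- upd(ly$W[[k]], g$dW[[k]], sprintf("%d.W%d", li, k))
      ly$b <- upd(ly$b, g$db, sprintf("%d.b", li))
    } else {
      ly$W <- upd(ly$W, g$dW, sprintf("%d.W", li))
      ly$b <- upd(ly$b, g$db, sprintf("%d.b", li))
    }
    layers[[li]] <- ly
  }
  layers
}

# Array (H, W, C, n) subset -> activation matrix layout.
.toMatrix <- function(x, idx) {
  xs <- x[, , , idx, drop = FALSE]
  d <- dim(xs)
  m <- aperm(xs, c(4, 1, 2, 3))
  dim(m) <- c(d[4] * d[1] * d[2], d[3])
  m
}

.cnnLoss <- function(layers, x, yIdx, idx, side, chunk = 128L) {
  tot <- 0
  n <- length(idx)
  for (s in seq(1, n, by = chunk)) {
    sub <- idx[s:min(n, s + chunk - 1L)]
    X <- .toMatrix(x, sub)
    out <- .cnnForward(layers, X, side, side, length(sub))$out
    P <- .softmax(out)
    tot <- tot - sum(log(P[cbind(seq_along(sub), yIdx[sub])] + 1e-12))
  }
  tot / n
}
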