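#' Convolutional classifier architecture
#'
#' The network is built from \code{nBlocks} blocks of two 3x3 convolution
#' layers (ReLU) followed by one 2x2 max-pool, then dense layers and a
#' softmax output — the standard small-image classification stack. Exact
#' widths are tunable; the desk-scale defaults are two blocks of 8 and 16
#' filters and one dense layer of 32 units.
#'
#' @param inputSide square input side in pixels.
#' @param nInputChannels 1-3 input channels.
#' @param nClasses number of output classes.
#' @param nBlocks number of conv-conv-pool blocks.
#' @param filters filter count per block (length \code{nBlocks}).
#' @param denseUnits hidden dense layer widths (may be empty).
#' @return a list with class "architectureSpec".
#' @export
architectureSpec <- function(inputSide, nInputChannels, nClasses,
                             nBlocks = 2L, filters = c(8L, 16L),
                             denseUnits = 32L) {
  nBlocks <- as.integer(nBlocks)
  stopifnot(nBlocks >= 1L, length(filters) == nBlocks,
            nInputChannels %in% 1:3, nClasses >= 2L)
  if (inputSide %/% 2^nBlocks < 1L)
    stop("too many pooling blocks for this input size")
  structure(list(inputSide = as.integer(inputSide),
                 nInputChannels = as.integer(nInputChannels),
                 nClasses = as.integer(nClasses), nBlocks = nBlocks,
                 filters = as.integer(filters),
                 denseUnits = as.integer(denseUnits)),
            class = "architectureSpec")
}

#' Training configuration
#'
#' @param maxEpochs maximum number of epochs.
#' @param batchSize minibatch size.
#' @param learningRate Adam learning rate.
#' @param patience early-stopping patience: training stops once the
#'   validation loss has failed to improve for more than \code{patience}
#'   consecutive epochs (0 stops at the first non-improvement).
#' @param seed RNG seed for initialisation and batch shuffling.
#' @return a list with class "trainConfig".
#' @export
trainConfig <- function(maxEpochs = 12L, batchSize = 32L,
                        learningRate = 1e-3, patience = 3L, seed = 1L) {
  structure(list(maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, patience = as.integer(patience),
                 seed = as.integer(seed)), class = "trainConfig")
}

#' A trained convolutional classifier
#'
#' @slot layers fitted layer parameters.
#' @slot arch the [architectureSpec()] used.
#' @slot classes class labels in output order.
#' @slot history per-epoch training and validation loss.
#' @slot pruned whether training was stopped by a pruning hook.
#' @exportClass CnnClassifier
setClass("CnnClassifier",
  representation(layers = "list", arch = "list", classes = "character",
                 history = "data.frame", pruned = "logical"))

setMethod("show", "CnnClassifier", function(object) {
  cat(sprintf(
    "CnnClassifier: %d blocks (%s filters), %d classes, %d epochs%s\n",
    object@arch$nBlocks, paste(object@arch$filters, collapse = "/"),
    object@arch$nClasses, nrow(object@history),
    if (object@pruned) " (pruned)" else ""))
})

#' Stratified train/validation/test split
#'
#' Assigns every item to train, validation or test, stratified by class:
#' within each class the items are shuffled (deterministically per seed) and
#' allocated by largest-remainder rounding of the class quota, so per-class
#' proportions match the global fractions to within one item and the
#' partition is exhaustive and disjoint.
#'
#' @param labels class label per item.
#' @param fractions train/validation/test fractions, summing to 1
#'   (default 0.70/0.10/0.20).
#' @param seed RNG seed.
#' @return character vector ("train", "val", "test") parallel to labels.
#' @export
splitDataset <- function(labels, fractions = c(0.70, 0.10, 0.20), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 3L))
    stop("every class needs at least 3 items to be split three ways")
  out <- character(length(labels))
  withSeed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      quota <- fractions * n
      base <- floor(quota)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      grp <- rep(c("train", "val", "test"), times = base)
      out[idx] <- grp
    }
  })
  out
}

#' Train the convolutional classifier
#'
#' Minimises the cross-entropy with Adam on the training split, evaluating
#' the validation loss after every epoch. Early stopping returns the weights
#' of the best validation epoch. Fully deterministic given the seed.
#'
#' @param x input array (side, side, channels, n), preprocessed and finite.
#' @param y class label per image.
#' @param split "train"/"val"/"test" assignment from [splitDataset()].
#' @param arch an [architectureSpec()]; defaults to the desk-scale network
#'   sized from \code{x} and \code{y}.
#' @param cfg a [trainConfig()].
#' @param pruneHook optional \code{function(epoch, valLoss)} returning TRUE
#'   to abandon training (used by the hyperparameter pruner).
#' @return a [CnnClassifier-class].
#' @export
trainModel <- function(x, y, split, arch = NULL, cfg = trainConfig(),
                       pruneHook = NULL) {
  stopifnot(length(dim(x)) == 4L, dim(x)[1] == dim(x)[2])
  if (any(!is.finite(x))) stop("inputs must be finite")
  classes <- sort(unique(as.character(y)))
  yIdx <- match(as.character(y), classes)
  side <- dim(x)[1]
  if (is.null(arch))
    arch <- architectureSpec(side, dim(x)[3], length(classes))
  stopifnot(arch$inputSide == side, arch$nInputChannels == dim(x)[3],
            arch$nClasses == length(classes))
  trainIdx <- which(split == "train")
  valIdx <- which(split == "val")
  stopifnot(length(trainIdx) > 0, length(valIdx) > 0)
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric())
  pruned <- FALSE
  withSeed(cfg$seed, {
    layers <- .cnnInit(arch)
    state <- new.env(parent = emptyenv())
    state$t <- 0L
    state$m <- list()
    state$v <- list()
    bestVal <- Inf
    bestLayers <- layers
    bad <- 0L
    for (epoch in seq_len(cfg$maxEpochs)) {
      ord <- sample(trainIdx)
      losses <- numeric()
      for (s in seq(1, length(ord), by = cfg$batchSize)) {
        bi <- ord[s:min(length(ord), s + cfg$batchSize - 1L)]
        X <- .toMatrix(x, bi)
        g <- .cnnGrad(layers, X, yIdx[bi], side, length(bi))
        if (!is.finite(g$loss))
          stop(sprintf("non-finite training loss at epoch %d; try a lower learning rate", epoch))
        layers <- .adamStep(layers, g$grads, state, cfg$learningRate)
        losses <- c(losses, g$loss)
      }
      valLoss <- .cnnLoss(layers, x, yIdx, valIdx, side)
      hist[nrow(hist) + 1L, ] <- list(epoch, mean(losses), valLoss)
      if (valLoss < bestVal) {
        bestVal <- valLoss
        bestLayers <- layers
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad > cfg$patience) break
      }
      if (!is.null(pruneHook) && isTRUE(pruneHook(epoch, valLoss))) {
        pruned <- TRUE
        break
      }
    }
    new("CnnClassifier", layers = bestLayers, arch = unclass(arch),
        classes = classes, history = hist, pruned = pruned)
  })
}

#' Class-probability predictions
#'
#' @param model a [CnnClassifier-class].
#' @param x input array (side, side, channels, n).
#' @return n x nClasses matrix of softmax probabilities (rows sum to 1),
#'   columns named by class.
#' @export
predictProb <- function(model, x) {
  stopifnot(is(model, "CnnClassifier"), length(dim(x)) == 4L)
  side <- model@arch$inputSide
  n <- dim(x)[4]
  out <- matrix(0, n, length(model@classes),
                dimnames = list(NULL, model@classes))
  for (s in seq(1, n, by = 128L)) {
    sub <- s:min(n, s + 127L)
    X <- .toMatrix(x, sub)
    Z <- .cnnForward(model@layers, X, side, side, length(sub))$out
    out[sub, ] <- .softmax(Z)
  }
  out
}

#' Classification accuracy in percent
#'
#' The percentage of images assigned to their correct class; the test split
#' is the only data this function should ever see during an experiment.
#'
#' @param model a [CnnClassifier-class].
#' @param x input array for the evaluation items.
#' @param y true class label per item.
#' @return accuracy in percent (0-100).
#' @export
evaluateAccuracy <- function(model, x, y) {
  if (length(y) == 0L) stop("empty evaluation set")
  p <- predictProb(model, x)
  pred <- model@classes[max.col(p, ties.method = "first")]
  100 * mean(pred == as.character(y))
}

#' Hyperparameter-search configuration
#'
#' @param nTrials number of trials.
#' @param sampler "random" or "bayesian" (Gaussian-process expected
#'   improvement after three seeding trials).
#' @param pruning abandon trials whose validation loss is above the median
#'   of previous trials at the same epoch (from epoch 2 on)?
#' @param maxEpochs,batchChoices,lrRange,blockChoices,filterChoices,denseChoices
#'   search-space bounds.
#' @param seed base seed; trial t trains with seed \code{seed + t}.
#' @return a list with class "hpoConfig".
#' @export
hpoConfig <- function(nTrials = 5L, sampler = c("random", "bayesian"),
                      pruning = TRUE, maxEpochs = 8L,
                      batchChoices = c(32L, 64L),
                      lrRange = c(3e-4, 1e-2),
                      blockChoices = c(1L, 2L),
                      filterChoices = c(4L, 8L, 16L),
                      denseChoices = c(16L, 32L, 64L),
                      seed = 1L) {
  sampler <- match.arg(sampler)
  stopifnot(nTrials >= 1L)
  structure(list(nTrials = as.integer(nTrials), sampler = sampler,
                 pruning = pruning, maxEpochs = as.integer(maxEpochs),
                 batchChoices = batchChoices, lrRange = lrRange,
                 blockChoices = blockChoices, filterChoices = filterChoices,
                 denseChoices = denseChoices, seed = as.integer(seed)),
            class = "hpoConfig")
}

# Draw one hyperparameter point, as a plain numeric encoding plus the
# decoded pieces. The encoding is used by the GP surrogate.
.hpoSample <- function(hpo) {
  nb <- sample(hpo$blockChoices, 1)
  fb <- sample(hpo$filterChoices, 1)
  du <- sample(hpo$denseChoices, 1)
  lr <- exp(runif(1, log(hpo$lrRange[1]), log(hpo$lrRange[2])))
  bs <- sample(hpo$batchChoices, 1)
  list(nBlocks = nb, filterBase = fb, denseUnits = du, lr = lr, batch = bs,
       enc = c(nb, log2(fb), log2(du), log10(lr), log2(bs)))
}

# Minimal RBF-kernel Gaussian process for expected improvement.
.gpEI <- function(encs, losses, cands) {
  X <- scale(encs)
  ctr <- attr(X, "scaled:center")
  scl <- attr(X, "scaled:scale")
  scl[scl == 0 | is.na(scl)] <- 1
  Xc <- sweep(sweep(cands, 2, ctr), 2, scl, "/")
  X <- sweep(sweep(encs, 2, ctr), 2, scl, "/")
  k <- function(a, b) exp(-0.5 * outer(rowSums(a^2), rowSums(b^2), "+") +
                          tcrossprod(a, b) - 0.5 * 0)
  K <- k(X, X) + diag(1e-6 + 1e-4 * stats::var(losses), nrow(X))
  Ks <- k(Xc, X)
  alpha <- solve(K, losses - mean(losses))
  mu <- mean(losses) + Ks %*% alpha
  v <- pmax(1 - diag(Ks %*% solve(K, t(Ks))), 1e-12)
  s <- sqrt(v) * stats::sd(losses)
  best <- min(losses)
  z <- (best - mu) / s
  ei <- (best - mu) * pnorm(z) + s * dnorm(z)
  which.max(ei)
}

#' Tune architecture and training hyperparameters
#'
#' Runs seeded trials over the search space, each training on the train
#' split and scored by best validation loss; returns the best trial's
#' configuration and model. The random sampler draws points independently;
#' the Bayesian sampler fits a Gaussian-process surrogate to completed
#' trials and picks the candidate with maximal expected improvement.
#' With pruning enabled, a trial is abandoned once its validation loss
#' exceeds the median of previous trials at the same epoch. Trial t always
#' derives its RNG stream from \code{seed + t}, so a longer run extends a
#' shorter one with identical initial trials.
#'
#' @param x,y,split as in [trainModel()].
#' @param hpo an [hpoConfig()].
#' @return list with \code{best} (trial row), \code{model} (best
#'   [CnnClassifier-class]) and \code{trials} (data.frame, one row per
#'   trial with parameters, best validation loss and pruned flag).
#' @export
tuneHyperparameters <- function(x, y, split, hpo = hpoConfig()) {
  side <- dim(x)[1]
  nClasses <- length(unique(as.character(y)))
  trials <- data.frame()
  encs <- NULL
  models <- list()
  epochLosses <- list() # per completed trial: val loss per epoch
  for (t in seq_len(hpo$nTrials)) {
    par <- withSeed(hpo$seed + t, {
      if (hpo$sampler == "bayesian" && nrow(trials) >= 3L) {
        cands <- lapply(1:32, function(i) .hpoSample(hpo))
        ce <- do.call(rbind, lapply(cands, `[[`, "enc"))
        done <- !is.na(trials$valLoss)
        cands[[.gpEI(encs[done, , drop = FALSE], trials$valLoss[done], ce)]]
      } else .hpoSample(hpo)
    })
    maxBlocks <- floor(log2(side))
    nb <- min(par$nBlocks, maxBlocks)
    arch <- architectureSpec(side, dim(x)[3], nClasses, nBlocks = nb,
                             filters = par$filterBase * 2^(seq_len(nb) - 1L),
                             denseUnits = par$denseUnits)
    cfg <- trainConfig(maxEpochs = hpo$maxEpochs, batchSize = par$batch,
                       learningRate = par$lr, seed = hpo$seed + t)
    hook <- NULL
    if (hpo$pruning && length(epochLosses) >= 1L) {
      hook <- function(epoch, valLoss) {
        prev <- vapply(epochLosses, function(v)
          if (length(v) >= epoch) v[epoch] else NA_real_, numeric(1))
        prev <- prev[!is.na(prev)]
        epoch >= 2L && length(prev) >= 1L && valLoss > median(prev)
      }
    }
    model <- trainModel(x, y, split, arch = arch, cfg = cfg,
                        pruneHook = hook)
    vbest <- min(model@history$valLoss)
    trials <- rbind(trials, data.frame(
      trial = t, nBlocks = nb, filterBase = par$filterBase,
      denseUnits = par$denseUnits, lr = par$lr, batch = par$batch,
      valLoss = vbest, pruned = model@pruned, seed = hpo$seed + t))
    encs <- rbind(encs, par$enc)
    models[[t]] <- model
    if (!model@pruned)
      epochLosses[[length(epochLosses) + 1L]] <- model@history$valLoss
  }
  completed <- which(!trials$pruned)
  bestPool <- if (length(completed)) completed else seq_len(nrow(trials))
  bi <- bestPool[which.min(trials$valLoss[bestPool])]
  list(best = trials[bi, ], model = models[[bi]], trials = trials)
}
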