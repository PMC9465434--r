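#' Enumerate the factorial design cells
#'
#' The full cross-product of classification level, dose-comparison method,
#' normalization method and image resolution, in stable order (resolution
#' varies fastest, then normalization, then method, then level). The full
#' default factor sets give 2 x 12 x 2 x 3 = 144 cells.
#'
#' @param levels classification levels (1 = error type, 2 = relevance).
#' @param methods comparison methods (subset of [comparisonMethods()]).
#' @param normalizations "minmax" and/or "meanstd".
#' @param resolutions square sides, subset of 32/64/128.
#' @return data.frame with one row per cell.
#' @export
enumerateCells <- function(levels = 1:2, methods = comparisonMethods(),
                           normalizations = c("minmax", "meanstd"),
                           resolutions = c(32L, 64L, 128L)) {
  stopifnot(length(levels) > 0, length(methods) > 0,
            length(normalizations) > 0, length(resolutions) > 0)
  stopifnot(all(methods %in% comparisonMethods()))
  cells <- expand.grid(resolution = as.integer(resolutions),
                       normalization = normalizations, method = methods,
                       level = as.integer(levels),
                       stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  cells[, c("level", "method", "normalization", "resolution")]
}

#' Desk-scale study configuration
#'
#' Defaults define the reduced synthetic study: one modality, a small plan
#' cohort, all five error types on the step-doubled magnitude grids, no
#' hyperparameter search (the desk-scale default architecture), and a short
#' training budget. Scale up any of these for larger runs.
#'
#' @param modality cohort modality; "SBRT" keeps the dose grids small.
#' @param nPlans plans in the cohort (2 arcs each by default).
#' @param samplesPerType error simulations per arc and type.
#' @param stepFactor magnitude-grid reduction factor.
#' @param cropThreshold low-dose crop threshold.
#' @param hpoTrials hyperparameter trials per cell (0 = defaults, no search).
#' @param maxEpochs,batchSize,learningRate,patience training budget.
#' @param gammaSubsample candidate grid refinement for gamma methods.
#' @param seed master seed; all stage seeds derive from it.
#' @return a list with class "studyConfig".
#' @export
studyConfig <- function(modality = "SBRT", nPlans = 10L, samplesPerType = 5L,
                        stepFactor = 2, cropThreshold = 0.1, hpoTrials = 0L,
                        maxEpochs = 12L, batchSize = 32L, learningRate = 1e-3,
                        patience = 3L, gammaSubsample = 4L, seed = 1L) {
  structure(list(modality = modality, nPlans = as.integer(nPlans),
                 samplesPerType = as.integer(samplesPerType),
                 stepFactor = stepFactor, cropThreshold = cropThreshold,
                 hpoTrials = as.integer(hpoTrials),
                 maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, patience = as.integer(patience),
                 gammaSubsample = as.integer(gammaSubsample),
                 seed = as.integer(seed)), class = "studyConfig")
}

#' Run the factorial study
#'
#' For every cell: simulate (or reuse) the shared plan/dose/error cohort,
#' compute the cell's comparison images, crop, normalize with
#' training-split statistics, resize, train the classifier and evaluate the
#' test accuracy. Upstream artifacts are cached by config-derived keys so
#' every cell sees identical raw images: all cells share one simulated
#' cohort and one split; cells sharing a method share byte-identical cropped
#' comparison images. Per-cell failures are recorded and the study
#' continues.
#'
#' @param cells data.frame from [enumerateCells()].
#' @param study a [studyConfig()].
#' @param cache optional environment reused across calls (for incremental
#'   studies); pass the \code{cache} of a previous result.
#' @return list with \code{results} (one row per cell: the cell factors,
#'   test accuracy in percent, split sizes, seed, runtime and an error
#'   string for failed cells) and \code{cache} (the stage cache).
#' @export
runStudy <- function(cells, study = studyConfig(), cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  getStage <- function(key, expr) {
    if (is.null(cache[[key]])) cache[[key]] <- force(expr)
    cache[[key]]
  }
  simCfg <- simConfig(study$modality, seed = study$seed)
  simKey <- sprintf("sim|%s|%d|%d|%d|%g", study$modality, study$seed,
                    study$nPlans, study$samplesPerType, study$stepFactor)
  ds <- getStage(simKey, simulateErrorDataset(
    simCfg, study$nPlans, samplesPerType = study$samplesPerType,
    stepFactor = study$stepFactor, seed = study$seed))
  splitKey <- paste0(simKey, "|split")
  split <- getStage(splitKey,
                    splitDataset(ds$manifest$level1, seed = study$seed + 1L))
  results <- data.frame()
  for (r in seq_len(nrow(cells))) {
    cell <- cells[r, ]
    t0 <- proc.time()[3]
    row <- data.frame(level = cell$level, method = cell$method,
                      normalization = cell$normalization,
                      resolution = cell$resolution,
                      accuracy = NA_real_, nTrain = sum(split == "train"),
                      nVal = sum(split == "val"), nTest = sum(split == "test"),
                      seed = study$seed, runtimeS = NA_real_,
                      error = NA_character_)
    res <- try({
      cropKey <- sprintf("%s|crop|%s|%d|%g", simKey, cell$method,
                         study$gammaSubsample, study$cropThreshold)
      cropped <- getStage(cropKey, {
        comps <- buildComparisonSet(ds, cell$method,
                                    gammaSubsample = study$gammaSubsample)
        mapply(function(cmp, ri) cropToField(cmp, ds$refs[[ri]],
                                             study$cropThreshold),
               comps, ds$refIdx, SIMPLIFY = FALSE)
      })
      xKey <- sprintf("%s|x|%s|%d", cropKey, cell$normalization,
                      cell$resolution)
      xPrep <- getStage(xKey, {
        stats <- computeDatasetStats(cropped[split == "train"])
        nch <- dim(cropped[[1]]@channels)[3]
        x <- array(0, c(cell$resolution, cell$resolution, nch,
                        length(cropped)))
        for (i in seq_along(cropped)) {
          img <- normalizeImage(cropped[[i]], stats, cell$normalization)
          x[, , , i] <- resizeSquare(img, cell$resolution)@channels
        }
        list(x = x, stats = stats)
      })
      y <- makeLabels(ds$manifest, cell$level)
      cellSeed <- study$seed + 100L * r
      if (study$hpoTrials > 0L) {
        tuned <- tuneHyperparameters(xPrep$x, y, split,
          hpoConfig(nTrials = study$hpoTrials, maxEpochs = study$maxEpochs,
                    seed = cellSeed))
        model <- tuned$model
      } else {
        cfg <- trainConfig(maxEpochs = study$maxEpochs,
                           batchSize = study$batchSize,
                           learningRate = study$learningRate,
                           patience = study$patience, seed = cellSeed)
        model <- trainModel(xPrep$x, y, split, cfg = cfg)
      }
      ti <- split == "test"
      evaluateAccuracy(model, xPrep$x[, , , ti, drop = FALSE], y[ti])
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      row$error <- conditionMessage(attr(res, "condition"))
    } else {
      row$accuracy <- res
    }
    row$runtimeS <- proc.time()[3] - t0
    results <- rbind(results, row)
  }
  list(results = results, cache = cache)
}

#' Summarize study accuracies by a design factor
#'
#' Median, quartiles and range of the test accuracy grouped by the chosen
#' factor, separately per classification level — the reporting style used
#' for factor rankings.
#'
#' @param results the \code{results} data.frame of [runStudy()].
#' @param by grouping factor: "method", "normalization" or "resolution".
#' @return data.frame with one row per (level, group).
#' @export
summarizeStudy <- function(results, by = c("method", "normalization",
                                           "resolution")) {
  by <- match.arg(by)
  results <- results[!is.na(results$accuracy), , drop = FALSE]
  stopifnot(nrow(results) > 0)
  groups <- split(results, list(results$level, results[[by]]), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) data.frame(
    level = g$level[1], group = as.character(g[[by]][1]), n = nrow(g),
    median = stats::median(g$accuracy),
    q1 = unname(stats::quantile(g$accuracy, 0.25)),
    q3 = unname(stats::quantile(g$accuracy, 0.75)),
    min = min(g$accuracy), max = max(g$accuracy))))
  names(out)[names(out) == "group"] <- by
  rownames(out) <- NULL
  out[order(out$level, -out$median), ]
}

#' Rank-sum comparison between two factor groups
#'
#' Wilcoxon rank-sum test between the accuracies of two groups of a design
#' factor (pooling the other factors), per level. This is the harness's own
#' choice of significance procedure for factor contrasts.
#'
#' @param results the \code{results} data.frame of [runStudy()].
#' @param factor design factor name.
#' @param a,b the two factor values to compare.
#' @param level classification level to restrict to.
#' @return the \code{htest} object of [stats::wilcox.test()].
#' @export
compareFactorGroups <- function(results, factor, a, b, level = 1) {
  results <- results[!is.na(results$accuracy) & results$level == level, ]
  ga <- results$accuracy[results[[factor]] == a]
  gb <- results$accuracy[results[[factor]] == b]
  stopifnot(length(ga) > 0, length(gb) > 0)
  stats::wilcox.test(ga, gb, exact = FALSE)
}
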