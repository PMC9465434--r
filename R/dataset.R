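#' Simulate a labelled error dataset
#'
#' Generates a plan cohort, renders the error-free reference dose of every
#' arc, and for every arc draws error simulations of all five mechanical
#' error types with target magnitudes sampled from the (optionally reduced)
#' magnitude grids. Each sample renders the perturbed arc dose; the dataset
#' unit is the treatment arc.
#'
#' @param config a [SimConfig-class].
#' @param nPlans number of plans in the cohort.
#' @param samplesPerType error simulations per arc and type.
#' @param stepFactor magnitude-grid step multiplier (2 halves each grid for
#'   desk-scale studies; 1 is the full 20-point grid).
#' @param types error types to simulate (default all five).
#' @param seed base seed; all draws derive from it.
#' @return list with \code{refs} (reference [DoseImage-class] per arc),
#'   \code{evals} (perturbed [DoseImage-class] per sample), \code{refIdx}
#'   (arc index per sample) and \code{manifest} (data.frame: plan, arc,
#'   errorType, magnitude, level1, level2, banksAffected, clampedLeafPairs,
#'   seed).
#' @export
simulateErrorDataset <- function(config, nPlans, samplesPerType = 2L,
                                 stepFactor = 2, types = errorTypes(),
                                 seed = config@seed) {
  plans <- generateCohort(config, nPlans, seed = seed)
  refs <- list()
  evals <- list()
  refIdx <- integer()
  manifest <- data.frame()
  arcNo <- 0L
  sampleSeed <- seed * 13L
  for (p in seq_len(nPlans)) {
    plan <- plans[[p]]
    for (a in seq_along(arcs(plan))) {
      arcNo <- arcNo + 1L
      refs[[arcNo]] <- renderDose(plan, config, arc = a)
      for (ty in types) {
        grid <- magnitudeGrid(ty, stepFactor = stepFactor)
        mags <- withSeed(sampleSeed + arcNo * 101L + match(ty, errorTypes()),
                         sample(grid, samplesPerType))
        for (m in mags) {
          sampleSeed <- sampleSeed + 1L
          spec <- sampleErrorSpec(ty, m, plan, seed = sampleSeed)
          perturbed <- applyError(plan, spec)
          evals[[length(evals) + 1L]] <- renderDose(perturbed, config, arc = a)
          refIdx <- c(refIdx, arcNo)
          manifest <- rbind(manifest, data.frame(
            plan = p, arc = a, errorType = ty, magnitude = spec@magnitude,
            level1 = spec@errorType,
            level2 = level2Label(ty, spec@magnitude),
            banksAffected = spec@banksAffected,
            clampedLeafPairs = attr(perturbed, "clampedLeafPairs"),
            seed = sampleSeed))
        }
      }
    }
  }
  list(refs = refs, evals = evals, refIdx = refIdx, manifest = manifest)
}

#' Comparison images for every sample of an error dataset
#'
#' @param ds a dataset from [simulateErrorDataset()].
#' @param method one of [comparisonMethods()].
#' @param gammaSubsample candidate-grid refinement for gamma variants.
#' @return list of [ComparisonImage-class], parallel to \code{ds$evals}.
#' @export
buildComparisonSet <- function(ds, method, gammaSubsample = 4L) {
  lapply(seq_along(ds$evals), function(i)
    compareDose(ds$refs[[ds$refIdx[i]]], ds$evals[[i]], method,
                gammaSubsample = gammaSubsample))
}

#' Classification labels for a dataset manifest
#'
#' Level 1 labels the error type (5 classes). Level 2 labels the error
#' relevance (relevant/irrelevant from the per-type thresholds); with
#' \code{joint = TRUE} the 10-class type-by-relevance variant is returned
#' instead.
#'
#' @param manifest the manifest of [simulateErrorDataset()].
#' @param level 1 or 2.
#' @param joint use the joint type-x-relevance labelling for level 2?
#' @return character label per sample.
#' @export
makeLabels <- function(manifest, level, joint = FALSE) {
  stopifnot(level %in% 1:2)
  if (level == 1) manifest$level1
  else if (joint) paste(manifest$level1, manifest$level2, sep = ":")
  else manifest$level2
}

#' Save / load a preprocessed image dataset
#'
#' The container is a directory of 32-bit float multi-page TIFF images (one
#' page per channel, affine-rescaled with the scale recorded per image), a
#' manifest CSV with labels and split assignment, the normalization
#' statistics, and the full provenance configuration as YAML.
#'
#' @param x image array (side, side, channels, n).
#' @param manifest data.frame of per-sample metadata.
#' @param split split assignment per sample.
#' @param stats the [DatasetStats-class] used for normalization.
#' @param config provenance (any list; stored as YAML).
#' @param dir target directory (created if needed).
#' @return \code{saveDataset}: the directory, invisibly.
#'   \code{loadDataset}: a list with the same four components.
#' @export
saveDataset <- function(x, manifest, split, stats, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(x)[4]
  scales <- data.frame(sample = seq_len(n), offset = 0, scale = 1)
  for (i in seq_len(n)) {
    img <- x[, , , i, drop = FALSE]
    lo <- min(img)
    hi <- max(img)
    sc <- if (hi > lo) hi - lo else 1
    scales$offset[i] <- lo
    scales$scale[i] <- sc
    pages <- lapply(seq_len(dim(x)[3]), function(c) (x[, , c, i] - lo) / sc)
    tiff::writeTIFF(pages, file.path(dir, sprintf("img%05d.tif", i)),
                    bits.per.sample = 32L)
  }
  utils::write.csv(cbind(manifest, split = split, scales[-1]),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(data.frame(channel = seq_along(stats@mean),
                              mean = stats@mean, sd = stats@sd,
                              clipMin = stats@clipMin,
                              clipMax = stats@clipMax),
                   file.path(dir, "stats.csv"), row.names = FALSE)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname saveDataset
#' @export
loadDataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  st <- utils::read.csv(file.path(dir, "stats.csv"))
  config <- yaml::read_yaml(file.path(dir, "config.yaml"))
  n <- nrow(man)
  first <- tiff::readTIFF(file.path(dir, "img00001.tif"), all = TRUE)
  side <- nrow(first[[1]])
  nch <- length(first)
  x <- array(0, c(side, side, nch, n))
  for (i in seq_len(n)) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("img%05d.tif", i)),
                            all = TRUE)
    for (c in seq_len(nch))
      x[, , c, i] <- pages[[c]] * man$scale[i] + man$offset[i]
  }
  stats <- new("DatasetStats", mean = st$mean, sd = st$sd,
               clipMin = st$clipMin, clipMax = st$clipMax)
  list(x = x, manifest = man[, setdiff(names(man), c("offset", "scale"))],
       split = man$split, stats = stats, config = config)
}
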