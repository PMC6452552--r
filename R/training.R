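## Grayscale-group assignment, pixel sampling and the two integration levels:
## one pooled full-view forest and a bank of per-group zoom-view forests.

#' Create a training configuration
#'
#' Defaults reproduce the reference setting: N = 37 grayscale groups,
#' M = 2000 sampled pixels per image, T = 100 trees of depth at most D = 9.
#'
#' @param nGroups number of grayscale groups N.
#' @param samplesPerImage pixels sampled per training image M.
#' @param nTrees trees per forest T.
#' @param maxDepth maximum tree depth D.
#' @param featureConfig a \linkS4class{FeatureConfig}.
#' @param balanceClasses draw half of each sample from each class; thin
#'   membranes cover a small area fraction, so proportional sampling would
#'   starve the foreground class.
#' @param seed integer master seed.
#' @return a \linkS4class{TrainingConfig}.
#' @export
trainingConfig <- function(nGroups = 37L, samplesPerImage = 2000L,
                           nTrees = 100L, maxDepth = 9L,
                           featureConfig = RFStacks::featureConfig(),
                           balanceClasses = TRUE, seed = 1L) {
  new("TrainingConfig",
      nGroups = as.integer(nGroups),
      samplesPerImage = as.integer(samplesPerImage),
      nTrees = as.integer(nTrees), maxDepth = as.integer(maxDepth),
      featureConfig = featureConfig,
      balanceClasses = balanceClasses, seed = as.integer(seed))
}

#' Assign an image to its grayscale group
#'
#' The group is the bin containing the image's mean membrane gray value
#' (mean of image pixels under the mask). Means below the first bin clamp to
#' group 1 and means at or above the last bin clamp to group N, each with a
#' warning.
#'
#' @param image a \linkS4class{LabeledImage} with a non-empty mask.
#' @param groups a \linkS4class{GrayscaleGroups}.
#' @return integer group index.
#' @export
assignGroup <- function(image, groups) {
  m <- maskMean(image)           # errors on an empty mask
  iv <- groupIntervals(groups)
  n <- nrow(iv)
  if (m < iv[1, 1]) {
    warning(sprintf("mask mean %.2f below the first bin; clamped to group 1", m))
    return(1L)
  }
  if (m >= iv[n, 2]) {
    warning(sprintf("mask mean %.2f above the last bin; clamped to group %d", m, n))
    return(n)
  }
  which(m >= iv[, 1] & m < iv[, 2])[1]
}

#' Sample labelled pixels from an image
#'
#' Draws exactly M pixels without replacement. In balanced mode (default)
#' ceiling(M/2) membrane and floor(M/2) background pixels are drawn; if a
#' class is too small, sampling falls back to class-proportional with a
#' warning. Feature vectors are read from the image's feature stack at the
#' sampled coordinates.
#'
#' @param image a \linkS4class{LabeledImage}.
#' @param M number of pixels to draw.
#' @param balance balanced class sampling (default TRUE).
#' @param seed integer seed.
#' @param cfg a \linkS4class{FeatureConfig}.
#' @param stack optional precomputed \linkS4class{FeatureStack} for
#'   \code{image} under \code{cfg} (avoids recomputation).
#' @return a \linkS4class{PixelSamples} of exactly M rows.
#' @export
samplePixels <- function(image, M, balance = TRUE, seed = 1L,
                         cfg = featureConfig(), stack = NULL) {
  stopifnot(is(image, "LabeledImage"))
  M <- as.integer(M)
  npix <- length(image@mask)
  if (M > npix)
    stop(sprintf("cannot draw %d samples from %d pixels", M, npix))
  fg <- which(image@mask)
  bg <- which(!image@mask)
  nFg <- as.integer(ceiling(M / 2)); nBg <- M - nFg
  idx <- withSeed(seed, {
    if (balance && (length(fg) < nFg || length(bg) < nBg)) {
      warning("a class is too small for balanced sampling; falling back to proportional")
      balance <- FALSE
    }
    if (balance)
      c(fg[sample.int(length(fg), nFg)], bg[sample.int(length(bg), nBg)])
    else
      sample.int(npix, M)
  })
  if (is.null(stack)) stack <- computeFeatureStack(image, cfg)
  fm <- featureMatrix(stack)
  rc <- arrayInd(idx, dim(image@mask))
  new("PixelSamples",
      features = fm[idx, , drop = FALSE],
      labels = factor(ifelse(image@mask[idx], "GBM", "background"),
                      levels = c("background", "GBM")),
      origin = data.frame(image = image@provenance,
                          row = rc[, 1], col = rc[, 2]))
}

#' Combine pixel samples
#'
#' @param ... \linkS4class{PixelSamples} objects with identical channels.
#' @return a single pooled \linkS4class{PixelSamples}.
#' @export
poolSamples <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is(parts[[1]], "PixelSamples"))
    parts <- parts[[1]]
  cn <- colnames(parts[[1]]@features)
  for (p in parts)
    if (!identical(colnames(p@features), cn))
      stop("cannot pool samples with differing feature channels")
  new("PixelSamples",
      features = do.call(rbind, lapply(parts, function(p) p@features)),
      labels = factor(unlist(lapply(parts, function(p) as.character(p@labels))),
                      levels = c("background", "GBM")),
      origin = do.call(rbind, lapply(parts, function(p) p@origin)))
}

#' Number of samples
#' @param x a \linkS4class{PixelSamples}.
#' @return integer count.
#' @export
nSamples <- function(x) {
  stopifnot(is(x, "PixelSamples"))
  nrow(x@features)
}

#' Train one bagged decision-tree ensemble
#'
#' Grows T trees, each on a bootstrap resample with random feature-subset
#' selection at every split (subset size sqrt(F), the usual forest
#' convention, Gini split criterion) and depth capped at D. The model
#' carries its ordered feature channel names and refuses to predict under a
#' mismatched feature configuration.
#'
#' @param samples a \linkS4class{PixelSamples} containing both classes.
#' @param nTrees number of trees T.
#' @param maxDepth depth cap D.
#' @param seed integer seed; identical samples + seed give identical models.
#' @return a \linkS4class{ForestModel}.
#' @export
trainForest <- function(samples, nTrees = 100L, maxDepth = 9L, seed = 1L) {
  stopifnot(is(samples, "PixelSamples"))
  if (length(unique(samples@labels)) < 2L)
    stop("training samples must contain both classes")
  df <- data.frame(samples@features, check.names = FALSE)
  df$..class <- samples@labels
  fit <- ranger::ranger(
    dependent.variable.name = "..class", data = df,
    num.trees = as.integer(nTrees), max.depth = as.integer(maxDepth),
    mtry = max(1L, floor(sqrt(ncol(samples@features)))),
    splitrule = "gini", seed = as.integer(seed), num.threads = 1L,
    verbose = FALSE)
  new("ForestModel", forest = fit,
      channelNames = colnames(samples@features),
      meta = list(nTrees = as.integer(nTrees), maxDepth = as.integer(maxDepth),
                  seed = as.integer(seed), splitrule = "gini",
                  nSamples = nrow(df)))
}

#' @rdname channelNames
#' @export
setMethod("channelNames", "ForestModel", function(x) x@channelNames)

setMethod("show", "ForestModel", function(object) {
  cat(sprintf("ForestModel: %d trees, depth <= %d, %d feature channels, %d training samples\n",
              object@meta$nTrees, object@meta$maxDepth,
              length(object@channelNames), object@meta$nSamples))
})

## One image per group per training session; selection and per-image sample
## seeds all derive from the master seed so a session replays bit-identically.
.selectSessionImages <- function(dataset, seed) {
  counts <- vapply(dataset@images, length, integer(1))
  if (any(counts == 0L))
    stop("every grayscale group needs at least one training image")
  withSeed(deriveSeed(seed, 0L),
           vapply(counts, function(k) sample.int(k, 1L), integer(1)))
}

.sessionSamples <- function(dataset, cfg, selected) {
  lapply(seq_len(nGroups(dataset)), function(g) {
    samplePixels(dataset@images[[g]][[selected[g]]],
                 M = cfg@samplesPerImage, balance = cfg@balanceClasses,
                 seed = deriveSeed(cfg@seed, g), cfg = cfg@featureConfig)
  })
}

#' Train the full-view classifier
#'
#' Selects one image per grayscale group (at random under the session seed),
#' pools their M samples each into one M x N training set, and fits a single
#' forest on it. Pooling across the whole grayscale range is what gives the
#' full-view model its generalization across intensities.
#'
#' @param dataset a \linkS4class{GroupedTrainingSet} with no empty group.
#' @param cfg a \linkS4class{TrainingConfig}.
#' @return a \linkS4class{FullViewModel}; provenance records the selected
#'   image per group and the pooled sample count.
#' @export
trainFullView <- function(dataset, cfg) {
  stopifnot(is(dataset, "GroupedTrainingSet"), is(cfg, "TrainingConfig"))
  selected <- .selectSessionImages(dataset, cfg@seed)
  pooled <- poolSamples(.sessionSamples(dataset, cfg, selected))
  forest <- trainForest(pooled, nTrees = cfg@nTrees, maxDepth = cfg@maxDepth,
                        seed = cfg@seed)
  new("FullViewModel", forest = forest,
      provenance = list(selectedImages = selected,
                        pooledCount = nSamples(pooled)))
}

#' Train the zoom-view classifier bank
#'
#' Selects one image per group under the same session-seed rule as
#' \code{\link{trainFullView}} and fits N independent forests, forest g on
#' group g's M samples only, with per-group seeds derived deterministically
#' from the master seed.
#'
#' @inheritParams trainFullView
#' @return a \linkS4class{ZoomViewModel} with forests index-aligned to the
#'   grayscale groups.
#' @export
trainZoomView <- function(dataset, cfg) {
  stopifnot(is(dataset, "GroupedTrainingSet"), is(cfg, "TrainingConfig"))
  selected <- .selectSessionImages(dataset, cfg@seed)
  samples <- .sessionSamples(dataset, cfg, selected)
  forests <- lapply(seq_along(samples), function(g)
    trainForest(samples[[g]], nTrees = cfg@nTrees, maxDepth = cfg@maxDepth,
                seed = deriveSeed(cfg@seed, g)))
  new("ZoomViewModel", forests = forests, groups = dataset@groups,
      provenance = list(selectedImages = selected))
}

#' @rdname nGroups
#' @export
setMethod("nGroups", "ZoomViewModel", function(x) length(x@forests))

#' @rdname groupIntervals
#' @export
setMethod("groupIntervals", "ZoomViewModel", function(x) x@groups@intervals)

#' Extract one forest of the zoom-view bank
#'
#' @param zoom a \linkS4class{ZoomViewModel}.
#' @param g group index.
#' @return a \linkS4class{ForestModel}.
#' @export
zoomForest <- function(zoom, g) {
  stopifnot(is(zoom, "ZoomViewModel"))
  zoom@forests[[g]]
}

#' The forest inside a full-view model
#'
#' @param full a \linkS4class{FullViewModel}.
#' @return a \linkS4class{ForestModel}.
#' @export
fullViewForest <- function(full) {
  stopifnot(is(full, "FullViewModel"))
  full@forest
}

setMethod("show", "FullViewModel", function(object) {
  cat(sprintf("FullViewModel: pooled forest over %d groups (%d samples)\n",
              length(object@provenance$selectedImages),
              object@provenance$pooledCount))
  show(object@forest)
})

setMethod("show", "ZoomViewModel", function(object) {
  cat(sprintf("ZoomViewModel: bank of %d per-group forests\n", nGroups(object)))
  show(object@groups)
})
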