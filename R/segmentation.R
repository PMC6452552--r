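## Test-phase fusion: per-pixel voting inside each forest, a probability map
## across the zoom-view coarse results, fuzzy C-means bipartition,
## morphological cleanup and the iterative refinement loop that discards
## coarse results dissimilar from the evolving consensus.

#' Fuzzy C-means settings
#'
#' @param fuzzifier exponent m (> 1, default 2).
#' @param tol convergence threshold (default 1e-5).
#' @param maxIters iteration cap (default 300).
#' @param seed used only to perturb degenerate ties.
#' @return an \linkS4class{FcmConfig}.
#' @export
fcmConfig <- function(fuzzifier = 2, tol = 1e-5, maxIters = 300L, seed = 1L) {
  new("FcmConfig", fuzzifier = fuzzifier, tol = tol,
      maxIters = as.integer(maxIters), seed = as.integer(seed))
}

#' Morphological cleanup settings
#'
#' @param minComponentArea remove 8-connected components below this area.
#' @param openingRadius disc radius of the binary opening (0 disables).
#' @return a \linkS4class{CleanupConfig}.
#' @export
cleanupConfig <- function(minComponentArea = 50L, openingRadius = 1L) {
  new("CleanupConfig", minComponentArea = as.integer(minComponentArea),
      openingRadius = as.integer(openingRadius))
}

#' Iterative refinement settings
#'
#' @param w1 initial retention fraction in (0, 1]; with \code{w1 = 1} all
#'   coarse results enter the first iteration unfiltered.
#' @param w2 Jaccard cutoff in [0, 1): a coarse result is retained when its
#'   Jaccard similarity to the current consensus is at least w2.
#' @param maxIters refinement iteration cap (default 10).
#' @param fcm an \linkS4class{FcmConfig}.
#' @param cleanup a \linkS4class{CleanupConfig}.
#' @return a \linkS4class{RefinementConfig}.
#' @export
refinementConfig <- function(w1 = 1, w2 = 0.3, maxIters = 10L,
                             fcm = fcmConfig(), cleanup = cleanupConfig()) {
  new("RefinementConfig", w1 = w1, w2 = w2, maxIters = as.integer(maxIters),
      fcm = fcm, cleanup = cleanup)
}

## ---- forest voting --------------------------------------------------------

## Fraction of trees voting for the membrane class, per row of a feature
## matrix. Kept separate from the mask rule so both are testable.
.voteFractions <- function(model, fm) {
  if (!identical(colnames(fm), model@channelNames))
    stop("feature channels do not match the channels the model was trained on")
  pr <- ranger::predictions(
    stats::predict(model@forest, data.frame(fm, check.names = FALSE),
                   predict.all = TRUE, num.threads = 1L))
  gbmIdx <- which(model@forest$forest$levels == "GBM")
  rowMeans(pr == gbmIdx)
}

## Majority rule: membrane iff strictly more than half the trees agree; an
## exact tie goes to background (conservative for a thin foreground class).
.voteMask <- function(fractions) fractions > 0.5

.predictMaskFromMatrix <- function(model, fm, dims) {
  matrix(.voteMask(.voteFractions(model, fm)), dims[1], dims[2])
}

#' Classify every pixel of an image with one forest
#'
#' Each tree votes per pixel; the pixel is labelled membrane iff the vote
#' fraction exceeds 0.5 (an exact tie is background).
#'
#' @param model a \linkS4class{ForestModel} or \linkS4class{FullViewModel}.
#' @param image numeric matrix in [0, 255] or a \linkS4class{LabeledImage}.
#' @param cfg the \linkS4class{FeatureConfig}; its channels must match the
#'   channels the model was trained on.
#' @return logical mask matrix.
#' @name classifyImage
#' @export
setMethod("classifyImage", signature("ForestModel", "ANY", "FeatureConfig"),
          function(model, image, cfg) {
  if (is(image, "LabeledImage")) image <- grayImage(image)
  stack <- computeFeatureStack(image, cfg)
  .predictMaskFromMatrix(model, featureMatrix(stack), dim(image))
})

#' @rdname classifyImage
#' @export
setMethod("classifyImage", signature("FullViewModel", "ANY", "FeatureConfig"),
          function(model, image, cfg) {
  classifyImage(model@forest, image, cfg)
})

#' Coarse results of the zoom-view bank
#'
#' Applies every forest of the bank to the image (the feature stack is
#' computed once and shared); output order matches forest order.
#'
#' @param zoom a \linkS4class{ZoomViewModel}.
#' @param image numeric matrix or \linkS4class{LabeledImage}.
#' @param cfg the shared \linkS4class{FeatureConfig}.
#' @return list of N logical masks.
#' @export
coarseResults <- function(zoom, image, cfg) {
  stopifnot(is(zoom, "ZoomViewModel"))
  if (is(image, "LabeledImage")) image <- grayImage(image)
  fm <- featureMatrix(computeFeatureStack(image, cfg))
  lapply(zoom@forests, .predictMaskFromMatrix, fm = fm, dims = dim(image))
}

## ---- probability map ------------------------------------------------------

#' Per-pixel membrane probability across coarse results
#'
#' \code{p(i,j) = n(i,j) / N} where \code{n(i,j)} counts the coarse results
#' marking pixel (i,j) as membrane; equivalently the pixel-wise mean of the
#' indicator masks. No smoothing is applied.
#'
#' @param x list of logical masks of identical shape, or a
#'   \linkS4class{SegmentationResult} (returns the stored map).
#' @return numeric matrix with values in \{k/N\}.
#' @name probabilityMap
#' @export
setMethod("probabilityMap", "list", function(x) {
  if (length(x) == 0L) stop("need at least one coarse result")
  d <- dim(x[[1]])
  for (m in x) {
    assertBinaryMask(m, "coarse result")
    if (!identical(dim(m), d)) stop("coarse results must share one shape")
  }
  Reduce(`+`, lapply(x, `*`, 1)) / length(x)
})

#' @rdname probabilityMap
#' @export
setMethod("probabilityMap", "SegmentationResult",
          function(x) x@probabilityMap)

## ---- fuzzy C-means bipartition -------------------------------------------

#' Bipartition a probability map with fuzzy C-means
#'
#' Classical 2-cluster FCM on the scalar probability values, initialized
#' deterministically from the two extreme observed values. Clustering is run
#' on the weighted unique values (algebraically identical to clustering all
#' pixels, since the objective depends on the data only through value
#' counts). Membrane pixels are those whose membership is highest for the
#' cluster with the larger centroid. A degenerate all-equal map yields an
#' empty mask with a warning.
#'
#' @param pm numeric probability-map matrix.
#' @param cfg an \linkS4class{FcmConfig}.
#' @return logical mask.
#' @export
fcmBipartition <- function(pm, cfg = fcmConfig()) {
  vals <- sort(unique(as.vector(pm)))
  if (length(vals) < 2L) {
    warning("probability map is constant; returning an empty mask")
    return(matrix(FALSE, nrow(pm), ncol(pm)))
  }
  counts <- tabulate(match(as.vector(pm), vals), nbins = length(vals))
  rng <- range(vals)
  eps <- 1e-6 * diff(rng)
  centers <- matrix(c(rng[1] + eps, rng[2] - eps), 2L, 1L)
  fit <- e1071::cmeans(matrix(vals, ncol = 1L), centers = centers,
                       weights = counts, m = cfg@fuzzifier,
                       iter.max = cfg@maxIters,
                       control = list(reltol = cfg@tol),
                       method = "cmeans", verbose = FALSE)
  hi <- which.max(fit$centers[, 1])
  gbmVals <- vals[fit$membership[, hi] > fit$membership[, -hi]]
  matrix(as.vector(pm) %in% gbmVals, nrow(pm), ncol(pm))
}

## ---- morphological cleanup ------------------------------------------------

#' Remove small false positives from a binary mask
#'
#' Binary opening with a disc of the configured radius followed by removal
#' of 8-connected components smaller than the minimum area. Never adds
#' pixels outside the input mask.
#'
#' @param mask logical mask.
#' @param cfg a \linkS4class{CleanupConfig}.
#' @return logical mask.
#' @export
morphologicalCleanup <- function(mask, cfg = cleanupConfig()) {
  assertBinaryMask(mask)
  m <- mask
  if (cfg@openingRadius > 0L && any(m)) {
    r <- cfg@openingRadius
    opened <- cropCenter(
      EBImage::opening(padReflect(m * 1, r), discBrush(r)),
      r, nrow(m), ncol(m))
    m <- opened > 0.5
  }
  if (cfg@minComponentArea > 1L && any(m)) {
    lab <- label8(m)
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= cfg@minComponentArea)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  m
}

## ---- iterative refinement -------------------------------------------------

## Consensus of a retained subset: probability map, bipartition (fuzzy
## C-means or plain 0.5 thresholding), cleanup.
.consensus <- function(crs, cfg, method = c("fcm", "threshold")) {
  method <- match.arg(method)
  pm <- probabilityMap(crs)
  core <- if (method == "fcm") fcmBipartition(pm, cfg@fcm) else pm >= 0.5
  morphologicalCleanup(core, cfg@cleanup)
}

#' Iteratively refine the coarse-result consensus
#'
#' Starting from the retained set S (all coarse results when \code{w1 = 1},
#' otherwise the top \code{ceiling(w1 * N)} ranked by mean pairwise Jaccard
#' to the others), the loop rebuilds the consensus from S — probability map,
#' bipartition, cleanup — then recomputes every coarse result's Jaccard
#' similarity to the consensus and retains those scoring at least \code{w2}.
#' It stops when S is unchanged, S would become empty (the previous S is
#' kept), or the iteration cap is reached.
#'
#' @param crs non-empty list of coarse masks (identical shapes).
#' @param cfg a \linkS4class{RefinementConfig}.
#' @param consensus \code{"fcm"} (default) bipartitions the probability map
#'   with fuzzy C-means; \code{"threshold"} uses plain \code{p >= 0.5}
#'   majority (used by the ablation variants).
#' @return list with elements \code{mask} (the final consensus) and
#'   \code{retained} (integer indices of the final retained set).
#' @export
iterativeRefinement <- function(crs, cfg = refinementConfig(),
                                consensus = c("fcm", "threshold")) {
  consensus <- match.arg(consensus)
  if (!is.list(crs) || length(crs) == 0L)
    stop("need a non-empty list of coarse results")
  n <- length(crs)
  S <- seq_len(n)
  if (cfg@w1 < 1 && n > 1L) {
    jac <- matrix(1, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      jac[i, j] <- jac[j, i] <- jaccard(crs[[i]], crs[[j]])
    }
    affinity <- (rowSums(jac) - 1) / (n - 1)   # mean pairwise similarity
    keep <- max(1L, as.integer(ceiling(cfg@w1 * n)))
    S <- sort(order(affinity, decreasing = TRUE)[seq_len(keep)])
  }
  C <- .consensus(crs[S], cfg, consensus)
  for (iter in seq_len(cfg@maxIters)) {
    J <- vapply(crs, jaccard, numeric(1), B = C)
    Snew <- which(J >= cfg@w2)
    if (length(Snew) == 0L || identical(Snew, S)) break
    S <- Snew
    C <- .consensus(crs[S], cfg, consensus)
  }
  list(mask = C, retained = S)
}

## ---- the full test-phase pipeline -----------------------------------------

#' Segment a test image with both candidates
#'
#' Produces candidate R1 (full-view forest, then cleanup) and candidate R2
#' (zoom-view coarse results fused by probability map, fuzzy C-means,
#' cleanup and iterative refinement). The feature stack is computed once and
#' shared by all forests. When a gold mask is supplied, both candidates are
#' Jaccard-scored; the final choice between R1 and R2 is left unset by
#' default because it belongs to the human reviewer, unless
#' \code{autoSelect = TRUE} and a gold mask is available.
#'
#' @param image numeric matrix or \linkS4class{LabeledImage}.
#' @param full a \linkS4class{FullViewModel}.
#' @param zoom a \linkS4class{ZoomViewModel} trained under the same feature
#'   configuration.
#' @param featureCfg the shared \linkS4class{FeatureConfig}.
#' @param cfg a \linkS4class{RefinementConfig}.
#' @param gold optional logical gold mask.
#' @param autoSelect when TRUE and gold is given, set \code{selected} to the
#'   higher-scoring candidate.
#' @param cleanupR1 apply the same morphological cleanup to R1 as to R2's
#'   consensus (default TRUE, which keeps the two candidates comparable).
#' @return a \linkS4class{SegmentationResult}.
#' @export
segmentImage <- function(image, full, zoom, featureCfg = featureConfig(),
                         cfg = refinementConfig(), gold = NULL,
                         autoSelect = FALSE, cleanupR1 = TRUE) {
  stopifnot(is(full, "FullViewModel"), is(zoom, "ZoomViewModel"))
  goldMask <- gold
  if (is(image, "LabeledImage")) {
    if (is.null(goldMask)) goldMask <- gbmMask(image)
    image <- grayImage(image)
  }
  if (!identical(channelNames(full@forest),
                 channelNames(zoom@forests[[1]])))
    stop("full-view and zoom-view models were trained on different feature channels")
  fm <- featureMatrix(computeFeatureStack(image, featureCfg))
  d <- dim(image)
  r1 <- .predictMaskFromMatrix(full@forest, fm, d)
  if (cleanupR1) r1 <- morphologicalCleanup(r1, cfg@cleanup)
  crs <- lapply(zoom@forests, .predictMaskFromMatrix, fm = fm, dims = d)
  ref <- iterativeRefinement(crs, cfg)
  j1 <- j2 <- NA_real_
  selected <- "unset"
  if (!is.null(goldMask)) {
    j1 <- jaccard(goldMask, r1)
    j2 <- jaccard(goldMask, ref$mask)
    if (autoSelect) selected <- if (j1 >= j2) "R1" else "R2"
  }
  new("SegmentationResult",
      R1 = r1, R2 = ref$mask, coarseResults = crs,
      probabilityMap = probabilityMap(crs),
      retainedIndices = as.integer(ref$retained),
      jaccardR1 = j1, jaccardR2 = j2, selected = selected)
}

#' @rdname SegmentationResult-accessors
#' @name SegmentationResult-accessors
#' @aliases candidateR1 candidateR2 retainedIndices coarseMasks
#' @param x a \linkS4class{SegmentationResult}.
#' @export
setMethod("candidateR1", "SegmentationResult", function(x) x@R1)

#' @rdname SegmentationResult-accessors
#' @export
setMethod("candidateR2", "SegmentationResult", function(x) x@R2)

#' @rdname SegmentationResult-accessors
#' @export
setMethod("retainedIndices", "SegmentationResult", function(x) x@retainedIndices)

#' @rdname SegmentationResult-accessors
#' @export
setMethod("coarseMasks", "SegmentationResult", function(x) x@coarseResults)

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult %dx%d: R1 %d px, R2 %d px, %d/%d coarse results retained\n",
              nrow(object@R1), ncol(object@R1), sum(object@R1), sum(object@R2),
              length(object@retainedIndices), length(object@coarseResults)))
  if (!is.na(object@jaccardR1))
    cat(sprintf("  Jaccard: R1 = %.3f, R2 = %.3f, selected = %s\n",
                object@jaccardR1, object@jaccardR2, object@selected))
})
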