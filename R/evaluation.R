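## Jaccard scoring, the cross-grayscale heat map, and the ablation suite.

#' Jaccard similarity of two binary masks
#'
#' \code{|A intersect B| / |A union B|}. Two empty masks score 1 by
#' convention; exactly one empty mask scores 0.
#'
#' @param A,B logical masks of identical shape.
#' @return numeric in [0, 1].
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
#' b <- matrix(FALSE, 4, 4); b[1:2, 2:3] <- TRUE
#' jaccard(a, b)   # 2 / 6
#' @export
jaccard <- function(A, B) {
  assertBinaryMask(A, "A"); assertBinaryMask(B, "B")
  if (!identical(dim(A), dim(B)))
    stop("masks must have identical shapes")
  u <- sum(A | B)
  if (u == 0L) return(1)
  sum(A & B) / u
}

#' Cross-grayscale heat map of the zoom-view bank
#'
#' Scores every (test image, zoom-view forest) pair: cell (t, g) is the
#' Jaccard of test image t's gold mask against the cleaned-up prediction of
#' forest g. Rows are ordered by the test image's mean membrane gray value,
#' so grayscale-specific forests produce a bright diagonal band.
#'
#' @param zoom a \linkS4class{ZoomViewModel}.
#' @param tests list of \linkS4class{LabeledImage} with gold masks.
#' @param featureCfg the shared \linkS4class{FeatureConfig}.
#' @param cleanup a \linkS4class{CleanupConfig} applied to every prediction.
#' @return a \linkS4class{HeatmapGrid}.
#' @export
heatmapGrid <- function(zoom, tests, featureCfg = featureConfig(),
                        cleanup = cleanupConfig()) {
  stopifnot(is(zoom, "ZoomViewModel"), length(tests) > 0L)
  means <- vapply(tests, maskMean, numeric(1))
  ord <- order(means)
  tests <- tests[ord]; means <- means[ord]
  n <- length(tests); ng <- nGroups(zoom)
  scores <- matrix(NA_real_, n, ng,
                   dimnames = list(NULL, paste0("group", seq_len(ng))))
  for (t in seq_len(n)) {
    img <- grayImage(tests[[t]])
    fm <- featureMatrix(computeFeatureStack(img, featureCfg))
    for (g in seq_len(ng)) {
      pred <- morphologicalCleanup(
        .predictMaskFromMatrix(zoom@forests[[g]], fm, dim(img)), cleanup)
      scores[t, g] <- jaccard(gbmMask(tests[[t]]), pred)
    }
  }
  new("HeatmapGrid", scores = scores, rowMeans = means,
      colIntervals = groupIntervals(zoom))
}

#' @describeIn heatmapGrid the score matrix.
#' @param x a \linkS4class{HeatmapGrid}.
#' @export
jaccardScores <- function(x) {
  stopifnot(is(x, "HeatmapGrid"))
  x@scores
}

setMethod("show", "HeatmapGrid", function(object) {
  cat(sprintf("HeatmapGrid: %d test images x %d forests, Jaccard %.3f-%.3f\n",
              nrow(object@scores), ncol(object@scores),
              min(object@scores), max(object@scores)))
})

#' Fraction of test images whose best forest is their own grayscale group
#'
#' For each heat-map row, checks whether the column achieving the row
#' maximum lies within \code{tolBins} of the group whose interval contains
#' (or is nearest to) the test image's mean membrane gray value.
#'
#' @param grid a \linkS4class{HeatmapGrid}.
#' @param tolBins allowed group offset (default 1).
#' @return proportion in [0, 1].
#' @export
ownGroupRowmaxRate <- function(grid, tolBins = 1L) {
  stopifnot(is(grid, "HeatmapGrid"))
  iv <- grid@colIntervals
  hits <- vapply(seq_len(nrow(grid@scores)), function(t) {
    m <- grid@rowMeans[t]
    own <- which(m >= iv[, 1] & m < iv[, 2])
    if (length(own) == 0L)
      own <- which.min(pmax(iv[, 1] - m, m - iv[, 2], 0))
    best <- which.max(grid@scores[t, ])
    abs(best - own[1]) <= tolBins
  }, logical(1))
  mean(hits)
}

## ---- ablation -------------------------------------------------------------

#' Score the fusion variants on one test image
#'
#' Variants of the zoom-view fusion, all Jaccard-scored against the gold
#' mask: \code{V} thresholds the probability map at 0.5 with no cleanup
#' (plain level-2 voting); \code{VF} adds fuzzy C-means bipartition and
#' cleanup; \code{VI} runs the refinement loop with plain thresholding in
#' place of fuzzy C-means; \code{VFI} is the full pipeline (candidate R2);
#' \code{RFS1} is the full-view candidate R1; \code{final} is the better of
#' the two candidates (the choice a reviewer with the gold mask would make).
#'
#' @param image a \linkS4class{LabeledImage} with a gold mask.
#' @param zoom a \linkS4class{ZoomViewModel}.
#' @param full a \linkS4class{FullViewModel}.
#' @param featureCfg the shared \linkS4class{FeatureConfig}.
#' @param cfg a \linkS4class{RefinementConfig}.
#' @return one-row data.frame with columns V, VF, VI, VFI, RFS1, final.
#' @export
ablation <- function(image, zoom, full, featureCfg = featureConfig(),
                     cfg = refinementConfig()) {
  stopifnot(is(image, "LabeledImage"))
  gold <- gbmMask(image)
  img <- grayImage(image)
  fm <- featureMatrix(computeFeatureStack(img, featureCfg))
  d <- dim(img)
  crs <- lapply(zoom@forests, .predictMaskFromMatrix, fm = fm, dims = d)
  pm <- probabilityMap(crs)
  v <- pm >= 0.5
  vf <- morphologicalCleanup(fcmBipartition(pm, cfg@fcm), cfg@cleanup)
  vi <- iterativeRefinement(crs, cfg, consensus = "threshold")$mask
  vfi <- iterativeRefinement(crs, cfg, consensus = "fcm")$mask
  r1 <- morphologicalCleanup(.predictMaskFromMatrix(full@forest, fm, d),
                             cfg@cleanup)
  out <- data.frame(
    V = jaccard(gold, v), VF = jaccard(gold, vf), VI = jaccard(gold, vi),
    VFI = jaccard(gold, vfi), RFS1 = jaccard(gold, r1))
  out$final <- pmax(out$VFI, out$RFS1)
  out
}

#' Mean and variance per ablation variant
#'
#' @param reports data.frame of per-image ablation rows (one column per
#'   variant).
#' @return data.frame with columns variant, mean, variance (sample variance;
#'   0 for a single report).
#' @export
summarizeAblation <- function(reports) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1L)
  data.frame(
    variant = names(reports),
    mean = vapply(reports, mean, numeric(1)),
    variance = vapply(reports, function(x)
      if (length(x) > 1L) var(x) else 0, numeric(1)),
    row.names = NULL)
}
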