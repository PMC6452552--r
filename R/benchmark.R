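## A self-contained seeded benchmark: a grayscale-stratified synthetic
## dataset, both classifiers, the cross-grayscale heat map and the ablation
## table. This is the study the package's own evaluation rests on; the
## methods vignette documents the chosen problem sizes.

#' Default feature configuration of the synthetic benchmark
#'
#' A reduced family set (local mean and variance, Sobel magnitude,
#' difference of Gaussians, Gaussian blur, membrane projections, shifted
#' neighbors at scales 1, 2, 4, 8) that keeps the benchmark quick while
#' retaining both absolute-intensity channels (which make forests
#' grayscale-specific) and intensity-shift-invariant channels (which the
#' pooled full-view forest needs to generalize).
#'
#' @return a \linkS4class{FeatureConfig}.
#' @export
benchmarkFeatureConfig <- function() {
  featureConfig(
    families = c("mean", "variance", "sobel", "difference_of_gaussians",
                 "gaussian_blur", "membrane_projections", "neighbors"),
    scales = c(1, 2, 4, 8))
}

#' Run the seeded synthetic benchmark
#'
#' Generates a training set of 5 grayscale groups spanning membrane means
#' 75--145 (bins of width 14) with 3 images per group and a test set of 10
#' images (2 per group), trains the full-view forest and the zoom-view bank
#' (M = 500 samples per image, T = 25 trees, depth D = 9), computes the
#' cross-grayscale heat map, and scores the fusion ablation variants on
#' every test image.
#'
#' @param seed integer master seed; every stage derives its stream from it.
#' @param nGroups,imagesPerGroup,nTestPerGroup,samplesPerImage,nTrees,maxDepth
#'   study sizes; defaults are the benchmark conditions.
#' @param meanStart,binWidth grayscale bin layout.
#' @return list with elements \code{train}, \code{tests}, \code{full},
#'   \code{zoom}, \code{featureCfg}, \code{refinementCfg}, \code{grid}
#'   (a \linkS4class{HeatmapGrid}) and \code{ablation} (one row per test
#'   image).
#' @export
runBenchmark <- function(seed = 1L, nGroups = 5L, imagesPerGroup = 3L,
                         nTestPerGroup = 2L, samplesPerImage = 500L,
                         nTrees = 25L, maxDepth = 9L,
                         meanStart = 75, binWidth = 14) {
  fc <- benchmarkFeatureConfig()
  base <- syntheticSpec("strip", height = 128L, width = 160L,
                        gbmContrast = 35, noiseSigma = 10,
                        illuminationAmplitude = 25, clutterDensity = 1.2)
  train <- generateGroupedDataset(nGroups, imagesPerGroup,
                                  meanStart = meanStart, binWidth = binWidth,
                                  baseSpec = base, seed = deriveSeed(seed, 1L))
  testGrouped <- generateGroupedDataset(nGroups, nTestPerGroup,
                                        meanStart = meanStart,
                                        binWidth = binWidth,
                                        baseSpec = base,
                                        seed = deriveSeed(seed, 2L))
  tests <- unlist(testGrouped@images, recursive = FALSE)
  tc <- trainingConfig(nGroups = nGroups, samplesPerImage = samplesPerImage,
                       nTrees = nTrees, maxDepth = maxDepth,
                       featureConfig = fc, seed = deriveSeed(seed, 3L))
  full <- trainFullView(train, tc)
  zoom <- trainZoomView(train, tc)
  rcfg <- refinementConfig(w1 = 1, w2 = 0.3)
  grid <- heatmapGrid(zoom, tests, fc, rcfg@cleanup)
  abl <- do.call(rbind, lapply(tests, ablation, zoom = zoom, full = full,
                               featureCfg = fc, cfg = rcfg))
  list(train = train, tests = tests, full = full, zoom = zoom,
       featureCfg = fc, refinementCfg = rcfg, grid = grid, ablation = abl)
}
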