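#' @import methods
#' @importFrom stats dnorm median quantile rnorm runif sd setNames spline var
#' @importFrom utils read.delim write.table head
NULL

## ---- synthetic data -------------------------------------------------------

#' Specification of a synthetic membrane image
#'
#' Describes one synthetic transmission-electron-microscopy-like image: a
#' dark, ribbon-shaped membrane drawn over a brighter, cluttered background.
#' The membrane is laid out as a smooth random curve (an open spline for
#' \code{"strip"}, a radially perturbed closed contour for \code{"closed"},
#' or the union of both for \code{"compound"}) and dilated to a smoothly
#' varying width.
#'
#' @slot morphology one of \code{"strip"}, \code{"closed"}, \code{"compound"}.
#' @slot height,width frame size in pixels.
#' @slot gbmMean target mean gray value of membrane pixels (0--255).
#' @slot gbmContrast absolute gray-level difference between the membrane mean
#'   and the background mean; the membrane is drawn darker by default, the
#'   usual appearance of electron-dense material.
#' @slot membraneDarker logical; set \code{FALSE} to invert the contrast sign.
#' @slot ribbonWidthRange length-2 numeric, min/max membrane half-width (px).
#' @slot noiseSigma std. dev. of additive Gaussian noise (gray levels).
#' @slot illuminationAmplitude peak-to-peak linear shading across the frame
#'   (gray levels), applied to the background.
#' @slot clutterDensity expected number of organelle-like background blobs
#'   per 1e4 pixels.
#' @slot seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @name SyntheticSpec-class
#' @rdname SyntheticSpec-class
#' @exportClass SyntheticSpec
setClass("SyntheticSpec", representation(
  morphology = "character",
  height = "integer",
  width = "integer",
  gbmMean = "numeric",
  gbmContrast = "numeric",
  membraneDarker = "logical",
  ribbonWidthRange = "numeric",
  noiseSigma = "numeric",
  illuminationAmplitude = "numeric",
  clutterDensity = "numeric",
  seed = "integer"
))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (!object@morphology %in% c("strip", "closed", "compound"))
    msg <- c(msg, "morphology must be 'strip', 'closed' or 'compound'")
  if (object@height < 16L || object@width < 16L)
    msg <- c(msg, "frame must be at least 16x16 pixels")
  if (object@gbmMean < 0 || object@gbmMean > 255)
    msg <- c(msg, "gbmMean must lie in [0, 255]")
  if (object@gbmContrast < 0)
    msg <- c(msg, "gbmContrast must be non-negative")
  if (length(object@ribbonWidthRange) != 2L ||
      any(object@ribbonWidthRange < 1) ||
      diff(object@ribbonWidthRange) < 0)
    msg <- c(msg, "ribbonWidthRange must be increasing and >= 1 pixel")
  if (object@noiseSigma < 0 || object@illuminationAmplitude < 0 ||
      object@clutterDensity < 0)
    msg <- c(msg, "noise, illumination and clutter parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' An image paired with its ground-truth membrane mask
#'
#' The universal currency of the pipeline: a 2-D 8-bit-range gray image
#' (numeric matrix, values in [0, 255], rows = image rows) together with a
#' logical mask of the same shape marking membrane pixels.
#'
#' @slot image numeric matrix in [0, 255].
#' @slot mask logical matrix, same dimensions as \code{image}.
#' @slot provenance character scalar: a file path or a description of the
#'   generating spec.
#' @name LabeledImage-class
#' @rdname LabeledImage-class
#' @exportClass LabeledImage
setClass("LabeledImage", representation(
  image = "matrix",
  mask = "matrix",
  provenance = "character"
))

setValidity("LabeledImage", function(object) {
  msg <- character()
  if (!identical(dim(object@image), dim(object@mask)))
    msg <- c(msg, "image and mask must have identical dimensions")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be a logical matrix")
  if (!is.numeric(object@image))
    msg <- c(msg, "image must be numeric")
  else if (any(object@image < 0 | object@image > 255))
    msg <- c(msg, "image values must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

## ---- grayscale grouping ---------------------------------------------------

#' Contiguous grayscale bins for training-image stratification
#'
#' N half-open, contiguous intervals of mean membrane gray value. The
#' defaults reproduce 37 bins of width 2 starting at 73.5 (the first bin is
#' [73.5, 75.5) and the last [145.5, 147.5)).
#'
#' @slot intervals numeric matrix with columns \code{lo}, \code{hi}; row g is
#'   group g's half-open interval [lo, hi).
#' @name GrayscaleGroups-class
#' @rdname GrayscaleGroups-class
#' @exportClass GrayscaleGroups
setClass("GrayscaleGroups", representation(intervals = "matrix"))

setValidity("GrayscaleGroups", function(object) {
  iv <- object@intervals
  msg <- character()
  if (ncol(iv) != 2L || nrow(iv) < 1L)
    msg <- c(msg, "intervals must be an n x 2 matrix")
  else {
    if (any(iv[, 2] <= iv[, 1]))
      msg <- c(msg, "each interval must have hi > lo")
    if (nrow(iv) > 1L && any(abs(iv[-nrow(iv), 2] - iv[-1, 1]) > 1e-9))
      msg <- c(msg, "consecutive intervals must be contiguous")
  }
  if (length(msg)) msg else TRUE
})

#' Training images stratified by mean membrane gray value
#'
#' @slot groups a \linkS4class{GrayscaleGroups} object.
#' @slot images a list of length \code{nGroups(groups)}; element g is a list
#'   of \linkS4class{LabeledImage} objects whose mask-mean gray values fall
#'   in group g's interval.
#' @name GroupedTrainingSet-class
#' @rdname GroupedTrainingSet-class
#' @exportClass GroupedTrainingSet
setClass("GroupedTrainingSet", representation(
  groups = "GrayscaleGroups",
  images = "list"
))

setValidity("GroupedTrainingSet", function(object) {
  iv <- object@groups@intervals
  if (length(object@images) != nrow(iv))
    return("images list length must equal the number of groups")
  for (g in seq_along(object@images)) {
    for (im in object@images[[g]]) {
      if (!is(im, "LabeledImage"))
        return("every element must be a LabeledImage")
      m <- mean(im@image[im@mask])
      if (m < iv[g, 1] - 1e-9 || m >= iv[g, 2] + 1e-9)
        return(sprintf("image mask-mean %.2f outside group %d interval", m, g))
    }
  }
  TRUE
})

## ---- features -------------------------------------------------------------

#' Configuration of the per-pixel feature stack
#'
#' Selects which feature families are computed and at which scales. The
#' fourteen default families follow the trainable-segmentation convention:
#' local gray statistics (mean, minimum, maximum, median, variance), boundary
#' responses (Sobel magnitude, Hessian eigenvalues, difference of Gaussians),
#' texture (Gaussian blur, local entropy, Kuwahara), and membrane projections,
#' Lipschitz top-hat and raw shifted neighbors. Anisotropic diffusion and
#' bilateral filtering are implemented but disabled by default (diffusion is
#' costly and tends to blur away the thin target structure).
#'
#' @slot families ordered character vector of enabled family names.
#' @slot scales strictly increasing positive radii/sigmas (pixels).
#' @slot membraneSize side length of the membrane-projection line kernel (px).
#' @slot membraneOrientations number of kernel orientations over 180 degrees.
#' @slot neighborOffsets integer matrix with columns (row shift, col shift).
#' @slot lipschitzSlope slope of the Lipschitz cover (gray levels / pixel).
#' @slot entropyBins number of histogram bins for the local entropy filter.
#' @name FeatureConfig-class
#' @rdname FeatureConfig-class
#' @exportClass FeatureConfig
setClass("FeatureConfig", representation(
  families = "character",
  scales = "numeric",
  membraneSize = "integer",
  membraneOrientations = "integer",
  neighborOffsets = "matrix",
  lipschitzSlope = "numeric",
  entropyBins = "integer"
))

.featureRegistry <- c(
  "mean", "minimum", "maximum", "median", "variance",
  "sobel", "hessian", "difference_of_gaussians",
  "gaussian_blur", "entropy", "kuwahara",
  "membrane_projections", "lipschitz", "neighbors",
  "anisotropic_diffusion", "bilateral"
)

setValidity("FeatureConfig", function(object) {
  msg <- character()
  if (length(object@families) == 0L)
    msg <- c(msg, "at least one feature family must be enabled")
  unknown <- setdiff(object@families, .featureRegistry)
  if (length(unknown))
    msg <- c(msg, paste("unknown feature families:",
                        paste(unknown, collapse = ", ")))
  if (anyDuplicated(object@families))
    msg <- c(msg, "families must not repeat")
  if (length(object@scales) == 0L || any(object@scales <= 0) ||
      is.unsorted(object@scales, strictly = TRUE))
    msg <- c(msg, "scales must be strictly increasing and positive")
  if (object@membraneSize %% 2L == 0L)
    msg <- c(msg, "membraneSize must be odd")
  if (ncol(object@neighborOffsets) != 2L)
    msg <- c(msg, "neighborOffsets must have two columns")
  if (object@entropyBins < 2L)
    msg <- c(msg, "entropyBins must be at least 2")
  if (length(msg)) msg else TRUE
})

#' A computed per-pixel feature stack
#'
#' @slot values numeric array height x width x F, finite everywhere.
#' @slot channelNames character vector of length F (family + scale).
#' @name FeatureStack-class
#' @rdname FeatureStack-class
#' @exportClass FeatureStack
setClass("FeatureStack", representation(
  values = "array",
  channelNames = "character"
))

setValidity("FeatureStack", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-D array")
  else if (dim(object@values)[3] != length(object@channelNames))
    msg <- c(msg, "third dimension must match channelNames length")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "feature values must be finite")
  if (length(msg)) msg else TRUE
})

## ---- training -------------------------------------------------------------

#' Training hyperparameters for the two-level ensemble
#'
#' @slot nGroups number of grayscale groups N (default 37).
#' @slot samplesPerImage pixels sampled per training image M (default 2000).
#' @slot nTrees trees per forest T (default 100).
#' @slot maxDepth maximum tree depth D (default 9).
#' @slot featureConfig the \linkS4class{FeatureConfig} shared by all forests.
#' @slot balanceClasses draw half the samples from each class (default TRUE).
#' @slot seed integer master seed.
#' @name TrainingConfig-class
#' @rdname TrainingConfig-class
#' @exportClass TrainingConfig
setClass("TrainingConfig", representation(
  nGroups = "integer",
  samplesPerImage = "integer",
  nTrees = "integer",
  maxDepth = "integer",
  featureConfig = "FeatureConfig",
  balanceClasses = "logical",
  seed = "integer"
))

setValidity("TrainingConfig", function(object) {
  if (object@nGroups < 1L || object@samplesPerImage < 1L ||
      object@nTrees < 1L || object@maxDepth < 1L)
    "nGroups, samplesPerImage, nTrees and maxDepth must all be >= 1"
  else TRUE
})

#' Pixel samples drawn from a labelled image
#'
#' Feature vectors and class labels for a set of sampled pixels; the matrix
#' representation keeps sampling and training fast while each row remains one
#' (feature vector, label, origin) record.
#'
#' @slot features numeric matrix n x F with channel names as column names.
#' @slot labels factor with levels \code{background}, \code{GBM}.
#' @slot origin data.frame with columns \code{image}, \code{row}, \code{col}.
#' @name PixelSamples-class
#' @rdname PixelSamples-class
#' @exportClass PixelSamples
setClass("PixelSamples", representation(
  features = "matrix",
  labels = "factor",
  origin = "data.frame"
))

setValidity("PixelSamples", function(object) {
  msg <- character()
  if (nrow(object@features) != length(object@labels))
    msg <- c(msg, "features and labels must have matching length")
  if (!identical(levels(object@labels), c("background", "GBM")))
    msg <- c(msg, "labels must be a factor with levels background, GBM")
  if (length(msg)) msg else TRUE
})

#' A single bagged decision-tree ensemble
#'
#' Wraps a trained forest together with the ordered feature channel names it
#' was fitted on (predictions are refused when the feature configuration at
#' test time yields different channels) and training metadata.
#'
#' @slot forest the underlying \code{ranger} model.
#' @slot channelNames ordered feature channel names.
#' @slot meta list: nTrees, maxDepth, seed, split rule, group provenance.
#' @name ForestModel-class
#' @rdname ForestModel-class
#' @exportClass ForestModel
setClass("ForestModel", representation(
  forest = "ANY",
  channelNames = "character",
  meta = "list"
))

#' The full-view classifier: one forest over pooled groups
#'
#' @slot forest a \linkS4class{ForestModel} trained on M x N pixels pooled
#'   simultaneously from one image of each grayscale group.
#' @slot provenance list: selected image index per group, pooled sample count.
#' @name FullViewModel-class
#' @rdname FullViewModel-class
#' @exportClass FullViewModel
setClass("FullViewModel", representation(
  forest = "ForestModel",
  provenance = "list"
))

#' The zoom-view classifier bank: one forest per grayscale group
#'
#' @slot forests list of \linkS4class{ForestModel}, index-aligned with groups.
#' @slot groups the \linkS4class{GrayscaleGroups} the bank was trained on.
#' @slot provenance list: selected image index per group.
#' @name ZoomViewModel-class
#' @rdname ZoomViewModel-class
#' @exportClass ZoomViewModel
setClass("ZoomViewModel", representation(
  forests = "list",
  groups = "GrayscaleGroups",
  provenance = "list"
))

setValidity("ZoomViewModel", function(object) {
  if (length(object@forests) != nrow(object@groups@intervals))
    return("one forest per grayscale group is required")
  if (!all(vapply(object@forests, is, logical(1), "ForestModel")))
    return("forests must all be ForestModel objects")
  TRUE
})

## ---- segmentation ---------------------------------------------------------

#' Fuzzy C-means settings for probability-map bipartition
#'
#' @slot fuzzifier exponent m > 1 (default 2).
#' @slot tol convergence threshold on the membership/centroid update.
#' @slot maxIters iteration cap.
#' @slot seed used only to break degenerate ties.
#' @name FcmConfig-class
#' @rdname FcmConfig-class
#' @exportClass FcmConfig
setClass("FcmConfig", representation(
  fuzzifier = "numeric",
  tol = "numeric",
  maxIters = "integer",
  seed = "integer"
))

setValidity("FcmConfig", function(object) {
  if (object@fuzzifier <= 1) "fuzzifier must be > 1" else TRUE
})

#' Morphological cleanup settings
#'
#' @slot minComponentArea connected components (8-connectivity) smaller than
#'   this many pixels are removed.
#' @slot openingRadius disc radius of the binary opening; 0 disables it.
#' @name CleanupConfig-class
#' @rdname CleanupConfig-class
#' @exportClass CleanupConfig
setClass("CleanupConfig", representation(
  minComponentArea = "integer",
  openingRadius = "integer"
))

#' Iterative-refinement settings
#'
#' @slot w1 initial retention fraction in (0, 1]; 1 keeps all coarse results.
#' @slot w2 Jaccard similarity cutoff in [0, 1) for retaining a coarse result
#'   against the current consensus.
#' @slot maxIters refinement iteration cap.
#' @slot fcm an \linkS4class{FcmConfig}.
#' @slot cleanup a \linkS4class{CleanupConfig}.
#' @name RefinementConfig-class
#' @rdname RefinementConfig-class
#' @exportClass RefinementConfig
setClass("RefinementConfig", representation(
  w1 = "numeric",
  w2 = "numeric",
  maxIters = "integer",
  fcm = "FcmConfig",
  cleanup = "CleanupConfig"
))

setValidity("RefinementConfig", function(object) {
  msg <- character()
  if (object@w1 <= 0 || object@w1 > 1)
    msg <- c(msg, "w1 must lie in (0, 1]")
  if (object@w2 < 0 || object@w2 >= 1)
    msg <- c(msg, "w2 must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Result of segmenting one test image
#'
#' Holds both candidate segmentations: R1 from the full-view forest and R2
#' from the zoom-view bank after probability-map fusion, fuzzy C-means
#' bipartition, cleanup and iterative refinement — together with the
#' intermediate artifacts and, when a gold mask was supplied, Jaccard scores.
#'
#' @slot R1,R2 logical candidate masks.
#' @slot coarseResults list of the N zoom-view coarse masks.
#' @slot probabilityMap numeric matrix of per-pixel membrane frequencies.
#' @slot retainedIndices indices of coarse results kept by the refinement.
#' @slot jaccardR1,jaccardR2 numeric scores (NA when no gold mask given).
#' @slot selected \code{"R1"}, \code{"R2"} or \code{"unset"}; the final choice
#'   is a human decision by default.
#' @name SegmentationResult-class
#' @rdname SegmentationResult-class
#' @exportClass SegmentationResult
setClass("SegmentationResult", representation(
  R1 = "matrix",
  R2 = "matrix",
  coarseResults = "list",
  probabilityMap = "matrix",
  retainedIndices = "integer",
  jaccardR1 = "numeric",
  jaccardR2 = "numeric",
  selected = "character"
))

## ---- evaluation -----------------------------------------------------------

#' Cross-grayscale Jaccard heat map
#'
#' Row t, column g holds the Jaccard score of zoom-view forest g on test
#' image t; rows are ordered by the test image's mean membrane gray value so
#' the diagonal band visualises grayscale specificity.
#'
#' @slot scores numeric matrix (tests x groups).
#' @slot rowMeans mean membrane gray value per test image (row order).
#' @slot colIntervals the group intervals (groups x 2).
#' @name HeatmapGrid-class
#' @rdname HeatmapGrid-class
#' @exportClass HeatmapGrid
setClass("HeatmapGrid", representation(
  scores = "matrix",
  rowMeans = "numeric",
  colIntervals = "matrix"
))
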