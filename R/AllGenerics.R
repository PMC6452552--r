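#' @rdname channelNames
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname nGroups
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' @rdname groupIntervals
#' @export
setGeneric("groupIntervals", function(x) standardGeneric("groupIntervals"))

#' @rdname classifyImage
#' @export
setGeneric("classifyImage",
           function(model, image, cfg) standardGeneric("classifyImage"))

#' @rdname probabilityMap
#' @export
setGeneric("probabilityMap", function(x) standardGeneric("probabilityMap"))

#' @rdname SegmentationResult-accessors
#' @export
setGeneric("candidateR1", function(x) standardGeneric("candidateR1"))

#' @rdname SegmentationResult-accessors
#' @export
setGeneric("candidateR2", function(x) standardGeneric("candidateR2"))

#' @rdname SegmentationResult-accessors
#' @export
setGeneric("retainedIndices", function(x) standardGeneric("retainedIndices"))

#' @rdname SegmentationResult-accessors
#' @export
setGeneric("coarseMasks", function(x) standardGeneric("coarseMasks"))

#' @rdname LabeledImage-accessors
#' @export
setGeneric("grayImage", function(x) standardGeneric("grayImage"))

#' @rdname LabeledImage-accessors
#' @export
setGeneric("gbmMask", function(x) standardGeneric("gbmMask"))

#' @rdname LabeledImage-accessors
#' @export
setGeneric("maskMean", function(x) standardGeneric("maskMean"))
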