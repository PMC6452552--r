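## File I/O: 8-bit grayscale images and 0/255 binary masks (PNG/TIFF),
## versioned model archives, dataset manifests and run configs.

.MODEL_FORMAT_VERSION <- "rfstacks-models-1"

#' Read a grayscale image
#'
#' Accepts 8-bit grayscale PNG or TIFF. RGB inputs are collapsed by
#' luminosity (0.2126 R + 0.7152 G + 0.0722 B) with a warning; 16-bit TIFF
#' inputs are linearly rescaled to the 8-bit range with a warning.
#'
#' @param path file path.
#' @return numeric matrix with values in [0, 255], rows = image rows.
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  is16 <- FALSE
  if (grepl("\\.tiff?$", path, ignore.case = TRUE) &&
      requireNamespace("tiff", quietly = TRUE)) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (max(raw) > 255) is16 <- TRUE
    a <- if (is16) raw / 65535 else raw / 255
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))
  }
  if (length(dim(a)) == 3L) {
    warning("multi-channel image collapsed to grayscale by luminosity")
    wts <- c(0.2126, 0.7152, 0.0722, rep(0, max(0, dim(a)[3] - 3L)))
    wts <- wts[seq_len(dim(a)[3])] / sum(wts[seq_len(dim(a)[3])])
    a <- apply(sweep(a, 3L, wts, `*`), c(1, 2), sum)
  }
  if (is16) warning("16-bit image rescaled to the 8-bit range")
  img <- a * 255
  ## EBImage stores (x, y); tiff::readTIFF stores (row, col)
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE) ||
      !requireNamespace("tiff", quietly = TRUE))
    img <- t(img)
  pmin(pmax(img, 0), 255)
}

#' Write a grayscale image
#'
#' @param image numeric matrix in [0, 255].
#' @param path destination PNG or TIFF path.
#' @return the path, invisibly.
#' @export
writeGrayImage <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(image) / 255), path)
  invisible(path)
}

#' Read a binary mask
#'
#' Any nonzero pixel is treated as foreground; a warning is issued when the
#' file contains values other than 0 and 255.
#'
#' @param path file path (PNG or TIFF written with 0/255 values).
#' @return logical matrix.
#' @export
readMask <- function(path) {
  img <- suppressWarnings(readGrayImage(path))
  vals <- unique(round(as.vector(img)))
  if (!all(vals %in% c(0, 255)))
    warning("mask contains values other than {0, 255}; nonzero read as TRUE")
  img > 0
}

#' Write a binary mask as a 0/255 image
#'
#' @param mask logical matrix.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  assertBinaryMask(mask)
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' Save trained models to a versioned archive
#'
#' @param full a \linkS4class{FullViewModel}.
#' @param zoom a \linkS4class{ZoomViewModel}.
#' @param path destination file (.rds).
#' @param featureCfg optional \linkS4class{FeatureConfig} stored alongside
#'   so a predictor can verify channel compatibility.
#' @return the path, invisibly.
#' @export
saveModels <- function(full, zoom, path, featureCfg = NULL) {
  stopifnot(is(full, "FullViewModel"), is(zoom, "ZoomViewModel"))
  saveRDS(list(format = .MODEL_FORMAT_VERSION, full = full, zoom = zoom,
               featureConfig = featureCfg), path)
  invisible(path)
}

#' Load a model archive
#'
#' Rejects unreadable archives and mismatched format versions; loaded models
#' predict bit-identically to the saved ones.
#'
#' @param path archive path.
#' @return list with elements \code{full}, \code{zoom}, \code{featureConfig}.
#' @export
loadModels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable model archive: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, .MODEL_FORMAT_VERSION))
    stop(sprintf("model archive format mismatch: expected '%s', found '%s'",
                 .MODEL_FORMAT_VERSION,
                 if (is.list(obj)) as.character(obj$format %||% "<none>")
                 else "<not an archive>"))
  obj[c("full", "zoom", "featureConfig")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a grouped dataset to disk
#'
#' Writes each image and mask as PNG and a tab-delimited manifest (path,
#' group index, realized membrane mean, provenance) alongside.
#'
#' @param dataset a \linkS4class{GroupedTrainingSet}.
#' @param dir destination directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "GroupedTrainingSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (g in seq_len(nGroups(dataset))) {
    for (i in seq_along(dataset@images[[g]])) {
      li <- dataset@images[[g]][[i]]
      base <- sprintf("g%02d_i%02d", g, i)
      writeGrayImage(grayImage(li), file.path(dir, paste0(base, ".png")))
      writeMask(gbmMask(li), file.path(dir, paste0(base, "_mask.png")))
      rows[[length(rows) + 1L]] <- data.frame(
        image = paste0(base, ".png"), mask = paste0(base, "_mask.png"),
        group = g, gbm_mean = maskMean(li), provenance = li@provenance)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Read a grouped dataset written by \code{writeDataset}
#'
#' @param dir dataset directory containing \code{manifest.tsv}.
#' @param groups optional \linkS4class{GrayscaleGroups}; by default bins are
#'   rebuilt from the manifest's group indices and realized means.
#' @return a \linkS4class{GroupedTrainingSet}.
#' @export
readDataset <- function(dir, groups = NULL) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop("manifest not found: ", mpath)
  man <- read.delim(mpath)
  ng <- max(man$group)
  if (is.null(groups)) {
    ## reconstruct contiguous bins covering the observed means
    span <- range(man$gbm_mean)
    width <- (diff(span) + 2) / ng
    groups <- grayscaleGroups(ng, span[1] - 1, width)
  }
  images <- vector("list", ng)
  for (k in seq_len(nrow(man))) {
    g <- man$group[k]
    li <- labeledImage(readGrayImage(file.path(dir, man$image[k])),
                       readMask(file.path(dir, man$mask[k])),
                       provenance = man$image[k])
    images[[g]] <- c(images[[g]], li)
  }
  new("GroupedTrainingSet", groups = groups, images = images)
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level sections: \code{training} (nGroups,
#' samplesPerImage, nTrees, maxDepth, balanceClasses, seed), \code{feature}
#' (families, scales, ...), \code{refinement} (w1, w2, maxIters,
#' minComponentArea, openingRadius). Missing fields fall back to defaults,
#' so a run is fully replayable from its persisted config and seed.
#'
#' @param path YAML file path.
#' @return list with elements \code{training}, \code{feature},
#'   \code{refinement}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  fc <- do.call(featureConfig, y$feature %||% list())
  trArgs <- y$training %||% list()
  trArgs$featureConfig <- fc
  tc <- do.call(trainingConfig, trArgs)
  rf <- y$refinement %||% list()
  rc <- refinementConfig(
    w1 = rf$w1 %||% 1, w2 = rf$w2 %||% 0.3,
    maxIters = rf$maxIters %||% 10L,
    cleanup = cleanupConfig(
      minComponentArea = rf$minComponentArea %||% 50L,
      openingRadius = rf$openingRadius %||% 1L))
  list(training = tc, feature = fc, refinement = rc)
}

#' Write a replay manifest for a run
#'
#' @param path destination YAML path.
#' @param config named list of the run's parameters and seeds.
#' @return the path, invisibly.
#' @export
writeRunManifest <- function(path, config) {
  config$software <- paste0("RFStacks ",
                            as.character(utils::packageVersion("RFStacks")))
  yaml::write_yaml(config, path)
  invisible(path)
}
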