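## Synthetic TEM-like membrane images with exact ground truth.
##
## The generator emulates what makes basement-membrane segmentation hard:
## a thin dark ribbon of smoothly varying width and orientation, low
## foreground/background contrast, organelle-like clutter whose intensity is
## deliberately close to the membrane's, an illumination ramp, and additive
## noise. It does not attempt physically realistic TEM image formation.

#' Create a synthetic membrane image specification
#'
#' @param morphology \code{"strip"} (open curve crossing the frame),
#'   \code{"closed"} (perturbed closed contour) or \code{"compound"} (union
#'   of both).
#' @param height,width frame size in pixels; the default follows typical
#'   non-square TEM crops.
#' @param gbmMean target mean gray value of membrane pixels (0--255).
#' @param gbmContrast absolute difference between membrane and background
#'   means (gray levels).
#' @param membraneDarker if TRUE (default) the membrane is darker than the
#'   background, the usual appearance of electron-dense material in TEM.
#' @param ribbonWidthRange length-2 numeric: min/max membrane half-width (px).
#' @param noiseSigma additive Gaussian noise standard deviation (gray levels).
#' @param illuminationAmplitude peak-to-peak linear shading over the
#'   background (gray levels).
#' @param clutterDensity expected organelle-like blobs per 1e4 pixels; blob
#'   intensities are sampled within 15 gray levels of the membrane mean so
#'   that clutter is confusable with the target, as foot processes and
#'   endothelium are in real images.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @examples
#' sp <- syntheticSpec("strip", height = 64, width = 96, seed = 1)
#' li <- generateMembrane(sp)
#' dim(grayImage(li))
#' @export
syntheticSpec <- function(morphology = c("strip", "closed", "compound"),
                          height = 217L, width = 307L,
                          gbmMean = 110, gbmContrast = 35,
                          membraneDarker = TRUE,
                          ribbonWidthRange = c(3, 7),
                          noiseSigma = 10, illuminationAmplitude = 25,
                          clutterDensity = 1.2, seed = 1L) {
  new("SyntheticSpec",
      morphology = match.arg(morphology),
      height = as.integer(height), width = as.integer(width),
      gbmMean = gbmMean, gbmContrast = gbmContrast,
      membraneDarker = membraneDarker,
      ribbonWidthRange = as.numeric(ribbonWidthRange),
      noiseSigma = noiseSigma,
      illuminationAmplitude = illuminationAmplitude,
      clutterDensity = clutterDensity, seed = as.integer(seed))
}

#' Construct a labelled image
#'
#' @param image numeric matrix with values in [0, 255].
#' @param mask logical matrix of the same shape (TRUE = membrane).
#' @param provenance character description (spec summary or file path).
#' @return a \linkS4class{LabeledImage}.
#' @export
labeledImage <- function(image, mask, provenance = "in-memory") {
  new("LabeledImage", image = image, mask = mask, provenance = provenance)
}

#' @describeIn labeledImage the gray image matrix.
#' @param x a \linkS4class{LabeledImage}.
#' @name LabeledImage-accessors
#' @aliases grayImage gbmMask maskMean
#' @export
setMethod("grayImage", "LabeledImage", function(x) x@image)

#' @rdname LabeledImage-accessors
#' @export
setMethod("gbmMask", "LabeledImage", function(x) x@mask)

#' @rdname LabeledImage-accessors
#' @export
setMethod("maskMean", "LabeledImage", function(x) {
  if (!any(x@mask))
    stop("mask is empty: mean membrane gray value is undefined")
  mean(x@image[x@mask])
})

setMethod("show", "LabeledImage", function(object) {
  cat(sprintf("LabeledImage %dx%d, %d membrane px (%.1f%%), provenance: %s\n",
              nrow(object@image), ncol(object@image), sum(object@mask),
              100 * mean(object@mask), object@provenance))
})

## ---- curve geometry -------------------------------------------------------

## Open spline crossing the frame left-to-right through jittered control
## points; returns dense (row, col) samples.
.stripCurve <- function(h, w, margin) {
  nc <- 6L
  cx <- seq(1, w, length.out = nc)
  cy <- runif(nc, margin, h - margin)
  s <- spline(cx, cy, n = max(2L * w, 64L), method = "natural")
  cbind(row = s$y, col = s$x)
}

## Radially perturbed ellipse; low-order harmonics keep the contour smooth.
.closedCurve <- function(h, w, margin) {
  cy <- h / 2 + runif(1, -0.06, 0.06) * h
  cx <- w / 2 + runif(1, -0.06, 0.06) * w
  r0 <- 0.32 * min(h, w) * runif(1, 0.85, 1.05)
  aspect <- runif(1, 0.75, 1.3)
  k <- 2:4
  amp <- runif(3, 0, 0.12)
  phs <- runif(3, 0, 2 * pi)
  theta <- seq(0, 2 * pi, length.out = 720L)
  pert <- 1 + as.vector(cos(outer(theta, k) + rep(phs, each = 720L)) %*% amp)
  cbind(row = cy + r0 * pert * sin(theta),
        col = cx + r0 * aspect * pert * cos(theta))
}

## Smoothly varying half-width along the curve parameter.
.widthProfile <- function(npts, rng) {
  nc <- 5L
  cw <- runif(nc, rng[1], rng[2])
  s <- spline(seq(0, 1, length.out = nc), cw, n = npts, method = "natural")
  pmin(pmax(s$y, rng[1]), rng[2])
}

## Rasterise a ribbon: stamp a disc of the local half-width at each curve
## sample. Returns a logical mask.
.stampRibbon <- function(h, w, pts, widths) {
  mask <- matrix(FALSE, h, w)
  radii <- round(widths * 2) / 2
  offsets <- lapply(
    setNames(nm = unique(radii)),
    function(r) {
      ri <- as.integer(ceiling(r))
      d <- seq(-ri, ri)
      sel <- outer(d^2, d^2, "+") <= r^2
      cbind(dr = rep(d, times = length(d))[as.vector(sel)],
            dc = rep(d, each = length(d))[as.vector(sel)])
    })
  for (i in seq_len(nrow(pts))) {
    off <- offsets[[as.character(radii[i])]]
    rr <- round(pts[i, 1]) + off[, 1]
    cc <- round(pts[i, 2]) + off[, 2]
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

.curveFits <- function(pts, h, w, margin) {
  all(pts[, 1] >= margin & pts[, 1] <= h - margin &
      pts[, 2] >= 1 & pts[, 2] <= w)
}

## ---- generator ------------------------------------------------------------

#' Generate a synthetic membrane image with exact ground truth
#'
#' Draws the membrane ribbon, paints membrane pixels at the target mean gray
#' value, fills the background at \code{gbmMean +/- gbmContrast} (sign per
#' \code{membraneDarker}), adds clutter blobs and an illumination ramp to the
#' background, applies Gaussian noise last, and clips to [0, 255]. Before
#' noise, the mean gray value over membrane pixels equals \code{gbmMean}
#' exactly. Degenerate geometry (a curve that does not fit the frame) is
#' retried with fresh jitter a bounded number of times.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return a \linkS4class{LabeledImage}; identical spec + seed gives
#'   bit-identical output.
#' @export
generateMembrane <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, .generateMembraneImpl(spec))
}

.generateMembraneImpl <- function(spec) {
  h <- spec@height; w <- spec@width
  wmax <- spec@ribbonWidthRange[2]
  margin <- wmax + 2

  drawCurves <- function() {
    switch(spec@morphology,
      strip = list(.stripCurve(h, w, margin)),
      closed = list(.closedCurve(h, w, margin)),
      compound = list(.closedCurve(h, w, margin),
                      .stripCurve(h, w, max(2, wmax))))
  }
  curves <- NULL
  for (attempt in seq_len(25L)) {
    cand <- drawCurves()
    if (all(vapply(cand, .curveFits, logical(1), h, w,
                   if (spec@morphology == "strip") margin else wmax + 1))) {
      curves <- cand
      break
    }
  }
  if (is.null(curves))
    stop("degenerate geometry: membrane curve does not fit the frame")

  mask <- matrix(FALSE, h, w)
  for (pts in curves) {
    widths <- .widthProfile(nrow(pts), spec@ribbonWidthRange)
    mask <- mask | .stampRibbon(h, w, pts, widths)
  }

  sign <- if (spec@membraneDarker) 1 else -1
  bgMean <- min(max(spec@gbmMean + sign * spec@gbmContrast, 0), 255)
  img <- matrix(bgMean, h, w)

  ## illumination ramp: zero-mean linear shading, background only
  if (spec@illuminationAmplitude > 0) {
    phi <- runif(1, 0, 2 * pi)
    u <- outer((seq_len(h) - (h + 1) / 2) / h * sin(phi),
               (seq_len(w) - (w + 1) / 2) / w * cos(phi), "+")
    rng <- range(u)
    if (diff(rng) > 0) {
      ramp <- spec@illuminationAmplitude * ((u - rng[1]) / diff(rng) - 0.5)
      img <- img + ramp
    }
  }

  ## organelle-like clutter: elliptical blobs confusable with the membrane
  nBlob <- stats::rpois(1, spec@clutterDensity * h * w / 1e4)
  for (b in seq_len(nBlob)) {
    bc <- c(runif(1, 1, h), runif(1, 1, w))
    ax <- runif(2, 2, 9)
    ang <- runif(1, 0, pi)
    val <- spec@gbmMean + runif(1, -15, 15)
    ri <- max(1, floor(bc[1] - max(ax))):min(h, ceiling(bc[1] + max(ax)))
    ci <- max(1, floor(bc[2] - max(ax))):min(w, ceiling(bc[2] + max(ax)))
    dy <- outer(ri - bc[1], rep(1, length(ci)))
    dx <- outer(rep(1, length(ri)), ci - bc[2])
    u <- dy * cos(ang) + dx * sin(ang)
    v <- -dy * sin(ang) + dx * cos(ang)
    inside <- (u / ax[1])^2 + (v / ax[2])^2 <= 1
    sub <- img[ri, ci, drop = FALSE]
    sub[inside] <- val
    img[ri, ci] <- sub
  }

  ## membrane painted last among structural layers: exact target mean
  img[mask] <- spec@gbmMean

  if (spec@noiseSigma > 0)
    img <- img + matrix(rnorm(h * w, 0, spec@noiseSigma), h, w)
  img <- pmin(pmax(img, 0), 255)

  labeledImage(img, mask,
               sprintf("synthetic %s gbmMean=%.1f seed=%d",
                       spec@morphology, spec@gbmMean, spec@seed))
}

## ---- grouped dataset ------------------------------------------------------

#' Construct contiguous grayscale bins
#'
#' @param n number of groups (default 37).
#' @param start lower bound of the first bin (default 73.5 gray levels).
#' @param width bin width (default 2 gray levels); group g covers the
#'   half-open interval [start + (g-1) width, start + g width).
#' @return a \linkS4class{GrayscaleGroups}.
#' @examples
#' gg <- grayscaleGroups()          # 37 bins: [73.5,75.5) ... [145.5,147.5)
#' groupIntervals(gg)[c(1, 37), ]
#' @export
grayscaleGroups <- function(n = 37L, start = 73.5, width = 2) {
  lo <- start + (seq_len(n) - 1) * width
  new("GrayscaleGroups",
      intervals = cbind(lo = lo, hi = lo + width))
}

#' @rdname nGroups
#' @param x a grouping-aware object.
#' @export
setMethod("nGroups", "GrayscaleGroups", function(x) nrow(x@intervals))

#' @rdname groupIntervals
#' @param x a grouping-aware object.
#' @export
setMethod("groupIntervals", "GrayscaleGroups", function(x) x@intervals)

setMethod("show", "GrayscaleGroups", function(object) {
  iv <- object@intervals
  cat(sprintf("GrayscaleGroups: %d contiguous bins, [%.1f, %.1f) ... [%.1f, %.1f)\n",
              nrow(iv), iv[1, 1], iv[1, 2], iv[nrow(iv), 1], iv[nrow(iv), 2]))
})

#' Generate a grayscale-stratified synthetic training set
#'
#' For group g, each image's target membrane mean is drawn uniformly from the
#' group's bin; the image is regenerated with fresh jitter until its realized
#' mask-mean gray value falls inside the bin (additive noise can push a draw
#' near a bin edge across it). Morphologies cycle through strip, closed and
#' compound to emulate the variety of clinical material.
#'
#' @param nGroups number of grayscale groups.
#' @param imagesPerGroup images generated per group.
#' @param meanStart lower bound of the first bin (gray levels).
#' @param binWidth bin width (gray levels).
#' @param baseSpec a \linkS4class{SyntheticSpec} supplying all non-intensity
#'   parameters (frame size, contrast, noise, clutter, ...).
#' @param seed integer master seed; per-image seeds are derived from it.
#' @return a \linkS4class{GroupedTrainingSet}.
#' @export
generateGroupedDataset <- function(nGroups, imagesPerGroup,
                                   meanStart = 73.5, binWidth = 2,
                                   baseSpec = syntheticSpec(),
                                   seed = 1L) {
  stopifnot(nGroups >= 1L, imagesPerGroup >= 1L)
  groups <- grayscaleGroups(nGroups, meanStart, binWidth)
  iv <- groupIntervals(groups)
  morphs <- c("strip", "closed", "compound")
  images <- vector("list", nGroups)
  for (g in seq_len(nGroups)) {
    images[[g]] <- vector("list", imagesPerGroup)
    for (i in seq_len(imagesPerGroup)) {
      li <- NULL
      for (attempt in seq_len(20L)) {
        s <- deriveSeed(seed, (g - 1L) * 10000L + (i - 1L) * 100L + attempt)
        gm <- withSeed(s, runif(1, iv[g, 1], iv[g, 2]))
        sp <- initialize(baseSpec,
                         morphology = morphs[(i - 1L) %% 3L + 1L],
                         gbmMean = gm, seed = deriveSeed(s, 1L))
        cand <- generateMembrane(sp)
        m <- maskMean(cand)
        if (m >= iv[g, 1] && m < iv[g, 2]) { li <- cand; break }
      }
      if (is.null(li))
        stop(sprintf("could not realize an image inside bin %d after retries", g))
      images[[g]][[i]] <- li
    }
  }
  new("GroupedTrainingSet", groups = groups, images = images)
}

#' @rdname nGroups
#' @export
setMethod("nGroups", "GroupedTrainingSet", function(x) nGroups(x@groups))

#' @rdname groupIntervals
#' @export
setMethod("groupIntervals", "GroupedTrainingSet",
          function(x) groupIntervals(x@groups))

#' Images of one group
#'
#' @param dataset a \linkS4class{GroupedTrainingSet}.
#' @param g group index (1-based).
#' @return list of \linkS4class{LabeledImage}.
#' @export
groupImages <- function(dataset, g) {
  stopifnot(is(dataset, "GroupedTrainingSet"))
  dataset@images[[g]]
}

setMethod("show", "GroupedTrainingSet", function(object) {
  n <- vapply(object@images, length, integer(1))
  cat(sprintf("GroupedTrainingSet: %d groups, %d images total\n",
              nGroups(object), sum(n)))
  show(object@groups)
})
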