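## Per-pixel feature stack in the trainable-segmentation tradition: every
## channel is a filtered view of the image, borders handled by mirroring,
## channel order deterministic and recorded so that models can refuse
## mismatched configurations at predict time.

.defaultFamilies <- c(
  "mean", "minimum", "maximum", "median", "variance",
  "sobel", "hessian", "difference_of_gaussians",
  "gaussian_blur", "entropy", "kuwahara",
  "membrane_projections", "lipschitz", "neighbors"
)

#' Create a feature configuration
#'
#' @param families ordered character vector of enabled feature families; the
#'   default enables the fourteen standard families. \code{"anisotropic_diffusion"}
#'   and \code{"bilateral"} are available but off by default: diffusion is
#'   costly and tends to erode the thin target structure.
#' @param scales strictly increasing positive smoothing radii/sigmas in
#'   pixels; the default \code{c(1, 2, 4, 8, 16)} is the usual dyadic ladder.
#' @param membraneSize side length of the square membrane-projection kernel.
#' @param membraneOrientations number of line orientations over 180 degrees.
#' @param neighborOffsets integer matrix (row shift, col shift); default the
#'   eight unit neighbors.
#' @param lipschitzSlope slope of the Lipschitz cover in gray levels per
#'   pixel of city-block distance.
#' @param entropyBins histogram bins for the local entropy filter.
#' @return a \linkS4class{FeatureConfig}.
#' @export
featureConfig <- function(families = .defaultFamilies,
                          scales = c(1, 2, 4, 8, 16),
                          membraneSize = 19L,
                          membraneOrientations = 6L,
                          neighborOffsets = NULL,
                          lipschitzSlope = 10,
                          entropyBins = 64L) {
  if (is.null(neighborOffsets))
    neighborOffsets <- cbind(
      dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
      dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  new("FeatureConfig",
      families = families, scales = as.numeric(scales),
      membraneSize = as.integer(membraneSize),
      membraneOrientations = as.integer(membraneOrientations),
      neighborOffsets = neighborOffsets,
      lipschitzSlope = lipschitzSlope,
      entropyBins = as.integer(entropyBins))
}

.fmtScale <- function(s) gsub("\\.", "p", format(s, trim = TRUE))
.fmtOffset <- function(d) gsub("-", "m", as.character(d))

## Ordered channel names contributed by one family.
.familyChannels <- function(family, cfg) {
  sc <- cfg@scales
  switch(family,
    mean = ,
    minimum = ,
    maximum = ,
    median = ,
    variance = ,
    entropy = ,
    kuwahara = paste0(family, "_r", .fmtScale(sc)),
    sobel = ,
    gaussian_blur = ,
    anisotropic_diffusion = ,
    bilateral = paste0(family, "_s", .fmtScale(sc)),
    hessian = as.vector(rbind(paste0("hessian_eig1_s", .fmtScale(sc)),
                              paste0("hessian_eig2_s", .fmtScale(sc)))),
    difference_of_gaussians =
      if (length(sc) >= 2L)
        paste0("dog_s", .fmtScale(sc[-length(sc)]), "_s", .fmtScale(sc[-1]))
      else paste0("dog_s0_s", .fmtScale(sc)),
    membrane_projections =
      paste0("membrane_", c("sum", "mean", "std", "median", "max", "min")),
    lipschitz = "lipschitz",
    neighbors = paste0("neighbor_", .fmtOffset(cfg@neighborOffsets[, 1]),
                       "_", .fmtOffset(cfg@neighborOffsets[, 2])),
    stop("unknown feature family: ", family)
  )
}

#' @rdname channelNames
#' @param x a \linkS4class{FeatureConfig}, \linkS4class{FeatureStack} or
#'   \linkS4class{ForestModel}.
#' @return ordered character vector of feature channel names.
#' @export
setMethod("channelNames", "FeatureConfig", function(x) {
  unlist(lapply(x@families, .familyChannels, cfg = x), use.names = FALSE)
})

#' @rdname channelNames
#' @export
setMethod("channelNames", "FeatureStack", function(x) x@channelNames)

## ---- individual filters ---------------------------------------------------

.sobelX <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)

.gradMagnitude <- function(img) {
  gx <- convReflect(img, .sobelX)
  gy <- convReflect(img, t(.sobelX))
  sqrt(gx^2 + gy^2)
}

.hessianEigen <- function(img) {
  dxx <- convReflect(img, matrix(c(1, -2, 1), 1, 3))
  dyy <- convReflect(img, matrix(c(1, -2, 1), 3, 1))
  dxy <- convReflect(img, matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3) / 4)
  half <- (dxx + dyy) / 2
  disc <- sqrt(((dxx - dyy) / 2)^2 + dxy^2)
  list(eig1 = half + disc, eig2 = half - disc)
}

.localEntropy <- function(img, radius, nbins) {
  r <- as.integer(ceiling(radius))
  p <- padReflect(img, r)
  bins <- pmin(pmax(floor(p / 256 * nbins), 0), nbins - 1)
  kern <- discKernel(radius, normalize = FALSE)
  total <- sum(kern)
  h <- nrow(img); w <- ncol(img)
  ent <- matrix(0, h, w)
  for (b in sort(unique(as.vector(bins)))) {
    cnt <- EBImage::filter2((bins == b) * 1, kern, boundary = "circular")
    pr <- pmin(pmax(cropCenter(cnt, r, h, w) / total, 0), 1)
    nz <- pr > 1e-12
    ent[nz] <- ent[nz] - pr[nz] * log2(pr[nz])
  }
  ent
}

.kuwahara <- function(img, radius) {
  q <- as.integer(ceiling(radius)) + 1L   # quadrant side, includes centre
  k <- 2L * q - 1L
  mk <- function(rows, cols) {
    kk <- matrix(0, k, k)
    kk[rows, cols] <- 1 / q^2
    kk
  }
  kerns <- list(mk(1:q, 1:q), mk(1:q, q:k), mk(q:k, 1:q), mk(q:k, q:k))
  img2 <- img^2
  out <- NULL; best <- NULL
  for (kk in kerns) {
    m <- convReflect(img, kk)
    v <- pmax(convReflect(img2, kk) - m^2, 0)
    if (is.null(out)) { out <- m; best <- v }
    else {
      sel <- v < best
      out[sel] <- m[sel]
      best[sel] <- v[sel]
    }
  }
  out
}

.membraneKernels <- function(size, norient) {
  ctr <- (size + 1L) %/% 2L
  half <- (size - 1L) / 2
  lapply(seq_len(norient), function(o) {
    th <- (o - 1) * pi / norient
    kk <- matrix(0, size, size)
    t <- seq(-half, half, by = 0.5)
    rr <- round(ctr + t * cos(th)); cc <- round(ctr + t * sin(th))
    ok <- rr >= 1 & rr <= size & cc >= 1 & cc <= size
    kk[unique(cbind(rr[ok], cc[ok]))] <- 1
    kk / sum(kk)
  })
}

.membraneProjections <- function(img, cfg) {
  kerns <- .membraneKernels(cfg@membraneSize, cfg@membraneOrientations)
  resp <- lapply(kerns, function(k) convReflect(img, k))
  n <- length(resp)
  s1 <- Reduce(`+`, resp)
  mu <- s1 / n
  sdv <- sqrt(pmax(Reduce(`+`, lapply(resp, `^`, 2)) / n - mu^2, 0))
  ## vectorized per-pixel median: sort responses within pixel in one pass
  m <- matrix(unlist(resp, use.names = FALSE), ncol = n)
  srt <- matrix(m[order(row(m), m)], nrow(m), n, byrow = TRUE)
  med <- if (n %% 2L) srt[, (n + 1L) %/% 2L]
         else (srt[, n %/% 2L] + srt[, n %/% 2L + 1L]) / 2
  shape <- function(v) matrix(v, nrow(img), ncol(img))
  list(sum = s1, mean = mu, std = sdv,
       median = shape(med),
       max = Reduce(pmax, resp),
       min = Reduce(pmin, resp))
}

## Upper Lipschitz cover under the city-block metric, computed by alternating
## directional sweeps (each is a running max of f + slope*index); the emitted
## channel is cover - image, a top-hat that lights up narrow dark valleys.
.lipschitzCover <- function(img, slope) {
  h <- nrow(img); w <- ncol(img)
  ic <- slope * seq_len(w); ir <- slope * seq_len(h)
  L <- img
  for (iter in seq_len(10L)) {
    prev <- L
    L <- t(apply(L, 1, function(v) cummax(v + ic) - ic))                 # left->right
    L <- t(apply(L, 1, function(v) rev(cummax(rev(v) + ic) - ic)))       # right->left
    L <- apply(L, 2, function(v) cummax(v + ir) - ir)                    # top->bottom
    L <- apply(L, 2, function(v) rev(cummax(rev(v) + ir) - ir))          # bottom->top
    if (max(abs(L - prev)) < 1e-9) break
  }
  L
}

.peronaMalik <- function(img, iters, K = 15, lambda = 0.2) {
  u <- img
  for (i in seq_len(iters)) {
    dn <- shiftReflect(u, -1L, 0L) - u
    ds <- shiftReflect(u, 1L, 0L) - u
    de <- shiftReflect(u, 0L, 1L) - u
    dw <- shiftReflect(u, 0L, -1L) - u
    g <- function(d) exp(-(d / K)^2)
    u <- u + lambda * (g(dn) * dn + g(ds) * ds + g(de) * de + g(dw) * dw)
  }
  u
}

.bilateral <- function(img, sigmaSpace, sigmaRange = 25) {
  r <- as.integer(ceiling(2 * sigmaSpace))
  d <- seq(-r, r)
  offs <- expand.grid(dr = d, dc = d)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, ]
  num <- matrix(0, nrow(img), ncol(img)); den <- num
  for (i in seq_len(nrow(offs))) {
    sh <- shiftReflect(img, offs$dr[i], offs$dc[i])
    wgt <- exp(-(offs$dr[i]^2 + offs$dc[i]^2) / (2 * sigmaSpace^2)) *
      exp(-(sh - img)^2 / (2 * sigmaRange^2))
    num <- num + wgt * sh
    den <- den + wgt
  }
  num / den
}

## ---- the stack ------------------------------------------------------------

.computeFamily <- function(family, img, cfg) {
  sc <- cfg@scales
  switch(family,
    mean = lapply(sc, function(s) convReflect(img, discKernel(s))),
    ## EBImage grayscale morphology clamps to [0, 1]; rescale around it
    minimum = lapply(sc, function(s) {
      r <- as.integer(ceiling(s))
      255 * cropCenter(EBImage::erode(padReflect(img, r) / 255, discBrush(s)),
                       r, nrow(img), ncol(img))
    }),
    maximum = lapply(sc, function(s) {
      r <- as.integer(ceiling(s))
      255 * cropCenter(EBImage::dilate(padReflect(img, r) / 255, discBrush(s)),
                       r, nrow(img), ncol(img))
    }),
    median = lapply(sc, function(s) {
      r <- as.integer(ceiling(s))
      255 * cropCenter(EBImage::medianFilter(padReflect(img, r) / 255, r),
                       r, nrow(img), ncol(img))
    }),
    variance = lapply(sc, function(s) {
      k <- discKernel(s)
      pmax(convReflect(img^2, k) - convReflect(img, k)^2, 0)
    }),
    sobel = lapply(sc, function(s)
      .gradMagnitude(convReflect(img, gaussKernel(s)))),
    hessian = {
      out <- list()
      for (s in sc) {
        e <- .hessianEigen(convReflect(img, gaussKernel(s)))
        out <- c(out, list(e$eig1, e$eig2))
      }
      out
    },
    difference_of_gaussians = {
      blurs <- lapply(sc, function(s) convReflect(img, gaussKernel(s)))
      if (length(sc) >= 2L)
        lapply(seq_len(length(sc) - 1L),
               function(i) blurs[[i]] - blurs[[i + 1L]])
      else list(img - blurs[[1L]])
    },
    gaussian_blur = lapply(sc, function(s) convReflect(img, gaussKernel(s))),
    entropy = lapply(sc, function(s) .localEntropy(img, s, cfg@entropyBins)),
    kuwahara = lapply(sc, function(s) .kuwahara(img, s)),
    membrane_projections = unname(.membraneProjections(img, cfg)),
    lipschitz = list(.lipschitzCover(img, cfg@lipschitzSlope) - img),
    neighbors = lapply(seq_len(nrow(cfg@neighborOffsets)), function(i)
      shiftReflect(img, cfg@neighborOffsets[i, 1], cfg@neighborOffsets[i, 2])),
    anisotropic_diffusion = lapply(sc, function(s)
      .peronaMalik(img, iters = max(1L, as.integer(round(4 * s))))),
    bilateral = lapply(sc, function(s) .bilateral(img, s)),
    stop("unknown feature family: ", family)
  )
}

#' Compute the per-pixel feature stack
#'
#' One channel per (family, scale) combination for scale-parameterized
#' families, plus the fixed channels (membrane projections, Lipschitz
#' top-hat, shifted neighbors). Borders are handled by mirroring, channel
#' order is deterministic and recorded in \code{channelNames}. Each enabled
#' family is computed independently, so removing a family from the
#' configuration leaves the remaining channels bit-identical.
#'
#' @param image numeric matrix in [0, 255] or a \linkS4class{LabeledImage}.
#' @param cfg a \linkS4class{FeatureConfig}.
#' @return a \linkS4class{FeatureStack}.
#' @examples
#' img <- matrix(runif(64 * 64, 0, 255), 64, 64)
#' fs <- computeFeatureStack(img, featureConfig(c("mean", "sobel"), c(1, 2)))
#' channelNames(fs)
#' @export
computeFeatureStack <- function(image, cfg = featureConfig()) {
  if (is(image, "LabeledImage")) image <- grayImage(image)
  if (!is.matrix(image) || length(image) == 0L)
    stop("image must be a non-empty 2-D matrix")
  validObject(cfg)
  chans <- list()
  for (fam in cfg@families)
    chans <- c(chans, .computeFamily(fam, image, cfg))
  nm <- channelNames(cfg)
  stopifnot(length(chans) == length(nm))
  vals <- array(unlist(chans, use.names = FALSE),
                dim = c(nrow(image), ncol(image), length(chans)))
  new("FeatureStack", values = vals, channelNames = nm)
}

#' Flatten a feature stack to a pixels x channels matrix
#'
#' Rows are in column-major pixel order (R's native matrix order), columns
#' are named by channel.
#'
#' @param stack a \linkS4class{FeatureStack}.
#' @return numeric matrix (height*width) x F.
#' @export
featureMatrix <- function(stack) {
  stopifnot(is(stack, "FeatureStack"))
  d <- dim(stack@values)
  m <- stack@values
  dim(m) <- c(d[1] * d[2], d[3])
  colnames(m) <- stack@channelNames
  m
}

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureStack %dx%d, %d channels: %s%s\n", d[1], d[2], d[3],
              paste(head(object@channelNames, 4), collapse = ", "),
              if (d[3] > 4) ", ..." else ""))
})
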