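## Internal numerics shared across modules.

## Evaluate expr under a local RNG stream; the caller's RNG state (including
## absence of one) is restored afterwards, so generation is reproducible
## without clobbering user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Deterministic child seed: keeps derived streams distinct across components
## (g) of one master seed while staying inside 32-bit integer range.
deriveSeed <- function(seed, g) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(g) * 104729) %% 2147483647)
}

## Mirror padding (edge row/col duplicated) by r pixels on every side.
padReflect <- function(m, r) {
  if (r == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  ri <- c(pmin(rev(seq_len(r)), h), seq_len(h), pmax(h - seq_len(r) + 1L, 1L))
  ci <- c(pmin(rev(seq_len(r)), w), seq_len(w), pmax(w - seq_len(r) + 1L, 1L))
  m[ri, ci, drop = FALSE]
}

cropCenter <- function(m, r, h, w) {
  m[(r + 1L):(r + h), (r + 1L):(r + w), drop = FALSE]
}

## 2-D correlation with mirror-boundary handling. The kernel is applied as a
## sliding window (odd-sized); EBImage::filter2 does the heavy lifting on a
## padded copy so the circular wrap never reaches the valid region.
convReflect <- function(m, kernel) {
  r <- max((dim(kernel) - 1L) %/% 2L)
  p <- padReflect(m, r)
  out <- EBImage::filter2(p, kernel, boundary = "circular")
  cropCenter(out, r, nrow(m), ncol(m))
}

## Normalised sampled Gaussian kernel, radius ceil(3 sigma).
gaussKernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  d <- seq(-r, r)
  k <- outer(exp(-d^2 / (2 * sigma^2)), exp(-d^2 / (2 * sigma^2)))
  k / sum(k)
}

## Flat disc kernel of the given radius (includes centre pixel).
discKernel <- function(radius, normalize = TRUE) {
  r <- as.integer(ceiling(radius))
  d <- seq(-r, r)
  k <- (outer(d^2, d^2, "+") <= radius^2) * 1
  if (normalize) k / sum(k) else k
}

## Binary matrix describing the same disc (for morphology / sampling).
discBrush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(ceiling(radius)) + 1L, shape = "disc")
}

## Shift a matrix by (dr, dc) with mirror boundary fill.
shiftReflect <- function(m, dr, dc) {
  r <- max(abs(dr), abs(dc), 1L)
  p <- padReflect(m, r)
  p[(r + 1L - dr):(r + nrow(m) - dr),
    (r + 1L - dc):(r + ncol(m) - dc), drop = FALSE]
}

## 8-connected component labelling: EBImage::bwlabel is 4-connected, so labels
## touching diagonally are merged with a small union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- findRoot(pairs[k, 1]); b <- findRoot(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

assertBinaryMask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("'%s' must be a logical matrix", arg), call. = FALSE)
  invisible(mask)
}
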