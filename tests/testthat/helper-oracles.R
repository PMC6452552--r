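# Brute-force reference implementations used as independent oracles.

# Fixed-point fuzzy C-means on the raw value vector (no weighting shortcut).
bruteFcm <- function(x, m = 2, iters = 500L) {
  rng <- range(x)
  eps <- 1e-6 * diff(rng)
  cen <- c(rng[1] + eps, rng[2] - eps)
  u <- matrix(0, length(x), 2)
  for (it in seq_len(iters)) {
    d <- cbind(abs(x - cen[1]), abs(x - cen[2]))
    d[d < 1e-12] <- 1e-12
    u <- 1 / (d^(2 / (m - 1)) * rowSums(1 / d^(2 / (m - 1))))
    cenNew <- colSums(u^m * x) / colSums(u^m)
    if (max(abs(cenNew - cen)) < 1e-10) { cen <- cenNew; break }
    cen <- cenNew
  }
  list(centers = cen, membership = u)
}

# Naive 8-connected flood-fill labelling.
bruteLabel8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# Independent reimplementation of the refinement rule for tiny inputs.
bruteRefine <- function(crs, w2, cleanupCfg, maxIters = 10L) {
  consensus <- function(idx) {
    pm <- Reduce(`+`, lapply(crs[idx], `*`, 1)) / length(idx)
    vals <- as.vector(pm)
    if (length(unique(vals)) < 2L) {
      core <- matrix(FALSE, nrow(pm), ncol(pm))
    } else {
      f <- bruteFcm(vals)
      hi <- which.max(f$centers)
      core <- matrix(f$membership[, hi] > f$membership[, -hi],
                     nrow(pm), ncol(pm))
    }
    lab <- bruteLabel8(core)
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0])
      core <- matrix(lab %in% which(areas >= cleanupCfg@minComponentArea),
                     nrow(pm), ncol(pm))
    }
    core
  }
  jac <- function(a, b) {
    u <- sum(a | b); if (u == 0) 1 else sum(a & b) / u
  }
  S <- seq_along(crs)
  C <- consensus(S)
  for (it in seq_len(maxIters)) {
    J <- vapply(crs, jac, numeric(1), b = C)
    Snew <- which(J >= w2)
    if (length(Snew) == 0L || identical(Snew, S)) break
    S <- Snew
    C <- consensus(S)
  }
  list(mask = C, retained = S)
}

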