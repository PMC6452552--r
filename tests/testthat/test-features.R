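test_that("a flat field gives analytic values on every local-statistic channel", {
  img <- matrix(77, 32L, 40L)
  cfg <- featureConfig(c("mean", "minimum", "maximum", "median", "variance",
                         "sobel"), scales = c(1, 2))
  fs <- computeFeatureStack(img, cfg)
  nm <- channelNames(fs)
  for (ch in grep("^(mean|minimum|maximum|median)_", nm)) {
    expect_equal(as.vector(fs@values[, , ch]), rep(77, length(img)),
                 tolerance = 1e-6, label = nm[ch])
  }
  for (ch in grep("^(variance|sobel)_", nm)) {
    expect_equal(as.vector(fs@values[, , ch]), rep(0, length(img)),
                 tolerance = 1e-6, label = nm[ch])
  }
})

test_that("Gaussian blur of a unit impulse reproduces the discrete kernel's central weight", {
  h <- 33L
  img <- matrix(0, h, h)
  img[17L, 17L] <- 255
  for (s in c(1, 2)) {
    fs <- computeFeatureStack(img, featureConfig("gaussian_blur", scales = s))
    # independent oracle: the normalised sampled-Gaussian weight at (0, 0)
    r <- ceiling(3 * s)
    d <- seq(-r, r)
    k <- outer(exp(-d^2 / (2 * s^2)), exp(-d^2 / (2 * s^2)))
    w00 <- (k / sum(k))[r + 1, r + 1]
    expect_equal(fs@values[17L, 17L, 1L], 255 * w00, tolerance = 1e-8)
  }
})

test_that("channel bookkeeping: the stack depth is the sum of per-family channel counts", {
  cfg <- featureConfig()   # all 14 default families, scales 1,2,4,8,16
  nm <- channelNames(cfg)
  nsc <- length(cfg@scales)
  perFamily <- c(mean = nsc, minimum = nsc, maximum = nsc, median = nsc,
                 variance = nsc, sobel = nsc, hessian = 2L * nsc,
                 difference_of_gaussians = nsc - 1L, gaussian_blur = nsc,
                 entropy = nsc, kuwahara = nsc, membrane_projections = 6L,
                 lipschitz = 1L, neighbors = 8L)
  expect_identical(length(nm), sum(perFamily))
  expect_false(anyDuplicated(nm) > 0)

  img <- matrix(runif(24 * 24, 0, 255), 24L, 24L)
  small <- featureConfig(c("mean", "hessian", "difference_of_gaussians",
                           "membrane_projections", "lipschitz", "neighbors"),
                         scales = c(1, 2))
  fs <- computeFeatureStack(img, small)
  expect_identical(dim(fs@values)[3], length(channelNames(small)))
  expect_identical(channelNames(fs), channelNames(small))
  expect_true(all(is.finite(fs@values)))
})

test_that("adding a constant shifts averaging channels and leaves derivative channels unchanged", {
  set.seed(9)
  img <- matrix(sample(30:180, 40L * 48L, replace = TRUE), 40L, 48L)
  cfg <- featureConfig(c("mean", "minimum", "maximum", "median",
                         "gaussian_blur", "variance", "sobel",
                         "difference_of_gaussians"), scales = c(1, 2))
  a <- computeFeatureStack(img, cfg)
  b <- computeFeatureStack(img + 25, cfg)
  nm <- channelNames(a)
  interior <- function(x) x[8:33, 8:41]
  for (ch in grep("^(mean|minimum|maximum|median|gaussian_blur)_", nm)) {
    expect_equal(interior(b@values[, , ch]), interior(a@values[, , ch]) + 25,
                 tolerance = 1e-6, label = nm[ch])
  }
  for (ch in grep("^(variance|sobel|dog)_", nm)) {
    expect_equal(interior(b@values[, , ch]), interior(a@values[, , ch]),
                 tolerance = 1e-6, label = nm[ch])
  }
})

test_that("feature channels are shift-equivariant away from borders", {
  set.seed(4)
  img <- matrix(runif(60 * 80, 0, 255), 60L, 80L)
  dr <- 3L; dc <- 5L
  shifted <- img[(1 + dr):60, (1 + dc):80]
  img <- img[1:(60 - dr), 1:(80 - dc)]
  cfg <- featureConfig(c("mean", "variance", "sobel", "gaussian_blur",
                         "entropy", "kuwahara", "membrane_projections",
                         "neighbors"), scales = c(1, 2))
  a <- computeFeatureStack(img, cfg)
  b <- computeFeatureStack(shifted, cfg)
  m <- 16L   # margin exceeding every kernel radius in cfg
  h <- nrow(img); w <- ncol(img)
  for (ch in seq_along(channelNames(a))) {
    expect_equal(
      b@values[m:(h - dr - m), m:(w - dc - m), ch],
      a@values[(m + dr):(h - m), (m + dc):(w - m), ch],
      tolerance = 1e-6, label = channelNames(a)[ch])
  }
})

test_that("disabling a family removes exactly its channels, bit-identically", {
  img <- matrix(runif(24 * 24, 0, 255), 24L, 24L)
  all3 <- featureConfig(c("mean", "sobel", "neighbors"), scales = c(1, 2))
  two <- featureConfig(c("mean", "neighbors"), scales = c(1, 2))
  fsAll <- computeFeatureStack(img, all3)
  fsTwo <- computeFeatureStack(img, two)
  keep <- match(channelNames(two), channelNames(all3))
  expect_identical(fsAll@values[, , keep], fsTwo@values)
})

test_that("degenerate inputs and configs are rejected", {
  expect_error(computeFeatureStack(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(featureConfig(character(0)), "at least one")
  expect_error(featureConfig("mean", scales = c(2, 1)), "increasing")
  expect_error(featureConfig("sorcery"), "unknown")
})
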