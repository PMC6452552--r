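constantImage <- function(value, h = 20L, w = 20L) {
  mask <- matrix(FALSE, h, w); mask[8:12, ] <- TRUE
  labeledImage(matrix(value, h, w), mask)
}

test_that("group assignment follows the bins, clamps out-of-range means with a warning, and rejects empty masks", {
  gg <- grayscaleGroups()
  expect_identical(assignGroup(constantImage(74), gg), 1L)
  expect_identical(assignGroup(constantImage(146), gg), 37L)
  expect_identical(assignGroup(constantImage(100.2), gg),
                   which(100.2 >= groupIntervals(gg)[, 1] &
                           100.2 < groupIntervals(gg)[, 2]))
  expect_warning(g <- assignGroup(constantImage(60), gg), "below")
  expect_identical(g, 1L)
  expect_warning(g <- assignGroup(constantImage(200), gg), "above")
  expect_identical(g, 37L)
  empty <- labeledImage(matrix(100, 10, 10), matrix(FALSE, 10, 10))
  expect_error(assignGroup(empty, gg), "empty")
})

test_that("pixel sampling draws exactly M pixels, balances classes, and is seed-deterministic", {
  li <- cleanStrip()
  cfg <- quickFeatureConfig()
  s <- samplePixels(li, 200L, balance = TRUE, seed = 7L, cfg = cfg)
  expect_identical(nSamples(s), 200L)
  expect_identical(unname(table(s@labels)["GBM"]), 100L)
  expect_identical(unname(table(s@labels)["background"]), 100L)

  s2 <- samplePixels(li, 200L, balance = TRUE, seed = 7L, cfg = cfg)
  expect_identical(s@features, s2@features)
  expect_identical(s@origin, s2@origin)

  # feature vectors must be the stack values at the sampled coordinates
  fs <- computeFeatureStack(li, cfg)
  k <- 5L
  expect_identical(unname(s@features[k, ]),
                   unname(fs@values[s@origin$row[k], s@origin$col[k], ]))

  # labels match the mask at the sampled coordinates
  expect_identical(as.character(s@labels),
                   ifelse(gbmMask(li)[cbind(s@origin$row, s@origin$col)],
                          "GBM", "background"))

  expect_error(samplePixels(li, 1e7L, cfg = cfg), "cannot draw")

  # tiny foreground forces the proportional fallback
  tiny <- labeledImage(matrix(runif(400, 0, 255), 20, 20),
                       {m <- matrix(FALSE, 20, 20); m[1, 1:3] <- TRUE; m})
  expect_warning(sp <- samplePixels(tiny, 100L, balance = TRUE, seed = 1L,
                                    cfg = cfg), "proportional")
  expect_identical(nSamples(sp), 100L)
})

test_that("forest training: T trees, perfect fit on separable clusters, determinism, single-class rejection", {
  set.seed(1)
  n <- 120L
  feats <- rbind(matrix(rnorm(n, 0, 0.3), ncol = 2),
                 matrix(rnorm(n, 8, 0.3), ncol = 2))
  colnames(feats) <- c("f1", "f2")
  labs <- factor(rep(c("background", "GBM"), each = n / 2),
                 levels = c("background", "GBM"))
  samples <- new("PixelSamples", features = feats, labels = labs,
                 origin = data.frame(image = "toy", row = 1L,
                                     col = seq_len(n)))
  fm <- trainForest(samples, nTrees = 20L, maxDepth = 5L, seed = 3L)
  expect_equal(fm@forest$num.trees, 20)
  expect_identical(fm@meta$nTrees, 20L)

  # exhaustive evaluation over every training point
  pred <- RFStacks:::.voteMask(RFStacks:::.voteFractions(fm, feats))
  expect_identical(pred, labs == "GBM")

  fm2 <- trainForest(samples, nTrees = 20L, maxDepth = 5L, seed = 3L)
  probe <- matrix(runif(40, -2, 10), ncol = 2,
                  dimnames = list(NULL, c("f1", "f2")))
  expect_identical(RFStacks:::.voteFractions(fm, probe),
                   RFStacks:::.voteFractions(fm2, probe))

  oneClass <- new("PixelSamples", features = feats,
                  labels = factor(rep("GBM", n),
                                  levels = c("background", "GBM")),
                  origin = samples@origin)
  expect_error(trainForest(oneClass), "both classes")
})

test_that("full-view pooling conserves M x N samples and records provenance", {
  cfg <- trainingConfig(nGroups = 3L, samplesPerImage = 10L, nTrees = 5L,
                        maxDepth = 4L, featureConfig = quickFeatureConfig(),
                        seed = 9L)
  base <- syntheticSpec("strip", height = 48L, width = 72L, seed = 1L)
  ds <- generateGroupedDataset(3L, 2L, meanStart = 90, binWidth = 8,
                               baseSpec = base, seed = 21L)
  full <- trainFullView(ds, cfg)
  expect_identical(full@provenance$pooledCount, 30L)
  expect_identical(full@forest@meta$nSamples, 30L)
  expect_length(full@provenance$selectedImages, 3L)
  expect_true(all(full@provenance$selectedImages %in% 1:2))

  # an empty group is a hard error
  dsEmpty <- ds
  dsEmpty@images[[2]] <- list()
  expect_error(trainFullView(dsEmpty, cfg), "at least one")
})

test_that("zoom-view training yields one aligned forest per group with distinct derived seeds", {
  cfg <- trainingConfig(nGroups = 3L, samplesPerImage = 40L, nTrees = 5L,
                        maxDepth = 4L, featureConfig = quickFeatureConfig(),
                        seed = 9L)
  base <- syntheticSpec("strip", height = 48L, width = 72L, seed = 1L)
  ds <- generateGroupedDataset(3L, 1L, meanStart = 90, binWidth = 8,
                               baseSpec = base, seed = 21L)
  zoom <- trainZoomView(ds, cfg)
  expect_identical(nGroups(zoom), 3L)
  seeds <- vapply(zoom@forests, function(f) f@meta$seed, integer(1))
  expect_identical(anyDuplicated(seeds), 0L)

  # degenerate bank of one: identical to a direct trainForest call under the
  # same derived sampling and training seeds
  ds1 <- generateGroupedDataset(1L, 1L, meanStart = 90, binWidth = 8,
                                baseSpec = base, seed = 21L)
  cfg1 <- trainingConfig(nGroups = 1L, samplesPerImage = 40L, nTrees = 5L,
                         maxDepth = 4L, featureConfig = quickFeatureConfig(),
                         seed = 9L)
  zoom1 <- trainZoomView(ds1, cfg1)
  s <- samplePixels(groupImages(ds1, 1)[[1]], 40L, balance = TRUE,
                    seed = RFStacks:::deriveSeed(9L, 1L),
                    cfg = quickFeatureConfig())
  direct <- trainForest(s, nTrees = 5L, maxDepth = 4L,
                        seed = RFStacks:::deriveSeed(9L, 1L))
  probe <- computeFeatureStack(groupImages(ds1, 1)[[1]], quickFeatureConfig())
  expect_identical(
    RFStacks:::.voteFractions(zoomForest(zoom1, 1), featureMatrix(probe)),
    RFStacks:::.voteFractions(direct, featureMatrix(probe)))
})
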