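test_that("the voting rule is a strict majority with ties to background", {
  expect_identical(RFStacks:::.voteMask(c(2/3, 1/3, 0.5, 0.51, 1, 0)),
                   c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("pixel classification is deterministic and refuses mismatched feature channels", {
  tf <- tinyForest()
  cfg <- quickFeatureConfig()
  m1 <- classifyImage(tf$forest, tf$image, cfg)
  m2 <- classifyImage(tf$forest, tf$image, cfg)
  expect_identical(m1, m2)
  expect_type(m1, "logical")
  other <- featureConfig(c("mean", "sobel"), scales = c(1, 2))
  expect_error(classifyImage(tf$forest, tf$image, other), "channels")
})

test_that("the probability map is exactly n/N, the mean of indicator masks", {
  set.seed(31)
  crs <- lapply(1:5, function(i) randomMask(12, 9))
  pm <- probabilityMap(crs)
  # independent elementwise oracle
  expected <- matrix(0, 12, 9)
  for (m in crs) expected <- expected + m
  expect_equal(pm, expected / 5, tolerance = 0)
  expect_true(all(abs(pm * 5 - round(pm * 5)) < 1e-12))
  # conservation: total probability mass equals mean coarse-result area
  expect_equal(sum(pm), mean(vapply(crs, sum, numeric(1))) * 1,
               tolerance = 1e-12)
  expect_error(probabilityMap(list(randomMask(3, 3), randomMask(4, 3))),
               "shape")
  expect_error(probabilityMap(list()), "at least one")
})

test_that("fuzzy C-means bipartition matches the brute-force fixed point and handles degeneracy", {
  # perfectly separated {0,1} map: membership is crisp
  pm01 <- matrix(c(rep(0, 40), rep(1, 24)), 8, 8)
  expect_identical(fcmBipartition(pm01), pm01 == 1)

  # all-equal map: empty mask plus a warning
  expect_warning(res <- fcmBipartition(matrix(0.4, 6, 6)), "constant")
  expect_identical(res, matrix(FALSE, 6, 6))

  # two-valued map: centroids converge to the value means; cross-check the
  # package result against the independent fixed-point iteration
  pm2 <- matrix(c(rep(0.1, 40), rep(0.9, 24)), 8, 8)
  expect_identical(fcmBipartition(pm2), pm2 == 0.9)
  oracle <- bruteFcm(as.vector(pm2))
  expect_equal(sort(oracle$centers), c(0.1, 0.9), tolerance = 1e-3)

  # a graded map: package partition equals the oracle partition
  set.seed(8)
  pmg <- matrix(sample(c(0, 1/3, 2/3, 1), 64, replace = TRUE), 8, 8)
  got <- fcmBipartition(pmg)
  f <- bruteFcm(as.vector(pmg))
  hi <- which.max(f$centers)
  expect_identical(got, matrix(f$membership[, hi] > f$membership[, -hi], 8, 8))
})

test_that("morphological cleanup removes small components and never adds pixels", {
  blob <- matrix(FALSE, 30, 30); blob[5:6, 5:9] <- TRUE   # 10 px
  expect_identical(morphologicalCleanup(blob, cleanupConfig(50L, 0L)),
                   matrix(FALSE, 30, 30))
  expect_identical(morphologicalCleanup(matrix(FALSE, 10, 10)),
                   matrix(FALSE, 10, 10))
  big <- matrix(FALSE, 30, 30); big[5:24, 5:24] <- TRUE   # 400 px
  expect_identical(morphologicalCleanup(big, cleanupConfig(50L, 0L)), big)
  set.seed(2)
  for (i in 1:5) {
    m <- randomMask(20, 20, 0.4)
    out <- morphologicalCleanup(m, cleanupConfig(5L, 1L))
    expect_true(all(m[out]))   # subset of the input
  }
  # diagonal chains count as one 8-connected component
  diagm <- matrix(FALSE, 12, 12)
  for (k in 1:10) diagm[k, k] <- TRUE
  expect_identical(morphologicalCleanup(diagm, cleanupConfig(8L, 0L)), diagm)
})

test_that("refinement degenerates correctly: one pass at w1=1, w2=0; unanimity is a fixed point; adversaries are excluded", {
  set.seed(12)
  crs <- lapply(1:6, function(i) {
    m <- matrix(FALSE, 20, 20); m[6:14, (3 + i):(12 + i)] <- TRUE; m
  })
  cfg <- refinementConfig(w1 = 1, w2 = 0, cleanup = cleanupConfig(5L, 0L))
  ref <- iterativeRefinement(crs, cfg)
  onePass <- morphologicalCleanup(fcmBipartition(probabilityMap(crs),
                                                 cfg@fcm), cfg@cleanup)
  expect_identical(ref$mask, onePass)
  expect_identical(ref$retained, seq_along(crs))

  x <- matrix(FALSE, 20, 20); x[4:16, 6:15] <- TRUE
  same <- replicate(5, x, simplify = FALSE)
  for (w in list(c(1, 0), c(1, 0.3), c(0.6, 0.3))) {
    r <- iterativeRefinement(same, refinementConfig(w1 = w[1], w2 = w[2],
                                                    cleanup = cleanupConfig(5L, 0L)))
    expect_identical(r$mask, x)
  }

  good <- matrix(FALSE, 40, 40); good[10:29, 10:29] <- TRUE
  crs2 <- c(replicate(9, good, simplify = FALSE),
            list(matrix(TRUE, 40, 40)))
  r2 <- iterativeRefinement(crs2, refinementConfig(w1 = 1, w2 = 0.3,
                                                   cleanup = cleanupConfig(5L, 0L)))
  expect_identical(r2$retained, 1:9)
  expect_identical(r2$mask, good)
})

test_that("refinement matches a brute-force reimplementation on tiny inputs", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(1:3, 1)
    crs <- lapply(seq_len(n), function(i) randomMask(8, 8, runif(1, 0.2, 0.6)))
    w2 <- sample(c(0, 0.2, 0.4), 1)
    ccfg <- cleanupConfig(minComponentArea = 2L, openingRadius = 0L)
    got <- iterativeRefinement(crs, refinementConfig(w1 = 1, w2 = w2,
                                                     cleanup = ccfg))
    want <- bruteRefine(crs, w2, ccfg)
    expect_identical(got$mask, want$mask)
    expect_identical(got$retained, want$retained)
  }
})

test_that("the retained set never shrinks when the similarity cutoff is zero", {
  set.seed(5)
  crs <- lapply(1:7, function(i) randomMask(15, 15, 0.3))
  r <- iterativeRefinement(crs, refinementConfig(w1 = 1, w2 = 0,
                                                 cleanup = cleanupConfig(3L, 0L)))
  expect_identical(r$retained, 1:7)
})

test_that("a single-forest bank reproduces the full-view candidate through the zoom path", {
  tf <- tinyForest()
  cfg <- quickFeatureConfig()
  gg <- grayscaleGroups(1L, 95, 10)
  full <- new("FullViewModel", forest = tf$forest,
              provenance = list(selectedImages = 1L, pooledCount = 400L))
  zoom <- new("ZoomViewModel", forests = list(tf$forest), groups = gg,
              provenance = list())
  res <- segmentImage(tf$image, full, zoom, featureCfg = cfg,
                      cfg = refinementConfig(w1 = 1, w2 = 0))
  expect_identical(candidateR1(res), candidateR2(res))
  expect_identical(length(coarseMasks(res)), 1L)
  expect_false(is.na(res@jaccardR1))   # gold taken from the LabeledImage
  expect_identical(res@selected, "unset")

  resAuto <- segmentImage(tf$image, full, zoom, featureCfg = cfg,
                          cfg = refinementConfig(w1 = 1, w2 = 0),
                          autoSelect = TRUE)
  expect_true(resAuto@selected %in% c("R1", "R2"))

  # no gold: scores stay NA and nothing is selected
  resNoGold <- segmentImage(grayImage(tf$image), full, zoom,
                            featureCfg = cfg,
                            cfg = refinementConfig(w1 = 1, w2 = 0))
  expect_true(is.na(resNoGold@jaccardR1))
  expect_identical(resNoGold@selected, "unset")
})
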