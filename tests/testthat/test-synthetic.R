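test_that("membrane pixels hit the target mean exactly without noise, and generation is seed-deterministic", {
  sp <- syntheticSpec("strip", height = 217L, width = 307L, gbmMean = 100,
                      noiseSigma = 0, illuminationAmplitude = 0, seed = 11L)
  li <- generateMembrane(sp)
  expect_s4_class(li, "LabeledImage")
  expect_identical(dim(grayImage(li)), dim(gbmMask(li)))
  expect_type(gbmMask(li), "logical")
  expect_equal(maskMean(li), 100, tolerance = 1e-12)
  expect_true(all(grayImage(li) >= 0 & grayImage(li) <= 255))

  li2 <- generateMembrane(sp)
  expect_identical(grayImage(li), grayImage(li2))
  expect_identical(gbmMask(li), gbmMask(li2))

  # noise must not be able to leak pixels outside the 8-bit range either
  ln <- generateMembrane(syntheticSpec("strip", height = 64L, width = 96L,
                                       gbmMean = 250, gbmContrast = 30,
                                       noiseSigma = 40, seed = 2L))
  expect_true(all(grayImage(ln) >= 0 & grayImage(ln) <= 255))
})

test_that("a closed membrane encloses a lumen: the background has at least two components", {
  li <- generateMembrane(syntheticSpec("closed", height = 120L, width = 130L,
                                       seed = 7L))
  bgLabels <- EBImage::bwlabel((!gbmMask(li)) * 1)
  expect_gte(max(bgLabels), 2)
})

test_that("grouped generation respects its bins and the printed bin layout", {
  gg <- grayscaleGroups()   # defaults: 37 bins of width 2 from 73.5
  iv <- groupIntervals(gg)
  expect_equal(unname(iv[1, ]), c(73.5, 75.5))
  expect_equal(unname(iv[37, ]), c(145.5, 147.5))
  expect_true(all(abs(iv[-37, 2] - iv[-1, 1]) < 1e-12))  # contiguous

  base <- syntheticSpec("strip", height = 72L, width = 104L, seed = 1L)
  ds <- generateGroupedDataset(3L, 2L, meanStart = 80, binWidth = 6,
                               baseSpec = base, seed = 42L)
  expect_equal(nGroups(ds), 3L)
  ivd <- groupIntervals(ds)
  for (g in 1:3) {
    imgs <- groupImages(ds, g)
    expect_length(imgs, 2L)
    for (im in imgs) {
      m <- maskMean(im)
      expect_gte(m, ivd[g, 1])
      expect_lt(m, ivd[g, 2])
    }
  }

  # degenerate single group
  d1 <- generateGroupedDataset(1L, 3L, meanStart = 100, binWidth = 10,
                               baseSpec = base, seed = 5L)
  expect_length(groupImages(d1, 1L), 3L)

  # determinism of the whole dataset
  ds2 <- generateGroupedDataset(3L, 2L, meanStart = 80, binWidth = 6,
                                baseSpec = base, seed = 42L)
  expect_identical(grayImage(groupImages(ds, 2)[[1]]),
                   grayImage(groupImages(ds2, 2)[[1]]))
})

test_that("increasing the contrast setting widens the realized foreground/background separation", {
  sep <- vapply(c(10, 30, 60), function(contrast) {
    diffs <- vapply(1:3, function(s) {
      li <- generateMembrane(syntheticSpec(
        "strip", height = 64L, width = 96L, gbmMean = 100,
        gbmContrast = contrast, noiseSigma = 5, clutterDensity = 0,
        seed = s))
      abs(mean(grayImage(li)[gbmMask(li)]) -
            mean(grayImage(li)[!gbmMask(li)]))
    }, numeric(1))
    mean(diffs)
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("invalid specs are rejected", {
  expect_error(syntheticSpec("strip", gbmMean = 300), "gbmMean")
  expect_error(syntheticSpec("strip", ribbonWidthRange = c(5, 2)),
               "ribbonWidthRange")
  expect_error(syntheticSpec("spiral"))
})
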