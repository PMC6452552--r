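# Shared fixtures. Expensive objects (the seeded benchmark, small trained
# models) are built lazily and cached for the whole run.

.rfsCache <- new.env(parent = emptyenv())

# A small, fast feature configuration used wherever the particular feature
# set is not what is under test.
quickFeatureConfig <- function() {
  featureConfig(c("mean", "variance", "sobel", "gaussian_blur", "neighbors"),
                scales = c(1, 2))
}

# Clean, easy synthetic image: no noise, no clutter, no shading.
cleanStrip <- function(seed = 3L, h = 64L, w = 96L, gbmMean = 100) {
  generateMembrane(syntheticSpec(
    "strip", height = h, width = w, gbmMean = gbmMean,
    noiseSigma = 0, illuminationAmplitude = 0, clutterDensity = 0,
    seed = seed))
}

# Realistic small image (noise, clutter, shading on).
noisyStrip <- function(seed = 5L, h = 64L, w = 96L, gbmMean = 110) {
  generateMembrane(syntheticSpec(
    "strip", height = h, width = w, gbmMean = gbmMean, seed = seed))
}

# One trained forest on an easy image, cached.
tinyForest <- function() {
  if (is.null(.rfsCache$tinyForest)) {
    li <- cleanStrip()
    s <- samplePixels(li, 400L, balance = TRUE, seed = 1L,
                      cfg = quickFeatureConfig())
    .rfsCache$tinyForest <- list(
      image = li,
      forest = trainForest(s, nTrees = 15L, maxDepth = 7L, seed = 2L))
  }
  .rfsCache$tinyForest
}

# The seeded synthetic benchmark shared by the acceptance suite.
cachedBenchmark <- function() {
  if (is.null(.rfsCache$benchmark))
    .rfsCache$benchmark <- runBenchmark(seed = 1L)
  .rfsCache$benchmark
}

# Random binary mask with a controllable foreground rate.
randomMask <- function(h, w, rate = 0.3) {
  matrix(runif(h * w) < rate, h, w)
}
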