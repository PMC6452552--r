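---
title: "Random forest stacks for membrane segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random forest stacks for membrane segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(RFStacks)
```

## The problem and the model

The glomerular basement membrane (GBM) appears in kidney-biopsy TEM images
as a dark, thin, winding ribbon. Two properties make pixel-wise
segmentation hard. First, within an image the membrane's local appearance
is confusable with other electron-dense structures (podocyte foot
processes, endothelial cytoplasm). Second, across a dataset the absolute
gray level of the membrane drifts over tens of gray levels with specimen
preparation and illumination, so a classifier keyed to absolute intensity
transfers poorly between images.

RFStacks addresses the two difficulties with two levels of ensemble
integration on top of a per-pixel feature stack:

1. *Within a forest* (level 1): ordinary bagging. Each of T trees is grown
   on a bootstrap resample of the labelled pixel samples with random
   feature subsets of size √F at each split; at test time each tree votes
   per pixel and the strict majority wins (an exact tie is background —
   conservative, because the foreground is thin and sparse).
2. *Across grayscale groups* (level 2): training images are stratified
   into N contiguous bins of mean membrane gray value. The *full-view*
   model pools M pixel samples from one image of every bin into a single
   forest (M × N samples), forcing it to discover intensity-shift-tolerant
   split rules. The *zoom-view* model keeps N per-bin forests whose
   outputs — the coarse results CR₁…CR_N — are fused at test time: the
   probability map p(i,j) = n(i,j)/N is bipartitioned by 2-cluster fuzzy
   C-means, cleaned morphologically, and refined by iterating the loop
   "rebuild consensus from retained coarse results, drop coarse results
   whose Jaccard to the consensus is below w₂".

The pipeline assumes 8-bit single-channel images; a non-empty ground-truth
mask per training image; and a membrane that is darker than its local
background (configurable sign in the synthetic generator).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| N (`nGroups`) | 37 | bins | grayscale stratification; bins of width 2 from 73.5, i.e. [73.5, 75.5) … [145.5, 147.5) |
| M (`samplesPerImage`) | 2000 | pixels | labelled samples drawn per training image (balanced: ⌈M/2⌉ membrane, ⌊M/2⌋ background) |
| T (`nTrees`) | 100 | trees | forest size; accuracy saturates while cost grows linearly |
| D (`maxDepth`) | 9 | levels | depth cap; limits variance and keeps models small |
| scales | 1, 2, 4, 8, 16 | px | dyadic sigma/radius ladder shared by scale-parameterized feature families |
| w₁ | 1 | fraction | initial retained fraction of coarse results; 1 = start unfiltered |
| w₂ | 0.3 | Jaccard | similarity cutoff for keeping a coarse result against the consensus |
| `minComponentArea` | 50 | px | smallest 8-connected component kept after opening |
| `openingRadius` | 1 | px | disc radius of the binary opening |
| fuzzifier m | 2 | — | fuzzy C-means exponent; `tol` 1e-5, `maxIters` 300 |

On the grouping defaults: the source material for this design reports the
mean membrane intensities both as "starting near 73 with step 3" and, in
its printed bin boundaries, as bins of width 2 from 73.5. The printed
boundaries are self-consistent (37 bins of width 2 end exactly at 147.5),
so width 2 is the default; both start and width are plain arguments of
`grayscaleGroups()`.

## The feature stack

Fourteen families are enabled by default: local mean / minimum / maximum /
median / variance, Sobel magnitude, Hessian eigenvalues, difference of
Gaussians (consecutive scale pairs), Gaussian blur, local entropy,
Kuwahara, membrane projections (19 × 19 line kernels at 30° steps, reduced
across orientations by sum / mean / sd / median / max / min), a Lipschitz
top-hat, and raw shifted neighbors. Anisotropic diffusion and bilateral
filtering are implemented but disabled by default — diffusion in
particular costs much and tends to erode the thin target ribbon.

Numerical conventions, chosen once and recorded here:

* **Borders** are handled by mirroring (edge row/column duplicated); every
  channel is computed on a padded copy and cropped, so circular FFT wrap
  never reaches valid pixels.
* **Entropy** uses 64 histogram bins rather than a full 256: windows of
  radius ≤ 16 contain at most ~800 pixels, so a 256-bin histogram is
  mostly sampling noise; the bin count is a `FeatureConfig` field.
* **Hessian** emits the two eigenvalues per scale (the line-detection
  responses) rather than a larger derived set.
* **Lipschitz** is the upper cover under the city-block metric (computed
  by alternating directional running-max sweeps to a fixed point), emitted
  as cover − image so that narrow dark valleys light up; slope 10 gray
  levels/pixel by default.
* **Kuwahara** is the classical four-quadrant variance-minimizing mean;
  ties go to the first quadrant in scan order (deterministic).
* Features stay in floating point and are not normalized — trees are
  invariant to monotone per-feature scaling.
* Each family is computed independently, so disabling one removes exactly
  its channels and leaves the rest bit-identical (tested).

## Test-phase numerics

* **Voting**: membrane iff vote fraction > 0.5; exact ties are background.
* **Fuzzy C-means** runs on the weighted unique probability values
  (identical objective, much smaller problem: a probability map holds at
  most N + 1 distinct values) with centroids initialized deterministically
  just inside the two extreme observed values; the membrane cluster is the
  one with the larger converged centroid. A constant map cannot be
  bipartitioned: the result is an empty mask plus a warning.
* **Cleanup** is opening with a disc, then removal of 8-connected
  components below the area threshold. The base labelling is 4-connected;
  diagonal label pairs are merged by union-find to get 8-connectivity.
  Cleanup never adds pixels.
* **Refinement**: start from S = all coarse results when w₁ = 1, else the
  top ⌈w₁·N⌉ ranked by mean pairwise Jaccard to the others; loop
  consensus → rescore all CRs → retain {J ≥ w₂}; stop on an unchanged
  retained set, an about-to-be-empty set (previous set kept), or after
  `maxIters` (10). With w₁ = 1 and w₂ = 0 this provably reduces to a
  single unfiltered pass. The loop ordering (consensus before filtering)
  and the stopping rule are this package's own reconstruction of the
  published outline, chosen to be consistent with the documented
  semantics of w₁ = 1 ("all N results enter the optimization without
  filtering") and of w₂ as a similarity cutoff near 0.3; tests pin the
  behaviour against an independent brute-force reimplementation on tiny
  inputs.
* **Candidate R₁** receives the same morphological cleanup as R₂'s
  consensus (switchable via `cleanupR1 = FALSE`); without this the
  full-view/zoom-view comparison would confound the classifier with the
  post-processing.
* The ablation's plain **voting variant V** is defined as p ≥ 0.5 on the
  probability map with no cleanup; "voting" is not otherwise pinned down
  for level 2, and the ≥ convention makes V the natural majority rule.

## The synthetic generator

`generateMembrane()` emulates exactly the difficulties the method targets:
a ribbon drawn along a smooth random curve (open natural spline for
strips, radially perturbed ellipse for closed contours, their union for
compound shapes) with smoothly varying half-width (default 3–7 px);
membrane pixels painted at the target mean gray value (exactly, before
noise — tests rely on this); background at membrane ± contrast (default
35, membrane darker); elliptical clutter blobs whose intensity sits within
±15 gray levels of the membrane mean, making them genuinely confusable;
a zero-mean linear illumination ramp on the background (default 25
peak-to-peak); Gaussian noise last (default σ = 10); clipped to [0, 255].
Identical spec + seed is bit-identical. Degenerate curve geometry is
retried with fresh jitter up to a bounded count.

`generateGroupedDataset()` draws each image's target membrane mean
uniformly inside its bin and regenerates (bounded retries) until the
*realized* mask mean lies inside the bin, so stratification invariants
hold exactly; morphologies cycle strip/closed/compound.

What the generator does **not** model: physically realistic TEM image
formation (electron optics, film grain statistics), immune deposits or
membrane fractures as distinct classes, and texture inside organelles.
Passing tests on synthetic data therefore demonstrate the machinery —
stratification, stacking, fusion, refinement — under controlled
difficulty, not clinical-grade accuracy on real biopsies.

## The benchmark and its problem sizes

The package's evaluation study (`runBenchmark()`) uses 5 grayscale groups
spanning membrane means 75–145 (bins of width 14), 3 training images per
group, 10 test images (2 per group), frames of 128 × 160 pixels, M = 500,
T = 25, D = 9, and a reduced feature set (mean, variance, Sobel,
difference of Gaussians, blur, membrane projections, neighbors at scales
1–8; `benchmarkFeatureConfig()`). These sizes were fixed once as a
desk-scale version of the full setting: large enough that the
grayscale-specialization effect and the full-view model's advantage
emerge clearly, small enough to rerun routinely. The reduced feature set
keeps both absolute-intensity channels (which make zoom-view forests
grayscale-specific) and shift-invariant channels (which the full-view
forest needs).

Two properties are asserted on this benchmark: the heat-map row maximum
falls in the test image's own group ±1 bin for at least 70% of rows, and
the full-view model's mean Jaccard exceeds that of every individual
zoom-view forest. The fusion-ablation ordering mean(V) ≤ mean(V+F) ≤
mean(V+F+I) is asserted with a frozen slack of 0.02: with only five
coarse results the refinement step sometimes neither helps nor hurts, and
adjacent variants can tie to within a few thousandths.

## Known limitations

* Zoom-view fusion degrades when most coarse results are poor — the
  refinement can only discard outliers, not repair a majority of bad
  masks; on such images the full-view candidate is the useful one, which
  is exactly why both candidates are emitted.
* Low-contrast images (contrast comparable to noise) defeat both paths.
* The refinement loop is a reconstruction (see above); alternative
  orderings of filtering and consensus would satisfy the same published
  constraints.
* Feature computation is pure R/EBImage; throughput is adequate for
  hundreds of images, not for volumetric data.
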