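---
title: "Feature-based stitching of microscopy tile grids: methods and design"
author: "gridstitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based stitching of microscopy tile grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-slide imaging acquires a specimen as an M x N grid of overlapping
tiles; a motorized stage steps the field of view by a nominal fraction of
the tile size (typically 10--30% overlap) in a known scan pattern. The
stage is repeatable only to a percent or two of the tile size, so the
tiles must be registered to each other before they can be composed into a
single mosaic. Intensity-based registration (phase correlation, NCC) is
accurate but costly on large grids and fragile under uneven illumination;
`gridstitch` instead registers tiles by matching a small number of
dominant blob features, extracted from a deliberately restricted part of
the overlap, and then resolves the redundant set of pairwise estimates
into a single consistent placement through a weighted graph.

The pipeline has two phases:

1. **Pairwise alignment.** For every tile and its north and west
   neighbour -- `2MN - (M + N)` pairs in total -- estimate the
   translation `(t_x, t_y)` of the neighbour's top-left corner in the
   reference tile's frame. Scaling and rotation are not modelled: a
   calibrated microscope stage translates, and treating the model as a
   pure translation both stabilizes the estimate and lets a single
   matched feature pair generate a hypothesis.
2. **Global alignment.** The pairwise estimates over-determine the
   `MN - 1` placements actually needed, so a weighted graph over tiles is
   built and a spanning structure -- a minimum spanning tree (Prim) or a
   shortest path tree (Dijkstra) -- selects which links to trust;
   positions accumulate along tree edges. Tiles are then pasted into the
   frame with no blending, so any residual misalignment remains visible
   for inspection rather than being feathered away.

## Pairwise registration

### Two-stage restricted-region strategy

Features are first extracted only from a strip whose width is
`strip_fraction` (default **0.05**) of the tile width (west links) or
height (north links). Microscopy tiles are feature-rich, so a 5% strip
normally carries tens of blobs -- enough for a robust translation -- at a
fraction of the cost of processing the whole overlap; shrinking the region
also suppresses false matches from repetitive texture elsewhere in the
overlap. When the strip fails (too few matches, too small a consensus, or
an estimate outside the plausible stage range), the same detect--match--
estimate sequence is retried on the entire nominal overlap region before
the link is declared invalid. Range-filtering the strip estimate *before*
falling back maximizes the chance of recovering a usable link; this
ordering is a design choice the retry diagram leaves open.

The strip is placed just inside the shared tile edge, inset by the
descriptor support radius (about 11 px at the default scales), so that
descriptors for keypoints near the strip boundary sample real tile
content on both tiles rather than replicated border pixels. The
moving-tile search window covers the nominally corresponding strip widened
by the stage slack (2% of the tile dimension per side), so the shared
physical region stays inside both windows for any jitter the stage model
admits.

### Blob detection and descriptors

The detector is a scale-space determinant-of-Hessian (DoH) blob detector:
the tile region is smoothed at scales sigma = 1.2, 1.6, 2.2, 3.0 px, the
scale-normalized Hessian determinant `sigma^4 (L_xx L_yy - L_xy^2)` is
computed by finite differences, and keypoints are strict local maxima over
the 3x3 spatial neighbourhood that also dominate the adjacent scales and
exceed a response threshold. Thresholds follow the conventions of
Hessian-based detectors on a 0--255 intensity scale; the modality presets
are **1000** for bright-field (strong nuclei-scale blobs are plentiful;
keeping only dominant ones cuts matching cost) and **1** for
phase-contrast and fluorescence (flatter images need a permissive
threshold). The strongest 500 keypoints per region are kept.

Each keypoint carries a 64-dimensional descriptor: an 8x8 grid of
intensities sampled bilinearly from the smoothed image at the keypoint's
scale with grid spacing sigma, then mean-subtracted and unit-normalized.
Normalization makes the descriptor exactly invariant to local affine
intensity changes, which is what a smooth multiplicative shading field
looks like at patch scale -- this, not any explicit correction, is why the
pipeline tolerates a shared +-30% vignette (see the shading test and the
acceptance script). Descriptor matching uses nearest neighbour with a 0.8
ratio test and a mutual-best check; the matching criterion is our choice
(standard practice), since only *that* features are matched is inherent to
the method.

### MSAC translation estimation

Each correspondence proposes `(t_x, t_y) = p_ref - p_mov`. Hypotheses are
scored with the MSAC truncated loss `sum(min(r_i^2, tol^2))` with
`tol = 2 px`; the winning hypothesis's inliers are averaged component-wise
for the final sub-pixel estimate. With at most `max_iters = 500`
putative matches -- the usual case by a wide margin -- every hypothesis is
scored, making the estimator exhaustive and deterministic; above that, a
seeded sampler with adaptive stopping at 0.99 confidence takes over. An
estimate is accepted only with at least 3 matches attempted and at least 3
inliers: with a 2-dof model, a 1-point consensus is meaningless and a
2-point one barely better. These numerical choices (tolerance, confidence,
floors) are package decisions; the estimator family is the method's.

### Stage-model filtering

A west-link translation is plausible only if
`t_x` lies in `W(1-o) +- 0.02 W` and `|t_y| <= 0.02 H` (north links swap
axes): the stage cannot be wrong by more than about 2% of a tile. The
interval is closed -- an estimate exactly at the boundary is kept.
Filtered and failed links are set to NA sentinels (`status = "invalid"`);
downstream code branches on the status flag, never on NaN arithmetic.

### Repair of invalid links

Invalid north links take the component-wise mean of the valid north links
whose reference tile is in the same grid row (the row shares one vertical
stage step); if a whole row is invalid, the mean of all valid north links.
West links are repaired symmetrically by reference column. Averages use
only originally valid links, so repair is single-pass and idempotent.
Repaired links keep a sentinel matched count: they are placements of last
resort and must be penalized, not trusted, in the graph. A direction with
no valid links at all is a hard error -- no translation scale for that
axis can be inferred under this rule.

## Global alignment

Edge weights are the **normalized inverse matched-feature count**:
`w = (1/n) / max(1/n)` over finite-count edges, so weights lie in (0, 1]
and the weakest finite edge has weight exactly 1. The normalization
constant is our reading of "normalized" -- it bounds finite weights, which
in turn makes the penalty rule well defined. Sentinel-count edges get the
maximum finite weight plus a constant `c = 1` (configurable): strictly
heavier than any finite edge, so penalty edges enter the tree only where
no textured route exists (e.g. around background tiles).

Prim's MST minimizes the total weight of the selected links; Dijkstra's
SPT instead minimizes each tile's accumulated path weight to an origin
vertex, chosen as the vertex minimizing the sum of shortest-path weights
to all others (ties broken by smallest (row, col)) so the choice is not
arbitrary. Both use lexicographic tie-breaks so results are reproducible.
Positions accumulate edge translations along tree edges from the root and
are shifted so `min x = min y = 0`. With exact link translations the two
trees give identical, exactly correct positions; they differ only in how
estimation error propagates.

## Mosaic composition and metrics

Positions are rounded to integer pixels and tiles pasted in row-major scan
order, later tiles overwriting earlier ones; no interpolation, no
blending. Rounding rather than resampling keeps noiseless synthetic grids
bit-identical to their source image.

* **Overlap RMSE**: for every grid-adjacent pair, the RMSE of the two
  tiles' intensities (normalized to [0, 1]) over the intersection of
  their placed rectangles, averaged over pairs; pairs with empty
  intersection are excluded and counted, and an all-empty result is NA --
  the signature of a stitch where neighbours ended up disjoint.
* **D_err**: mean Euclidean distance between stitched and ground-truth
  tile centroids, both position sets normalized to a (0, 0) origin.
  Centroids are measured in the composed frame, where tiles sit at
  integer pixels, so an error-free integer placement reports exactly 0.
* **MSE / PSNR** against the source image; images of unequal size are
  cropped to the top-left-aligned common region (with a warning) first,
  and PSNR is infinite exactly when MSE is 0.

## The synthetic-data generator

The generator cuts a ground-truthed grid out of a single source image, so
true tile positions are known by construction.

* **Textured source** (`generate_texture_image`): smoothed random
  background plus a dense scatter (about one per 64 px^2) of small
  bright/dark Gaussian blobs of radius 1.3--2.4 px and contrast 0.5--0.9,
  emulating the nuclei-scale structure of histology at a density that
  guarantees dozens of detectable blobs in a 5% strip.
* **Binary bar-target source** (`generate_usaf_pattern`): deterministic
  three-bar elements at several bar widths plus square markers, clustered
  centrally with 18% empty margins -- high-contrast corners inside, and
  guaranteed featureless overlaps for border tiles, which forces the
  invalid-link repair path.
* **Splitting** (`split_image_to_grid`): tile (r, c) is cropped at its
  nominal position `(c W(1-o), r H(1-o))` plus independent uniform
  *integer* jitter per axis (integer so ground truth stays exact under
  pixel rounding); then a shading gain field -- identical on every tile,
  i.e. fixed-pattern vignetting, the hard case for intensity-based
  methods -- then additive Gaussian noise; designated background tiles are
  replaced by the source's median level.

What the generator does *not* emulate: optical distortion, focus
variation across the slide, stage rotation, chromatic effects, and
content-dependent deformation. Passing tests on synthetic grids therefore
demonstrates the geometric and graph machinery and the feature pipeline's
robustness to the modelled nuisances (jitter, noise, shading), not
performance on every real acquisition artefact.

## Problem sizes and defaults used in the shipped checks

The package's own verification uses a 10 x 10 grid of 200 x 200 px tiles
at 30% overlap for the zero-error and bar-target scenarios, and a 5 x 5
grid of 512 x 512 px tiles at 25% overlap with +-5 px jitter and 1% noise
for the jitter/shading scenarios. Tile sizes are chosen so the scenarios
are internally consistent: with +-5 px per-tile jitter, relative offsets
between neighbours reach +-10 px, and the 2% stage window must contain
them, which requires tiles of at least 500 px; 512 px gives a +-10.24 px
window. The smaller tiles of the 10 x 10 scenarios keep a full two-graph
run comfortably under a couple of minutes on one core while still carrying
more than 50 blobs per strip.

## Known limitations

* Translation-only: stages with measurable rotation need a different
  model.
* The repair rule assumes each row/column shares its stage step; a stage
  with drift *within* a row violates that assumption.
* Very feature-poor modalities may fail both stages on many links; the
  pipeline then leans on repair and penalty edges, and accuracy degrades
  toward nominal-grid placement.
* Keypoints are localized to integer pixels (no sub-pixel refinement of
  maxima); sub-pixel accuracy comes from averaging inlier displacements,
  which in practice lands well within 0.1 px of the truth on textured
  pairs but is bounded by it on nearly featureless ones.
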