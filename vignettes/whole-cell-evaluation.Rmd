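---
title: "Whole-cell segmentation from transcript density: models, conventions and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-cell segmentation from transcript density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txseg)
```

## The segmentation problem

Image-based spatial transcriptomics measures two things at once: the
coordinates (in µm) of individual decoded RNA molecules, and fluorescence
images — usually only a DAPI nuclear stain. Whole-cell boundaries must be
inferred. The two segmentation routes this package implements and
evaluates are:

1. **Nuclear expansion** (the platform default): segment nuclei, then
   grow each nuclear mask uniformly by a fixed distance (5 µm by
   convention) unless it would run into a neighbouring cell's territory.
2. **Transcript-density fusion**: convert the molecule coordinates into a
   pseudoimage by summing an isotropic Gaussian kernel at every retained
   molecule, and feed it together with the normalized DAPI image to an
   instance-segmentation model as a two-channel input.

The package's job is the full data path around route 2 (input
construction, tiling, training-pair export, backend contract) plus an
exact implementation of route 1 as the baseline, plus the complete
evaluation stack that compares any predicted mask to a reference.

## The transcript-density pseudoimage

With molecule locations $x_i \in \mathbb{R}^2$, the density at a pixel
centre $u$ is

$$f(u) = \sum_{i=1}^{N} \exp\!\left(-\frac{\lVert u - x_i\rVert^2}{2\sigma^2}\right).$$

Decisions behind the implementation:

* **σ is interpreted in pixels** (default 2.5). The spread parameter is
  dimensionally ambiguous in common usage; a kernel placed on "the pixel
  grid" reads most naturally in pixel units, and the alternative is one
  flag away (`sigma_units = "um"`, converted through the frame's pixel
  size).
* **Kernels are truncated at 4σ by default** (radial cutoff), bounding the
  per-molecule error by $e^{-8}$ and making the cost linear in $N$. The
  truncation radius is configurable, and the test suite holds the fast
  path within $10^{-6}$ of the exact $O(N \cdot \text{pixels})$ sum.
* **Scaling is per image**: the density map is min–max scaled to $[0,1]$
  per tile, matching the way tiles are fed to a model independently. A
  constant (e.g. empty) image scales to all zeros, not 0.5, so empty
  tiles stay empty.
* **DAPI normalization** caps at the image-wide 99th percentile
  (R's default type-7 quantile) and divides by it; an all-zero image maps
  to zeros rather than erroring.
* Quality control retains molecules with Q-score ≥ 20 (inclusive
  threshold). Density maps can apply the same threshold themselves via
  `density_params(qv_min = )`.

## Coordinates

Global coordinates are µm, y-down, origin at the frame's top-left corner.
Pixel $(r, c)$ (1-based, row = y) covers the half-open box
$[x_0 + (c-1)s,\, x_0 + cs) \times [y_0 + (r-1)s,\, y_0 + rs)$ with $s$
the pixel size (default 0.2125 µm/px, the Xenium mosaic convention;
always configurable). Half-open boxes make molecule binning unambiguous:
tiling a frame partitions its transcripts exactly, which the tests assert.
`px_to_um()` returns pixel centres. The frame origin is configurable so
either global or tile-local coordinates can be rasterized.

## Nuclear expansion as a nearest-nucleus rule

"Grow by $d$ µm unless you hit a neighbour" is formalized as: a background
pixel joins the nucleus whose pixel set is nearest (Euclidean,
pixel-centre to pixel-centre) provided that distance is ≤ $d$; expansion
fronts therefore meet midway, a Voronoi-style constraint. Exact ties go to
the smaller label so results are reproducible. Sub-pixel distance-transform
refinements were rejected deliberately: the chosen rule is checkable
against an exhaustive per-pixel oracle, and the tests verify exact
pixel-for-pixel agreement on randomized masks. The collision behaviour of
the platform's own pipeline is not published in detail; the nearest-nucleus
rule is this package's documented approximation.

## Evaluation stack

* **Image IoU**: from the ground-truth × predicted overlap matrix
  $\mathrm{IoU}(i,j) = |G_i \cap P_j| / |G_i \cup P_j|$, each predicted
  cell scores its column maximum and a tile scores the unweighted mean
  over predicted cells. Predicted cells with no overlap contribute 0
  (max over an all-zero column); a tile with no predictions has an
  undefined mean, is flagged, and is excluded from across-tile averages.
* **Gene IoU**: the identical construction on per-cell transcript index
  sets, after quality filtering. Predicted cells with zero assigned
  molecules are excluded from the tile mean (∅/∅ is undefined) and
  reported separately — a deliberate asymmetry with image IoU, where
  empty pixel sets cannot occur.
* **Alignment**: one-to-one pairs requiring IoU ≥ 0.3 *and* mutual
  best-match status in both directions. Argmax ties break toward the
  smaller label and are counted in an attribute; on continuous data they
  have probability zero, but deterministic tie-breaks keep tests
  reproducible.
* Dataset-level summaries are unweighted means over tiles, not pooled
  over cells.

## Morphometrics

Eight descriptors are computed from each cell's boundary polygon: area
(shoelace), perimeter, Feret diameter (max pairwise hull-vertex
distance), eccentricity ($1 - \lambda_2/\lambda_1$ from a PCA of the raw
vertex coordinates), roundness (area over minimum-enclosing-circle area),
circularity ($4\pi A/P^2$), solidity (area over convex-hull area) and
aspect ratio (long/short side of the minimum-area rotated bounding
rectangle, normalized to ≥ 1 so larger always means more elongated).

Numerical choices worth knowing:

* **Mask-to-polygon tracing follows pixel corners**, so polygon area
  equals pixel count × pixel-size² exactly — mask-based and polygon-based
  areas can never disagree. Interior holes are ignored (outer contour
  only) and diagonal pinch points are traversed without splitting the
  loop. Marching-squares-style smoothed contours were rejected because
  they break the exact area identity. Perimeters are therefore
  staircase perimeters; they are consistent between methods being
  compared, which is what the evaluation needs.
* **The minimum enclosing circle is exact** (Welzl's algorithm over hull
  points with a deterministic insertion order); roundness anchors such as
  the unit square's $2/\pi$ depend on exactness, and tests verify the
  ≤ 3-point support certificate.
* **The minimum-area rectangle** uses rotating calipers (one side
  collinear with a hull edge). For triangular hulls every edge ties at
  area $2A$, so the side *pair* is not unique even though the area is;
  the tie is resolved deterministically by edge order and the tests
  compare the minimized area, accepting any tied orientation.
* **Eccentricity uses the raw vertex coordinates**, as defined — vertex
  density therefore influences the estimate. Collinear-vertex degeneracy
  ($\lambda_2 = 0$) returns the boundary value 1.
* Degenerate polygons (zero area, zero-width rectangles) raise errors
  rather than returning NaN.

## Clustering and classification

Count matrices are restricted to aligned cells, library-size normalized
to the median library, `log1p`-transformed, reduced by PCA (≤ 50
components) and clustered with Leiden on a kNN graph (k = 15). The
resolution is tuned by bisection on $[0.01, 3]$ with at most 40
evaluations, caching every (resolution, k) pair; the target cluster
count relaxes from $k$ to $k \pm 1$ to $k \pm 2$ before erroring with the
full trace. Cluster-count is only approximately monotone in resolution —
the cache makes the search robust to non-monotone blips. PCA depth, kNN
size and the normalization target are ecosystem defaults (they are not
prescribed by the evaluation protocol) and all are arguments.

Agreement uses ARI, AMI (arithmetic normalization, exact hypergeometric
expected-MI), homogeneity and completeness computed from the contingency
table; no installed R package provides the last three, so all four are
implemented here and cross-checked in the tests against an independent
entropy-based oracle (and ARI against a second package).

The morphology classifier follows a fixed protocol: drop
unknown/unassigned cells, keep the five most abundant types, stratified
~80/20 split, random forest with 500 trees and class weights inversely
proportional to training-class frequency. All reported metrics
(accuracy, macro-F1, macro ROC-AUC) are pure functions of the held-out
predictions; ROC-AUC is the Mann–Whitney statistic with midrank ties,
identical to the trapezoidal ROC area with tied scores averaged.

## What the simulator emulates — and what it does not

`simulate_tissue()` provides the ground truth every stage is tested
against. It reproduces the geometric regime in which fixed-distance
expansion fails:

* contiguous, space-partitioning, non-circular cells (perturbed
  anisotropic metric balls around blue-noise seeds) with per-type
  elongation up to 3:1 by default;
* nuclei covering ~35% of their cell's area, offset from the cell
  centroid by a configurable fraction of the local radius and clipped to
  the cell;
* per-cell Poisson molecule counts (mean 80) placed uniformly over the
  cell's pixel set — so every cell molecule is inside its cell's mask by
  construction — with genes drawn from sparse per-type Dirichlet
  profiles and high quality scores;
* a background molecule population (0.05 /µm²) with mostly sub-20
  quality scores, so the Q ≥ 20 filter removes most but not all noise;
* DAPI as the blurred, noisy rendering of the nucleus image.

Default sizes (a 384² px, 0.5 µm/px patch with 120 cells and 5 types)
keep a full pipeline run under ten seconds on one CPU; tests use smaller
patches (224² px, 40 cells) and the clustering recovery check uses 1,000
cells with 10 planted programs. These sizes are the package's chosen
desk-scale study conditions, stated here so results are interpretable.

The simulator deliberately omits: optics (no PSF; blur + noise only),
3-D structure, gene-specific subcellular localization (the density map
ignores gene identity by design, for cross-panel generality), segmented
nuclei errors (nuclear masks are exact), and realistic platform noise
models for DAPI, which are not publicly specified. Passing tests
therefore demonstrate correctness of the algorithms and the expected
*ordering* of methods in this regime — not absolute accuracy figures on
real tissue, which depend on trained model weights and data this package
does not ship.

Because the demo tissue has 5 types, `default_config()` targets 5
clusters; `cluster_cells()` itself defaults to the conventional target
of 10.

## Known limitations

* The external-model backend is a contract plus a training-pair
  exporter; no learned weights are included, and the classical fallback
  segmenter makes no accuracy claims beyond exercising the stack.
* Label masks are written as 16-bit TIFF (≤ 65,535 instances per frame).
* Pixel size and origin travel in a JSON sidecar next to each TIFF, not
  in TIFF tags.
* `gene_iou()` sees only assignment vectors; cells with zero molecules
  are invisible to it unless the caller passes the mask's label set.
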