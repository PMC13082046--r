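# txseg

Whole-cell segmentation and evaluation for image-based spatial
transcriptomics.

## The problem

Image-based spatial transcriptomics platforms (Xenium and its relatives)
report the coordinates of individual RNA molecules together with a DAPI
nuclear stain. Most downstream analysis — building single-cell count
matrices, typing cells, studying cell morphology — needs *whole-cell*
boundaries, but DAPI shows only nuclei. The standard workaround, expanding
every nuclear mask by a fixed distance until it hits a neighbour, produces
round, oversized cells and misassigns cytoplasmic transcripts.

A better route exploits the fact that transcripts themselves mark cellular
extent: rasterize the molecules into a **transcript-density pseudoimage**

```
f(u) = Σ_i exp( −‖u − x_i‖² / (2σ²) ),   σ = 2.5 px
```

(one isotropic Gaussian per detected molecule, summed on the pixel grid),
scale it to [0, 1], and pair it with the 99th-percentile-normalized DAPI
image as a two-channel input for an instance-segmentation model. `txseg`
implements that data path and everything needed to evaluate it:

* **IO / spatial model** — Xenium-dialect and generic transcript tables
  (CSV/parquet), integer TIFF label masks and float TIFF intensity images
  with JSON sidecars, GeoJSON boundary polygons, half-open µm↔pixel
  coordinate conventions, tile cropping.
* **Pseudoimages** — quality filtering (Q-score ≥ 20), density maps with a
  truncated fast path guarded by an exact-sum oracle, channel stacking.
* **Segmenters** — the 5 µm boundary-constrained nuclear-expansion
  baseline (nearest-nucleus rule, exact to the pixel), a deterministic
  classical fallback (Otsu + seeded propagation) so the pipeline runs
  without trained weights, and a backend adapter for external models plus
  a training-pair exporter.
* **Evaluation** — image IoU (per-predicted-cell max over ground truth,
  averaged per tile), gene IoU (the same construction on per-cell
  transcript sets), and one-to-one mutual-best-match cell alignment at
  IoU ≥ 0.3.
* **Downstream** — cell-by-gene count matrices, Leiden clustering tuned by
  resolution bisection to a target cluster number (with the 10 → 9/11 →
  8/12 relaxation), ARI/AMI/homogeneity/completeness, eight polygon
  morphometrics (area, perimeter, Feret diameter, eccentricity, roundness,
  circularity, solidity, aspect ratio), UMAP morphology embeddings, and a
  random-forest cell-type classifier reported with accuracy / macro-F1 /
  macro ROC-AUC.
* **Simulator** — synthetic tissues with known cell and nucleus masks,
  cell types, expression profiles and background noise, so the entire
  stack is testable end-to-end with no external data.

## Worked example

```r
library(txseg)
report <- run_pipeline(default_config(seed = 1))
print(report)
#> <pipeline_report> 120 truth / 120 predicted cells
#>   image IoU 0.6105 | gene IoU 0.8384 | aligned 120
#>   clustering k = 5, ARI 1.000, AMI 1.000
#>   morphology RF: acc 0.600, macro-F1 0.573, macro-AUC 0.878
```

This simulates a 192 µm tissue patch (120 cells, 5 types), segments it
with the 5 µm nuclear-expansion baseline, and scores the result against
the known truth. The expansion baseline reaches an image IoU of 0.61 —
its boundaries systematically overshoot elongated cells — while its
transcript assignment is better (gene IoU 0.84) because most molecules
sit near nuclei. All 120 predicted cells align one-to-one with truth
cells, and clustering their count matrix recovers the 5 planted
expression programs exactly (ARI 1.0). The morphology classifier,
working from shape alone, separates the five types well above the 0.2
chance level. Swap `segmenter = "fallback"` into the config to score the
built-in classical segmenter instead, or drive individual stages through
the functions above; `inst/scripts/txseg.R` exposes the same stages as
shell subcommands.

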