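---
title: "Segmentation-free cell-type mapping: model, parameters and validation design"
author: "segfree authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-free cell-type mapping: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segfree)
```

## The problem

In situ capture spatial transcriptomics platforms such as Stereo-seq record
transcriptome-wide molecule counts on a sub-micron grid of barcoded spots.
At that pitch a single pixel rarely carries more than one molecule, so
per-pixel expression vectors are far too sparse to classify directly, and
the classical remedy — segmenting cells from a nuclear stain and pooling
counts per cell — fails wherever segmentation fails (anuclear erythrocytes,
dense neuropil, poor staining). `segfree` sidesteps segmentation entirely:
it models expression as a smooth field over the pixel grid and classifies
every pixel independently, producing a cell-type map at the native
resolution of the platform together with a per-pixel confidence.

## The model

**Gene expression density.** For each gene, molecule counts binned to the
pixel grid are smoothed by kernel density estimation. Because both the data
and the estimate live on the same discrete grid, the kernel is evaluated
once into a small odd-sided *mask* of weights and the KDE reduces to adding
the count-scaled mask around every nonzero pixel — the cost scales with the
number of nonzero pixels, not with the grid area. Two kernel families are
provided: Gaussian (weight `exp(-d²/2h²)` at pixel distance `d`, cropped at
`t·h`, default `t = 2`) and Epanechnikov (`1 - (d/h)²`, whose support ends
naturally at `h`, so no truncation choice arises).

We normalise every mask to unit sum rather than carrying the `1/N`
prefactor of a probability-density estimate. Downstream classification is
scale-invariant (cosine similarity) and thresholds are user-set, so this
changes no result; it buys a useful conservation law — the total-mRNA KDE
sums exactly to the molecule count for interior-supported data — which the
test suite exploits.

**Cell-type assignment.** Each pixel's KDE vector `p` (over the genes
shared between data and signatures) is compared to each cell-type signature
by cosine similarity, `Sc(p, s) = p·s / (‖p‖‖s‖)`, and the most similar
type is assigned.

**Assignment score.** The raw gap between the best and second-best cosine
is a poor confidence measure because it conflates pixel ambiguity with
signature similarity: two nearly identical signatures can never produce a
large gap. The assignment score therefore rescales the gap by its analytic
maximum given those two signatures,

```
AS = (Sc(p,a) - Sc(p,b)) / max_x (Sc(x,a) - Sc(x,b)),
```

where the maximum is over non-negative expression vectors `x`. With
unit-normalised signatures the gap equals `x/‖x‖ · (a - b)`, linear in the
direction of `x`, so it is maximised by the colinear direction with
negative coordinates clipped to zero (expression cannot be negative):
`max_x = ‖(a - b)₊‖₂`. The score is 1 when the pixel sits as far from the
runner-up as any non-negative vector could, and 0 when the two best types
are tied. Signatures are L2-normalised internally before the bound is
computed — the displayed formula is then exact for signatures of any scale,
since cosine itself is scale-free.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `binsize` | 1 | bead units per pixel when reading; 1 = native resolution |
| `bandwidth` | 8 px | kernel scale `h`; may be given in µm and converted via the grid resolution (8 px = 4 µm at 500 nm/px) |
| `truncation` | 2 | Gaussian mask radius in bandwidths; larger keeps more mass but costs quadratically |
| `chunk_size` | 500 | side of the processing windows; affects memory only, never results (windows are padded by the kernel radius) |
| `min_dist` | 4 px | minimum Chebyshev separation of sampled local maxima |
| `min_area` | 60 px | minimum above-zero connected-component area around a maximum; suppresses specks |
| `global_threshold` | 0 | total-mRNA KDE level below which pixels are relabelled background |

Bandwidth is the one genuinely scientific knob: it should be of the order
of the cell radius in pixels. Too small starves each pixel of molecules;
too large bleeds expression across cell boundaries (visible as depressed
assignment scores along interfaces).

## Numerical and design choices

* **Boundary handling** is zero padding: positions outside the capture area
  contribute no molecules. Mass near borders is consequently lost, never
  invented.
* **Background**: a pixel whose KDE vector is identically zero (no molecule
  of any shared gene within the kernel radius) cannot be classified; it
  carries the sentinel `-1` and `NA` cosine/score, so score statistics
  never silently include background. Additional background filtering by
  total-mRNA thresholds (global and per-type) is a separate, explicit step.
* **Ties** in the argmax go to the earlier signature column; local-maxima
  plateaus contribute their lowest (row, column) pixel. Both rules make
  outputs deterministic.
* **Score clamping**: floating-point round-off can push a score marginally
  outside [0, 1]; values are clamped, as the derivation bounds the exact
  quantity.
* **Chunked processing** tiles the grid in `chunk_size` windows padded by
  the kernel radius. Within a window, mask contributions are accumulated in
  the sparse storage order of the whole grid, so windowed and whole-grid
  evaluation agree bitwise on the KDE and the test suite checks invariance
  of labels and scores to the tiling.
* **Shared-gene convention**: signature genes absent from the data are
  dropped with a warning rather than treated as zero rows, which would bias
  cosines toward sparse signatures. Data genes absent from the signatures
  are simply unused.
* **Signature extraction at maxima** uses KDE values (the smoothed field
  the maxima were found in), with a raw-count option.
* **Local maxima neighborhoods** use the Chebyshev (square) metric, which
  matches the square mask geometry and makes `min_dist` an integer pixel
  radius; the area rule is applied to the 8-connected above-zero component
  containing the maximum.
* **Indexing**: all R-facing pixel coordinates are 1-based, as usual for R
  matrices; binning is `floor((y - y_min)/binsize)` with the origin at the
  observed minimum, rows corresponding to y and columns to x. The `labels`
  grid is a *coded* image: integer codes `0 .. k-1` in `celltype_names`
  order plus `-1` for background (image exports shift by +1, recorded in
  the legend).
* **Exports**: the local-maxima expression matrix is written as
  MatrixMarket + TSV sidecars (the standard single-cell exchange layout)
  with full `%.17g` precision so round-trips are bitwise; label grids go to
  16-bit TIFF losslessly, score/cosine to 32-bit float TIFF.

## The synthetic-tissue generator

`simulate_tissue()` reproduces the validation design used for
segmentation-free classifiers: cell centers placed uniformly at random on a
square grid (default 625 centers on 500 × 500), cell outlines defined by
their Voronoi diagram, one cell type per cell drawn from the abundance
vector, per-spot counts drawn as Poisson with the type's mean profile, and
exactly `round(0.2 · n_spots)` spots zeroed uniformly at random to model
capture dropout. Ground truth is per spot, because evaluation is per spot.

The published validation drew mean profiles from mouse-kidney single-cell
data; to stay self-contained the generator instead ships
`make_type_profiles()`: 100 genes, 9 types, log-normal marker means with a
2% cross-type leak (pairwise cosine similarity ≪ 0.2, i.e. near-orthogonal
types), each column scaled to a mean total of 1.0 transcript per spot — a
realistic density for sub-micron in situ capture data. These defaults were
fixed once, from first principles, as the package's study conditions.

What the simulation does *not* emulate: platform noise such as bead-pitch
jitter, lateral diffusion, barcode errors, spatially varying capture
efficiency, or transcriptional gradients within a type. Passing the
simulation study therefore demonstrates the statistical machinery —
smoothing, classification, score calibration — under the stated generative
model, not robustness to every artefact of real tissue.

## Validation summary

The test suite validates the pipeline four independent ways, at problem
sizes chosen to keep the default run in minutes:

* dual-route equivalence: on random grids up to 30 × 30 with up to 5 genes
  and 4 signatures, the full chunked sparse pipeline matches a naive dense
  reimplementation (direct summation over molecules, per-pixel cosine
  loops) to 1e-9, for both kernel families;
* the assignment-score bound is checked against 10⁵ random signature/pixel
  triples and against brute-force constrained maximisation;
* conservation, linearity, translation-equivariance and chunking-invariance
  properties of the KDE;
* a 20-replicate simulation study at the full validation geometry
  (500 × 500, 625 cells, 9 types, 20% dropout, Gaussian bandwidth 5
  truncated at 2 bandwidths): assigned-pixel accuracy above 0.9 in every
  replicate, and above-median-score pixels are systematically more accurate
  than below-median ones — the property that makes the score map useful as
  a confidence readout. `scripts/acceptance.R` recomputes these quantities
  from scratch.

## A complete run

```{r example, eval = FALSE}
library(segfree)

sim <- simulate_tissue(grid_size = 500, n_cells = 625,
                       zero_inflation = 0.2, seed = 11)
kernel <- gaussian_kernel(5, truncation = 2)
map <- assign_celltypes(sim$grid, sim$profiles, kernel)
map

acc <- evaluate_accuracy(map, sim)                 # all assigned pixels
attr(acc, "overall")
acc_hi <- evaluate_accuracy(map, sim, 0.5)         # above-median score
attr(acc_hi, "overall")

# de novo signatures: sample pseudo-cells at density peaks, cluster
# externally, average
peaks <- find_local_maxima(total_mrna_kde(sim$grid, kernel),
                           min_dist = 4, min_area = 60)
expr <- extract_expression(sim$grid, peaks, kernel)
export_maxima_matrix(expr, "maxima_out")           # MTX + TSV for scanpy et al.
```

## Known limitations

* Each pixel receives exactly one label: no mixture decomposition, so a
  pixel straddling two cells is assigned the locally dominant type (the
  score dips there, which is the intended diagnostic).
* No spatial regularisation of the label map; salt-and-pepper noise in
  low-density regions should be handled by background thresholds or
  downstream region filtering (`labeled_regions()`).
* De novo signature building delegates clustering (e.g. Leiden on a
  neighbor graph) to dedicated single-cell frameworks; the package exports
  and imports the interface matrices.
* 2D only; z-stacks or serial sections are out of scope.
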