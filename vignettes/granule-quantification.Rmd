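---
title: "Quantifying mitochondrial RNA-granule imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial RNA-granule imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulemap)
```

## The measurement problem

Mitochondrial RNA granules (MRGs) are punctate ribonucleoprotein foci on
the mitochondrial network; nascent transcripts (detected by BrU pulse
labelling) and double-stranded RNA (detected by anti-dsRNA antibodies)
form overlapping but distinct populations of such foci. Three questions
recur when imaging them:

1. **Object-based colocalization.** For each focus in a query channel,
   what fraction of its area is covered by foci of a reference channel,
   and is the overlap *complete*, *partial* or *absent*?
2. **Abundance.** How many foci per μm² of mitochondrial network does each
   cell carry, and how bright is the signal per cell (mean over the
   network, integrated over the cytoplasm)?
3. **Context.** How do these quantities distribute across cell-cycle
   phases called from DAPI, EdU and cyclin-A channels?

granulemap implements this pipeline over calibrated multi-channel 2D
frames, plus a synthetic-frame generator with full ground truth so every
stage can be validated quantitatively rather than by eye.

## Pipeline model

**Masking.** The mitochondrial channel is optionally preprocessed with an
unsharp mask, `(I - w G_r(I)) / (1 - w)` (defaults `r = 100` px,
`w = 0.7`, the common Fiji recipe), then thresholded. Thresholding is
Otsu's method on a 256-bin histogram by default, with an absolute
override; the applied threshold is always logged, because a reproducible
record of a manual-style threshold is the first thing a reviewer asks
for. Components smaller than `min_size` (default 4 px) are discarded as
shot noise.

**Foci.** Foci are 8-connected components of the thresholded foci
channel. Each focus is filtered for containment in the mitochondrial mask
under one of three rules — centroid inside (default), majority of pixels
inside, or any pixel inside. The phrase "lies within the mask" is
genuinely ambiguous at rasterized boundaries, so all three rules are
implemented and the applied rule is logged; on the synthetic frames the
choice is immaterial because planted foci are fully interior.

**Shape.** Area is the exact pixel count times `pixel_size²`. Axis
lengths come from the ellipse with the same second central moments as the
pixel set (`4·sqrt(eigenvalue)` pixels, the regionprops convention), and
eccentricity is `sqrt(1 − λ₂/λ₁)`. Degenerate sets are handled
explicitly: a single-pixel focus gets one-pixel axes and eccentricity 0;
a collinear set gets a one-pixel minor axis. Both are flagged.

**Overlap.** The overlap of a query focus is the pixel-exact intersection
of its pixel set with the union of all reference foci, expressed as a
percentage of the query focus's own area. The union convention means a
focus straddling two reference foci accumulates both; the asymmetric
denominator answers "how much of *this* granule is covered". Categories:
`none` at exactly zero intersection, `complete` at ≥ 99% (the 1%
tolerance absorbs single boundary pixels lost to rasterization — a strict
100% cutoff is fragile and the completeness of a biological overlap is
not defined to sub-pixel precision), `partial` in between; any nonzero
intersection counts as partial, with no minimum-pixel floor. Both the
tolerance and the floor are configurable.

**Per-cell metrics.** Cells are grown from segmented nuclei over a
cell-body mask by seeded propagation (each body pixel joins its nearest
nucleus, splitting touching cells along the distance watershed). Foci
belong to the cell containing their centroid; foci outside all cells are
dropped and counted in the log. Density is foci count over the cell's
mitochondrial area in μm²; "cytoplasmic area" is the whole-cell mask
minus the nucleus (configurable to whole-cell). Integrated intensity sums
raw pixels and is exactly additive over partitions.

**Phase calling.** EdU marks S phase, cyclin-A accumulates through S and
G2, DAPI marks any nucleus. Since cyclin-A is positive in S as well as
G2, the decision order must let EdU dominate: **S** if mean nuclear EdU ≥
cutoff, else **G2** if mean cyclin-A (whole-cell by default, nuclear
optionally) ≥ cutoff, else **G1** if nuclear DAPI is detectable, else
unassigned. Cutoffs default to 1D Otsu on the per-cell marker means — the
algorithmic stand-in for visual gating — with absolute overrides.

## The synthetic generator

`generate_frame()` renders frames whose every object is known:

* **Network** — union of persistent random-walk tubes dilated to
  `tube_width`, grown until coverage reaches `network_density`. Walk
  length is scaled so each walk adds ≈ 8% of the target, keeping the
  final coverage well inside ±20% of the request. This reproduces the
  tubular topology of TOMM20/MitoTracker staining without attempting
  biophysical realism.
* **Foci** — each focus is the set of exactly *n* pixels nearest a
  centre, giving pixel-exact planted areas; areas are lognormal with the
  requested mean and CV. Defaults calibrate the two foci channels to
  mean areas of 0.019 μm² (query) and 0.017 μm² (reference) at
  0.02 μm/px, matching measured MRG-scale granules at super-resolution
  sampling. Overlap categories are planted by construction:
  *complete* foci are carved as exact pixel subsets of a dedicated,
  sufficiently larger reference focus; *partial* foci are slid off a
  reference focus by bisection on the pixel-exact intersection fraction
  until it lands in `partial_overlap_range`; *none* foci stay clear of a
  safety margin around every reference focus. Category counts follow
  largest-remainder rounding of the composition, so they are
  deterministic and sum exactly.
* **Cells and markers** — disjoint disk cells with disk nuclei; phases
  apportioned by largest remainder of `phase_mix` (default G1 0.5 / S
  0.3 / G2 0.2, a typical unsynchronised HeLa distribution). Per-cell
  marker levels are drawn from normals truncated at ±2.5 SD — antibody
  staining of a gated population has bounded spread, and the truncation
  makes "populations separated by a wide margin" literally separable.
  The `sd` field sets the population SD; a *separation of k SD* in the
  tests means each population mean sits `k·sd` from the midpoint cutoff.
* **Optics and noise** — Gaussian PSF blur (`psf_sigma`, default 0.03 μm
  in the super-resolution regime, 0.1 μm in the per-cell preset), then
  scaled-Poisson shot noise plus Gaussian read noise (defaults give peak
  SNR ≈ 10), then rounding to integer detector units. Truth tables
  describe the rasters *before* blur and noise.

Two regimes mirror the two kinds of experiment: `generator_params()`
defaults to the 512² px, 0.02 μm/px foci regime; `cell_frame_params()`
gives the 0.1 μm/px per-cell regime with wider tubes, larger
diffraction-limited foci (0.15 μm² mean — individual MRGs are not
resolved at confocal sampling) and whole cells (nucleus 3 μm, cell
7.5 μm radius — compact, so a dozen cells fit a desk-scale frame).

What the generator does **not** emulate: uneven illumination,
out-of-focus haze from 3D structure, chromatic shift between channels,
clustered or touching foci, non-disk cell shapes, intensity gradients
within foci. Passing recovery tests therefore shows the *measurement*
machinery is correct, not that segmentation of difficult real data is
solved; on real frames thresholds remain the user's responsibility and
are logged for that reason.

## Numerical choices

* Coordinates are 0-based in concept but stored as R's 1-based (row,
  col) with pixel-centre convention; centroids are unweighted means of
  member pixel centres, and the "centroid pixel" is the rounded centroid
  clamped into the frame.
* 8-connectivity for labelling (two foci touching only at a corner are
  one object), implemented as a 4-connected pass plus union-find over
  diagonal label adjacencies; final labels follow column-major scan
  order, so labelling is deterministic.
* Otsu on images scans a 256-bin histogram; Otsu on per-cell marker
  vectors scans every midpoint between order statistics. Degenerate
  histograms (constant nonzero image) are an error rather than a silent
  threshold; an all-zero image yields an empty mask without error.
* Gaussian smoothing caps its kernel at the image size, so the large
  default unsharp radius behaves as background estimation instead of
  erroring on small frames.
* The generator enforces a minimum inter-focus separation (≥ 4 px,
  scaled up with the PSF) within each channel so that blur and noise
  cannot merge planted foci; without it, count recovery would measure
  crowding artefacts rather than pipeline correctness.
* All generator randomness runs under `withr::with_seed(seed)`: the same
  parameters give bit-identical frames, truth tables, and (through the
  pipeline) byte-identical CSVs. Config hashes exclude the output
  directory so provenance does not depend on where results land.

## Problem sizes used in validation

The automated checks run entirely on generated data at desk scale:
512² px frames with 100 + 100 foci for colocalization recovery (10 seeds,
noiseless and at default noise), a 768² px frame with 200 foci for area
calibration, 1280² px frames with 20 cells × 10 seeds per marker-gating
regime for phase calling, and a 768² px 6-cell frame for density and
intensity recovery. These sizes keep each property measurable with
comfortable statistical margin while a full run stays in the minutes
range on one CPU.

## Known limitations

* 2D only; no z-stacks, deconvolution, drift or flat-field correction.
* Object-based overlap only — no Pearson/Manders pixel-correlation
  colocalization and no nearest-neighbour distance association.
* Descriptive group summaries (n, mean, sample SD) only; inferential
  statistics are left to downstream tools.
* The cell-body partition assumes nuclei are reliable seeds; anucleate
  fragments are never assigned a cell.
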