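# granulemap

Object-based colocalization and per-cell quantification for fluorescence
microscopy of mitochondrial RNA granules.

Mitochondrial RNA granules (MRGs) appear as sub-diffraction puncta on the
tubular mitochondrial network. Experiments that pulse-label nascent RNA
(BrU) alongside double-stranded-RNA immunostaining ask, focus by focus,
how much of each granule is covered by the other marker; experiments at
confocal scale ask how many foci each cell carries per μm² of
mitochondria, how bright the signal is per cell, and how that varies with
cell-cycle phase (DAPI / EdU / cyclin-A gating). granulemap is for
microscopists and image analysts who need those numbers reproducibly from
multi-channel 2D TIFFs — with every threshold logged — rather than from
one-off notebook scripts.

## What it computes

For a query focus \(Q\) (an 8-connected set of above-threshold pixels,
containment-filtered against the mitochondrial mask \(M\)) and reference
foci \(R_1,\dots,R_k\):

* **overlap fraction** \(\omega(Q) = 100\,\frac{|Q \cap \bigcup_i R_i|}{|Q|}\)
  (pixel-exact, percent of the query focus's own area), categorised as
  **none** (\(\omega = 0\)), **complete** (\(\omega \ge 100 - \tau\),
  default tolerance \(\tau = 1\)), or **partial** otherwise, with the
  category mix summarised as percentages of foci counted;
* **shape descriptors**: area \(|Q| \cdot p^2\) (pixel size \(p\) in μm),
  major/minor axis of the moment-equivalent ellipse, eccentricity
  \(\sqrt{1 - \lambda_2/\lambda_1}\);
* **per-cell metrics**: foci density (count / μm² of the cell's
  mitochondrial network), mean intensity over the network, integrated
  intensity over the cytoplasm, cytoplasmic and mitochondrial areas;
* **phase calls** per cell with precedence S (EdU⁺) → G2 (cyclin-A⁺) →
  G1 (DAPI⁺), cutoffs by 1D Otsu on per-cell marker means or set
  absolutely;
* **group summaries**: n, mean, sample SD per phase/condition.

A synthetic-frame generator (`generate_frame()`) plants foci with
pixel-exact areas and overlap categories, cells with known phases, PSF
blur and Poisson–Gaussian noise, and returns the full ground truth — the
package's validation suite runs against it.

## Worked example

Simulate a super-resolution-style frame (512² px at 0.02 μm/px, 100
dsRNA-like query foci vs 100 BrU-like reference foci, planted at a
3% / 65% / 32% complete/partial/none composition) and run the pipeline:

```r
library(granulemap)

p   <- generator_params(seed = 1)
sim <- generate_frame(p)

cfg <- pipeline_config(
  channels   = list(mito = "mito", query_foci = "dsRNA",
                    reference_foci = "BrU"),
  thresholds = list(mito = list(method = "absolute", threshold = 60),
                    foci = list(method = "absolute", threshold = 75)))

res <- run_pipeline(cfg, frame = sim$frame)
res$overlap_summary
#>   reference_channel n_foci pct_none pct_partial pct_complete
#> 1               BrU    100       32          65            3

head(res$per_focus[, c("focus_id", "area_um2", "eccentricity",
                       "overlap_pct", "category")], 5)
#>   focus_id area_um2 eccentricity overlap_pct category
#> 1        1   0.0156    0.7558407    17.94872  partial
#> 2        2   0.0104    0.2543062     0.00000     none
#> 3        3   0.0168    0.4664401    73.80952  partial
#> 4        4   0.0156    0.5008894    43.58974  partial
#> 5        5   0.0320    0.2393233    65.00000  partial
```

The summary row says: of 100 segmented dsRNA foci surviving the
containment filter, 32% had zero pixel overlap with any BrU focus, 65%
overlapped partially, 3% were completely covered — recovering the planted
composition exactly. Per focus you get the area in μm², the moment-ellipse
eccentricity (0 = circular), and the exact overlap percentage behind the
category. The run log records every threshold applied:

```
mito: method=absolute threshold=60 area=16.7536 um2
dsRNA (query_foci): threshold=75 foci=100, after centroid containment filter=100
overlap vs BrU: none=32.00% partial=65.00% complete=3.00% (n=100, complete_tol=1)
```

For per-cell work, `cell_frame_params()` generates confocal-style frames
with whole cells; mapping the `dapi`, `edu` and `cyclinA` roles in the
config adds per-cell densities, intensities, phase calls and group
summaries (`res$per_cell`, `res$group_summary`).

A command-line front end ships in `inst/scripts/granulemap`
(`simulate`, `colocalize`, `quantify`, `run` subcommands over the same
functions).

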