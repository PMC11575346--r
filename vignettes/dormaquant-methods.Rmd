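---
title: "Methods: quantifying dormancy phenotypes with dormaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying dormancy phenotypes with dormaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dormaquant)
```

dormaquant quantifies three readouts of bacterial dormancy: protein-aggregate
foci per cell in microscopy images, colony appearance times on scanner
time-lapses (ScanLag), and toxin-dependent protein-aggregate (TdPA) sets
from replicate proteomics tables. This vignette explains the models and
procedures behind each stage, the parameters that matter, what the
synthetic-data generators emulate (and what they do not), and the numerical
choices made where the design was genuinely open.

## Synthetic microscopy and the cell model

`simulate_microscopy()` renders a field of rod-shaped cells as
spherocylinders — every pixel within `width/2` of a central segment — the
simplest geometry with the aspect-ratio and solidity behaviour of *E. coli*
rods. Cells are placed by rejection sampling with a 1 px clearance;
exceeding a bounded attempt budget raises an explicit density error rather
than silently dropping cells, so ground-truth row counts always equal the
request. Fluorescence is background plus a flat cytoplasmic level inside
cells, plus per-cell punctate foci rendered as 2-D Gaussians
(`focus_sigma`, default 2 px) whose peak height is
`focus_amplitude × noise_sd` (5 × by default; when `noise_sd = 0` the
multiplier base is one intensity unit so noise-free fixtures remain
expressible). Camera noise is additive Gaussian. Phase contrast is rendered
as dark interiors with a bright 1 px halo around the outer boundary of the
cell *union*: between touching cells the optical boundary vanishes, as in
real images, which is exactly what makes touching-cell splitting a problem
worth exercising.

Per-cell focus counts are drawn from the user's probability vector
(default 0.1/0.2/0.4/0.2/0.1 over 0–4), and focus positions are sampled
inside an inset footprint with a minimum pairwise distance of 10 px. That
distance is deliberate: two Gaussian spots of scale $\sigma_f = 2$ px imaged
through a detection filter of the same scale have an effective width
$\sigma_{\mathrm{eff}} = \sqrt{\sigma_f^2 + \sigma_k^2} \approx 2.8$ px, and
two-point separation below roughly $2\sigma_{\mathrm{eff}} \approx 5.7$ px
merges them into a single maximum for *any* detector. Planting foci closer
than the resolution limit would make "exact recovery" an impossible target;
10 px keeps all planted configurations physically resolvable. Cell sizes
(35–55 × 10–14 px on a 1280² field) were likewise chosen so that four such
foci fit in one cell at that spacing. No pixel calibration is implied; all
sizes are in pixels and intensities in arbitrary units.

The generator does **not** emulate photorealistic phase-contrast optics,
fluorophore photophysics, shading/vignetting, or cell-to-cell cytoplasmic
variability. Passing the recovery benchmarks therefore shows the pipeline's
logic is correct on idealised rods with known truth — not that it matches a
specific microscope; the `import_mask()` path exists so segmentations from
a trained network can replace the classical front end on real data.

## Segmentation and shape QC

`segment_cells()` normalises the image, smooths lightly
(`smoothing_sigma = 0.5` px — enough to suppress single-pixel noise without
eroding the thresholded footprint, which stays within a few percent of the
planted area), and thresholds dark interiors, globally by Otsu's method or
with a local-mean policy for uneven illumination. Touching cells are split
by a depth-limited watershed on the distance transform: a contact neck is a
saddle of the distance-to-background map, and `boundary_erosion` (default
2 px) is the minimal saddle depth that triggers a cut. The depth limit is
what keeps single rods whole — their distance ridge undulates by about one
pixel from rasterisation, so depth-1 cuts can oversplit, while depth 2
splits every planted touching pair and left all 500 benchmark singles
intact. Setting it to 0 disables splitting.

Shape QC (`apply_qc()`) excludes regions touching the border, smaller than
`min_area` (50 px), larger than `max_area` (2000 px), or with solidity
below `min_solidity` (0.85), the operational definition of "crooked". All
four thresholds are parameters, not constants, since the corresponding
post-processing rules in published pipelines are rarely stated numerically.
Each excluded region carries exactly one reason, assigned in the fixed
priority order border > small > large > crooked, so the partition is
exhaustive and disjoint and the operation is idempotent. Solidity is pixel
count over the convex-hull pixel area (the hull polygon through pixel
centres, corrected by half its perimeter plus one, so convex pixel blobs
score ≈ 1).

## Focus detection

`detect_foci()` follows mask-filter-peak-threshold. The segmented cell
shapes are used as masks on the fluorescence channel: each cell's padded
bounding box is extracted and pixels outside the cell are replaced by the
cell median, so the cell edge contributes no filter response — without this
the edge step (cytoplasm minus background, ~4× a focus) dominates the
response inside narrow cells and suppresses genuine foci. The subimage is
filtered with a Laplacian-of-Gaussian at `filter_sigma` (2 px, the standard
single-scale spot enhancer), and local maxima at least `min_separation`
(3 px) apart are candidate peaks, with ties broken by smallest (row, col)
for determinism.

A candidate becomes a focus when it passes the per-cell rule
*value > median + k·MAD·1.4826* (`threshold_k = 3`) on **both** the lightly
denoised intensity (Gaussian σ 1; `intensity_smoothing = 0` measures raw
pixels) and the LoG response; `measure` can restrict the gate to either.
Two details make this rule usable at a realistic 5-σ amplitude:

* *Denoised measurement.* At peak height 5 × noise SD, a single-pixel read
  has only a ~2σ margin over a 3-MAD threshold (≈ 2% misses per focus plus
  noise false positives); measuring on a σ-1-smoothed image keeps the
  signal at ~4 × noise SD but cuts the measurement noise ~3.5-fold.
* *Clipped reference statistics.* In a cell with 3–4 foci the Gaussian
  skirts cover more than half the pixels, inflating a naive median/MAD far
  above the peaks themselves. The reference is therefore computed with
  iterated upper sigma-clipping (values above median + 3·MAD are removed
  and the statistics recomputed until stable): upward contamination is
  excluded, while for a focus-free Gaussian cell the clip removes only the
  extreme tail and the estimate is essentially unbiased. The intensity gate
  additionally floors the scale at one part in 10⁵ of the cell level so
  that in noise-free cells (MAD exactly 0) sub-resolution spillover from a
  neighbouring cell's focus tail cannot pass.

Raising `threshold_k` can only remove peaks (counts are monotone
nonincreasing in *k*, and go to zero as *k* → ∞), and every reported peak
lies inside its cell's mask by construction. `summarize_foci()` bins counts
0..`max_bin` with ≥ `max_bin` pooled (default 4, matching how such
histograms are usually reported), and `score_detection()` matches segmented
cells to ground truth by nearest centroid (greedy one-to-one) to compute the
exact-match rate. On the default benchmark (500 cells, seeded), the rate is
0.95–0.98 across seeds with every bin fraction within 3 percentage points
of the planted multinomial.

## ScanLag: colony appearance and growth times

`simulate_scan()` grows each colony, after a Normal(lag_mean, lag_sd) lag
truncated at zero, along a logistic area curve (rate 0.004–0.008 min⁻¹,
plateau 400 px — values that carry a colony through both classical
thresholds well inside a 40 h window), rendered as a disk per frame at
20-min spacing. The planted appearance time is read from the rendered pixel
counts, so generator and detector see the same quantisation. Growth is not
mechanistic: only threshold crossings matter downstream, so any monotone
curve suffices.

`detect_and_track()` subtracts the first frame as the background reference,
thresholds, labels components of ≥ `min_blob_px` pixels, and links each
live track to its nearest component within `link_radius_px`. Two tracks
claiming one component mark a merge; merged tracks are flagged and excluded
from summaries rather than guessed apart. Area series are cleaned with a
running maximum before threshold scans — the appearance/growth definitions
presuppose monotone growth, and the running maximum guards against
rendering or detection flicker. `appearance_time()` reports the first frame
time with area ≥ 10 px and `growth_time()` the spacing between the first
crossings of 80 and 160 px, both at frame resolution with no interpolation
(censored = `NA`); the published threshold values are kept as defaults and
exposed. On noise-free stacks the extracted appearance times equal the
planted ones exactly for every unmerged track. `compare_appearance()` is a
two-sided Mann–Whitney rank-sum test: exhaustive enumeration of rank
assignments when both groups have ≤ 8 colonies (valid under ties),
otherwise the tie-corrected normal approximation without continuity
correction.

## TdPA construction

The proteomics module mirrors the published decision rules exactly, on
intensities as provided (no cross-run normalisation, no imputation —
missing values are simply excluded):

* **Combined supernatant (cSN):** proteins with ≥ 2 valid values in either
  genotype's supernatant.
* **Enriched:** among proteins with ≥ 2 valid values in both genotypes'
  pellet fractions, log2 fold change = mean(log2 WT) − mean(log2 Δ) > 1
  and Welch's t-test (statistic and Welch–Satterthwaite df on log2 values)
  with Benjamini–Hochberg q < 0.05. The BH family is exactly the set of
  tested proteins; proteins failing the min-valid gate are excluded from
  the family rather than assigned p = 1.
* **Exclusive:** ≥ `present_min` (2) valid WT PF values and
  ≤ `absent_max` (0) mutant PF values. The present/absent counts are
  parameters because published "exclusively present" rules rarely state
  them; the default of 2 matches the cSN identification rule.
* **TdPA** = enriched ∪ exclusive. The two sets are disjoint by
  construction (testing requires quantification in both genotypes,
  exclusivity requires absence in one) and the constructor asserts it.

`enrichment_1d()` implements rank-based 1D annotation enrichment: per
category (≥ 5 members inside and outside), a Mann–Whitney comparison of
member versus non-member fold changes, summarised by the rank-biserial
score $s = 2U/(n_1 n_2) - 1 \in [-1, 1]$ with BH control across categories
(default FDR 0.1). Under random labels its raw p-values are calibrated:
the fraction below 0.05 is ~0.05 over thousands of simulated tables.
`localization_fractions()` tallies compartment fractions with multi-label
proteins counted 1/k per label and unlabeled proteins as "unknown".

### Why the default proteome benchmark is small

`proteome_sim_spec()` defaults to 80 proteins with 30 enriched
(shift 3 log2 units), 20 exclusive, 3 replicates per group, replicate noise
0.5 log2 units, and no dropout (dropouts are exercised explicitly through
`dropout_rate`). The size is a designed choice, fixed by a power analysis
before any benchmark was run: a Welch test on 3-vs-3 replicates has only
2–4 degrees of freedom, so even a 7-σ shift yields p ≈ 0.002–0.02, and
Benjamini–Hochberg against a large null family then leaves essentially no
discoveries (with 1000 proteins, sensitivity collapses to a few percent at
any effect size). A pellet fraction is also biologically a small,
aggregate-focused table — washed pellets recover aggregation-prone proteins,
not the whole proteome — so the default emulates that regime, where the
planted aggregate set is recovered with ~0.95 sensitivity and near-zero
false-discovery proportion. Users emulating a whole-proteome table should
expect, and will observe, the small-*n* Welch/BH power collapse; that is a
property of the published procedure, not of this implementation.

## Problem sizes and determinism

The shipped benchmarks are sized for a desk run: the 500-cell microscopy
field (1280² px), a 30-colony / 121-frame scanner stack (600² px), 200
random proteomics tables for the brute-force cross-check, and 1000
simulated tables for the enrichment calibration; together they complete in
a few minutes on one CPU. Every generator takes its seed from its spec and
every pipeline stage is purely deterministic given its inputs, so identical
spec + seed reproduces byte-identical images, tables and results; ties in
peak finding are broken lexicographically to keep detection deterministic
too.

## Known limitations

* The classical segmenter assumes dark, roughly convex rods on a brighter
  background; densely clustered or strongly curved cells are better served
  by an external (e.g. learned) segmenter via `import_mask()`.
* Focus counting reports counts only — no sub-pixel localisation, size or
  intensity quantification, and no time-lapse focus tracking.
* Colony tracking assumes sessile colonies and flags merges instead of
  resolving them; area is the only morphology measured.
* The Mann–Whitney normal approximation is used whenever either group
  exceeds 8 values; for small, tie-heavy groups between ~9 and ~20 samples
  an exact permutation p would be slightly more accurate.
* Proteomics tables are analysed as provided; if runs need normalisation or
  batch correction, that must happen upstream.
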