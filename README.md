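# dormaquant

Quantification of dormancy-associated phenotypes in *Escherichia coli*
persister biology, from three data modalities:

1. **Per-cell aggregate-focus counting.** Persister-prone cells carry
   cytoplasmic protein aggregates marked by IbpA–msfGFP foci. The package
   segments rod-shaped cells from phase-contrast images, applies
   shape-quality exclusions (border / too small / too large / crooked), uses
   the cell shapes as masks on the GFP channel, and counts punctate foci per
   cell by Laplacian-of-Gaussian filtering, local-maximum peak finding and
   per-cell robust thresholding (median + *k*·MAD).
2. **ScanLag colony appearance times.** Dormancy depth is read out as the
   time a plated cell needs to form a visible colony on a flatbed-scanner
   time-lapse (one frame / 20 min, 40 h). Colonies are detected, tracked,
   and assigned an appearance time (first frame with area ≥ 10 px) and a
   growth time (first crossing of 160 px minus first crossing of 80 px);
   conditions are compared with a two-sided Mann–Whitney rank-sum test.
3. **TisB-dependent protein aggregates (TdPA).** From replicate label-free
   proteomics intensity tables of supernatant (SN) and pellet fraction (PF)
   for wild type and a Δ*tisB* mutant, the package builds the combined
   supernatant reference (identified in ≥ 2 replicates of either genotype's
   SN), calls *enriched* proteins (log2 fold change > 1 and Welch's t-test
   with Benjamini–Hochberg FDR < 0.05, computed on log2 intensities with
   ≥ 2 valid values per group), calls *exclusive* proteins (present in WT PF,
   absent from mutant PF), and unions both into the TdPA set. Rank-based 1D
   annotation enrichment and localization fractions summarise the sets.

Small quantification formulas used alongside these pipelines are included:
the Pfaffl efficiency-corrected qPCR fold change
(E_target^ΔCq_target / E_ref^ΔCq_ref), the ATP calibration-curve transform
(nM per OD600), and relative CFU / persister levels (post/pre CFU ratio).

Every modality has a seeded synthetic-data generator
(`simulate_microscopy()`, `simulate_scan()`, `simulate_proteome()`) that
emits machine-readable ground truth, so each pipeline stage is testable
end-to-end without any external download.

## Worked example

```r
library(dormaquant)

# synthetic field of 500 cells with planted focus counts
sim <- simulate_microscopy(microscopy_sim_spec(seed = 7))
seg <- segment_cells(sim$phase)
qc  <- apply_qc(seg$regions)
det <- detect_foci(sim$fluor, seg$mask, qc)

score_detection(det$counts, qc, sim$cells)$exact_match_rate
#> [1] 0.972

summarize_foci(det$counts)
#> # A tibble: 5 x 3
#>   bin   count fraction
#>   <fct> <int>    <dbl>
#> 1 0        39    0.078
#> 2 1       106    0.212
#> 3 2       206    0.412
#> 4 3        93    0.186
#> 5 >=4      56    0.112
```

97% of cells receive exactly their planted focus count, and the recovered
histogram matches the planted multinomial (0.1/0.2/0.4/0.2/0.1) within
3 percentage points per bin. `autoplot()` on the distribution draws the per-cell
histogram; `autoplot()` on a `build_tdpa()` result draws the
enrichment volcano.

The proteomics route mirrors the published decision rules:

```r
psim <- simulate_proteome(proteome_sim_spec(seed = 11))
res  <- build_tdpa(psim$sn_wt, psim$sn_del, psim$pf_wt, psim$pf_del)
res
#> TdPA result
#>   combined supernatant: 80 proteins
#>   enriched:             29
#>   exclusive:            20
#>   TdPA union:           49
```

with 30 enriched and 20 exclusive proteins planted (sensitivity 0.98 at the
default effect size; `tidy(res)` returns the per-protein statistics).

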