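# Small quantification formulas: efficiency-corrected qPCR fold change
# (Pfaffl), ATP calibration-curve transform, and relative CFU / persister
# levels.

#' Pfaffl fold change from qPCR Cq values
#'
#' Efficiency-corrected relative expression ratio
#' `E_target^dCq_target / E_ref^dCq_ref`, where `dCq = Cq(control) -
#' Cq(treated)` so that induction gives a fold change above 1. The reference
#' gene (e.g. *hcaT*) normalises for input amounts.
#'
#' @param dcq_target,dcq_ref Delta-Cq of target and reference gene, cycles.
#' @param e_target,e_ref Amplification efficiencies as fold per cycle, in
#'   (1, 2]; the classical assumption of perfect doubling is 2.
#' @return Fold change (unitless); vectorised over its arguments.
#' @examples
#' pfaffl_fold_change(3, 0)                   # 8
#' pfaffl_fold_change(2.5, 0.5, 1.9, 2.0)     # ~3.519
#' @export
pfaffl_fold_change <- function(dcq_target, dcq_ref, e_target = 2, e_ref = 2) {
  if (any(e_target <= 1) || any(e_ref <= 1)) {
    abort("amplification efficiencies must be > 1 (fold per cycle)")
  }
  if (any(e_target > 2) || any(e_ref > 2)) {
    abort("amplification efficiencies cannot exceed 2 (perfect doubling)")
  }
  e_target^dcq_target / e_ref^dcq_ref
}

#' ATP concentration from luminescence via a calibration curve
#'
#' Transforms luminescence counts to nM using the slope (and intercept) of
#' an ATP calibration curve and normalises to the culture OD600:
#' `((luminescence - intercept) / slope) / od600`. Negative concentrations
#' (luminescence below the intercept) are clipped to 0 with a warning.
#'
#' @param luminescence Luminescence counts; vectorised.
#' @param slope Calibration slope, counts per nM (> 0).
#' @param intercept Calibration intercept, counts (default 0).
#' @param od600 Optical density at 600 nm (> 0).
#' @return ATP concentration in nM per OD600 unit.
#' @examples
#' atp_concentration(2500, slope = 1000, intercept = 500, od600 = 0.4) # 5
#' @export
atp_concentration <- function(luminescence, slope, intercept = 0, od600) {
  if (any(slope <= 0)) abort("calibration slope must be > 0")
  if (any(od600 <= 0)) abort("od600 must be > 0")
  out <- ((luminescence - intercept) / slope) / od600
  if (any(out < 0)) {
    warn("luminescence below calibration intercept; clipping to 0 nM")
    out <- pmax(out, 0)
  }
  out
}

#' Colony-forming units per millilitre
#'
#' @param colonies Colony count on the plate (>= 0).
#' @param dilution_factor Total dilution factor (>= 1).
#' @param plated_volume_ml Plated volume in mL (> 0).
#' @return CFU per mL; vectorised.
#' @export
cfu_per_ml <- function(colonies, dilution_factor, plated_volume_ml) {
  if (any(colonies < 0)) abort("colony counts must be >= 0")
  if (any(dilution_factor < 1)) abort("dilution_factor must be >= 1")
  if (any(plated_volume_ml <= 0)) abort("plated volume must be > 0")
  colonies * dilution_factor / plated_volume_ml
}

#' Relative CFU count or persister level
#'
#' The ratio of post-treatment to pre-treatment CFU/mL, in percent. After a
#' non-lethal treatment this is the relative CFU count; after a bactericidal
#' antibiotic it is the persister level.
#'
#' @param pre,post Lists or one-row data frames with elements `colonies`,
#'   `dilution_factor` and `plated_volume_ml`.
#' @return `100 * post / pre`, percent.
#' @examples
#' relative_cfu(
#'   pre = list(colonies = 200, dilution_factor = 1e5, plated_volume_ml = 0.1),
#'   post = list(colonies = 40, dilution_factor = 1e4, plated_volume_ml = 0.1)
#' ) # 2
#' @export
relative_cfu <- function(pre, post) {
  if (pre$colonies == 0) {
    abort("pre-treatment colony count is 0; the ratio is undefined")
  }
  pre_cfu <- cfu_per_ml(pre$colonies, pre$dilution_factor, pre$plated_volume_ml)
  post_cfu <- cfu_per_ml(post$colonies, post$dilution_factor,
                         post$plated_volume_ml)
  100 * post_cfu / pre_cfu
}
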