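# Synthetic label-free proteomics generator: four replicate intensity tables
# (two genotypes x two fractions) with planted enrichment, exclusivity and
# dropouts, plus per-protein class labels.

#' Simulate replicate proteomics intensity tables with planted classes
#'
#' Baseline per-protein log2 intensities are Normal(`baseline_log2_mean`,
#' `baseline_log2_sd`); replicate values add Normal(0, `replicate_log2_sd`)
#' noise and are reported on the intensity scale (`2^log2`). The first
#' `n_enriched` proteins are shifted up by `enrichment_log2fc` in the WT
#' pellet fraction; the next `n_exclusive` proteins are entirely absent from
#' the mutant pellet fraction; all other values drop out independently with
#' probability `dropout_rate`.
#'
#' @param spec A [proteome_sim_spec()].
#' @return A list of class `proteome_sim` with elements `sn_wt`, `sn_del`,
#'   `pf_wt`, `pf_del` (tibbles: `protein_id` + replicate columns `rep_1`,
#'   ..., missing = `NA`), `classes` (tibble `protein_id`, `class` in
#'   `enriched`/`exclusive`/`background`), and `spec`.
#' @export
simulate_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_proteins
  reps <- spec$n_replicates
  ids <- sprintf("P%04d", seq_len(n))
  class <- rep("background", n)
  if (spec$n_enriched > 0L) class[seq_len(spec$n_enriched)] <- "enriched"
  if (spec$n_exclusive > 0L) {
    class[spec$n_enriched + seq_len(spec$n_exclusive)] <- "exclusive"
  }

  baseline <- stats::rnorm(n, spec$baseline_log2_mean, spec$baseline_log2_sd)

  draw_table <- function(shift = 0, absent = rep(FALSE, n)) {
    m <- matrix(
      stats::rnorm(n * reps, baseline + shift, spec$replicate_log2_sd),
      nrow = n, ncol = reps
    )
    m <- 2^m
    if (spec$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * reps) < spec$dropout_rate, n, reps)
      m[drop] <- NA_real_
    }
    m[absent, ] <- NA_real_
    colnames(m) <- paste0("rep_", seq_len(reps))
    bind_cols_tbl(ids, m)
  }

  sn_wt <- draw_table()
  sn_del <- draw_table()
  pf_wt <- draw_table(shift = ifelse(class == "enriched", spec$enrichment_log2fc, 0))
  pf_del <- draw_table(absent = class == "exclusive")

  structure(
    list(
      sn_wt = sn_wt, sn_del = sn_del, pf_wt = pf_wt, pf_del = pf_del,
      classes = tibble(protein_id = ids, class = class),
      spec = spec
    ),
    class = "proteome_sim"
  )
}

bind_cols_tbl <- function(ids, m) {
  out <- as_tibble(as.data.frame(m))
  out <- tibble(protein_id = ids) |> dplyr::bind_cols(out)
  out
}
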