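# Construction of the toxin-dependent protein-aggregate (TdPA) set from
# replicate label-free intensity tables: combined-supernatant reference,
# Welch/BH differential enrichment of pellet fractions, exclusive-presence
# rule, and the union set, plus rank-based 1D annotation enrichment and
# localization summaries.

#' Differential-enrichment criteria
#'
#' @param min_valid_per_group Minimum number of valid (non-missing)
#'   quantification values required in each group for a protein to be
#'   tested (default 2).
#' @param log2fc_threshold Enrichment calls require log2 fold change above
#'   this (default 1).
#' @param fdr_threshold Benjamini-Hochberg FDR cut-off (default 0.05).
#' @return A validated list of class `diff_criteria`.
#' @export
diff_criteria <- function(min_valid_per_group = 2L,
                          log2fc_threshold = 1,
                          fdr_threshold = 0.05) {
  if (min_valid_per_group < 2L) abort("min_valid_per_group must be >= 2")
  if (log2fc_threshold <= 0 || fdr_threshold <= 0) {
    abort("thresholds must be > 0")
  }
  structure(
    list(min_valid_per_group = as.integer(min_valid_per_group),
         log2fc_threshold = log2fc_threshold,
         fdr_threshold = fdr_threshold),
    class = "diff_criteria"
  )
}

# protein_id + replicate columns -> numeric matrix with protein_id rownames
intensity_matrix <- function(tbl, ids = NULL) {
  stopifnot("protein_id" %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), "protein_id")])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$protein_id
  if (!is.null(ids)) {
    out <- matrix(NA_real_, length(ids), ncol(m),
                  dimnames = list(ids, colnames(m)))
    found <- intersect(ids, rownames(m))
    out[found, ] <- m[found, , drop = FALSE]
    m <- out
  }
  m
}

#' Combined-supernatant reference set
#'
#' Proteins identified in at least `min_reps` replicates of either
#' genotype's supernatant.
#'
#' @param sn_wt,sn_del Supernatant intensity tables (`protein_id` +
#'   replicate columns; `NA` = not identified).
#' @param min_reps Minimum replicates with a value (default 2).
#' @return Sorted character vector of protein identifiers.
#' @export
combined_supernatant <- function(sn_wt, sn_del, min_reps = 2L) {
  ids <- sort(union(sn_wt$protein_id, sn_del$protein_id))
  w <- intensity_matrix(sn_wt, ids)
  d <- intensity_matrix(sn_del, ids)
  keep <- rowSums(!is.na(w)) >= min_reps | rowSums(!is.na(d)) >= min_reps
  ids[keep]
}

#' Differential enrichment of pellet-fraction proteins
#'
#' For every protein with at least `min_valid_per_group` valid values in
#' both genotypes: log2 fold change = mean(log2 WT) - mean(log2 mutant),
#' Welch's t-test on log2 intensities (missing values excluded, never
#' imputed), and Benjamini-Hochberg adjustment across all tested proteins.
#' `enriched` requires `log2fc > log2fc_threshold` and `q < fdr_threshold`.
#'
#' @param pf_wt,pf_del Pellet-fraction intensity tables.
#' @param criteria A [diff_criteria()].
#' @return A tibble with one row per protein: `protein_id`, `n_wt`,
#'   `n_del`, `log2fc`, `t`, `df`, `p`, `q`, `tested`, `enriched`.
#' @export
differential_enrichment <- function(pf_wt, pf_del,
                                    criteria = diff_criteria()) {
  ids <- sort(union(pf_wt$protein_id, pf_del$protein_id))
  w <- log2(intensity_matrix(pf_wt, ids))
  d <- log2(intensity_matrix(pf_del, ids))
  res <- welch_t_rows(w, d)
  tested <- res$n_x >= criteria$min_valid_per_group &
    res$n_y >= criteria$min_valid_per_group
  if (!any(tested)) abort("no protein has enough valid values to test")
  q <- rep(NA_real_, length(ids))
  q[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  log2fc <- res$mean_x - res$mean_y
  tibble(
    protein_id = ids,
    n_wt = res$n_x, n_del = res$n_y,
    log2fc = ifelse(tested, log2fc, NA_real_),
    t = ifelse(tested, res$t, NA_real_),
    df = ifelse(tested, res$df, NA_real_),
    p = ifelse(tested, res$p, NA_real_),
    q = q,
    tested = tested,
    enriched = tested & !is.na(q) &
      log2fc > criteria$log2fc_threshold & q < criteria$fdr_threshold
  )
}

#' Proteins exclusively present in the wild-type pellet fraction
#'
#' @param pf_wt,pf_del Pellet-fraction intensity tables.
#' @param present_min Minimum valid WT values for "present" (default 2).
#' @param absent_max Maximum valid mutant values for "absent" (default 0).
#' @return Sorted character vector of protein identifiers.
#' @export
exclusive_proteins <- function(pf_wt, pf_del, present_min = 2L,
                               absent_max = 0L) {
  ids <- sort(union(pf_wt$protein_id, pf_del$protein_id))
  w <- intensity_matrix(pf_wt, ids)
  d <- intensity_matrix(pf_del, ids)
  keep <- rowSums(!is.na(w)) >= present_min & rowSums(!is.na(d)) <= absent_max
  ids[keep]
}

#' Build the toxin-dependent protein-aggregate (TdPA) set
#'
#' Runs [combined_supernatant()], [differential_enrichment()] and
#' [exclusive_proteins()] and combines enriched and exclusive proteins into
#' the TdPA union. Enriched and exclusive sets are disjoint by construction
#' (enrichment requires quantification in both genotypes, exclusivity
#' requires absence in one); this is asserted.
#'
#' @param sn_wt,sn_del,pf_wt,pf_del The four intensity tables.
#' @param criteria A [diff_criteria()].
#' @param present_min,absent_max Passed to [exclusive_proteins()].
#' @param sn_min_reps Passed to [combined_supernatant()].
#' @return A list of class `tdpa_result` with `csn`, `stats` (the
#'   differential-enrichment tibble plus a `class` column), `enriched`,
#'   `exclusive`, `tdpa` and `criteria`.
#' @export
build_tdpa <- function(sn_wt, sn_del, pf_wt, pf_del,
                       criteria = diff_criteria(),
                       present_min = 2L, absent_max = 0L,
                       sn_min_reps = 2L) {
  csn <- combined_supernatant(sn_wt, sn_del, min_reps = sn_min_reps)
  stats_tbl <- differential_enrichment(pf_wt, pf_del, criteria)
  enriched <- stats_tbl$protein_id[stats_tbl$enriched]
  exclusive <- exclusive_proteins(pf_wt, pf_del, present_min, absent_max)
  if (length(intersect(enriched, exclusive)) > 0L) {
    abort("internal error: enriched and exclusive sets overlap")
  }
  stats_tbl <- stats_tbl |>
    mutate(class = dplyr::case_when(
      .data$protein_id %in% enriched ~ "enriched",
      .data$protein_id %in% exclusive ~ "exclusive",
      TRUE ~ "none"
    ))
  structure(
    list(
      csn = csn,
      stats = stats_tbl,
      enriched = sort(enriched),
      exclusive = sort(exclusive),
      tdpa = sort(union(enriched, exclusive)),
      criteria = criteria
    ),
    class = "tdpa_result"
  )
}

#' @export
print.tdpa_result <- function(x, ...) {
  cat("TdPA result\n")
  cat("  combined supernatant:", length(x$csn), "proteins\n")
  cat("  enriched:            ", length(x$enriched), "\n")
  cat("  exclusive:           ", length(x$exclusive), "\n")
  cat("  TdPA union:          ", length(x$tdpa), "\n")
  invisible(x)
}

#' @method tidy tdpa_result
#' @export
tidy.tdpa_result <- function(x, ...) x$stats

#' @method glance tdpa_result
#' @export
glance.tdpa_result <- function(x, ...) {
  tibble(
    n_csn = length(x$csn),
    n_tested = sum(x$stats$tested),
    n_enriched = length(x$enriched),
    n_exclusive = length(x$exclusive),
    n_tdpa = length(x$tdpa)
  )
}

#' 1D annotation enrichment over protein fold changes
#'
#' For each annotation category with at least `min_members` proteins both
#' inside and outside, performs a rank-based two-sample comparison of member
#' versus non-member log2 fold changes (Mann-Whitney) and reports the
#' rank-biserial score s = 2U/(n1 n2) - 1 in [-1, 1] (positive = members
#' shifted towards higher fold changes), the two-sided p, and the
#' Benjamini-Hochberg q across categories.
#'
#' @param stats A tibble with `protein_id` and `log2fc` columns (for example
#'   from [differential_enrichment()]); rows with missing `log2fc` are
#'   dropped.
#' @param annotations A tibble with `protein_id` and `category` columns
#'   (one row per assignment; proteins may carry several categories).
#' @param fdr Significance threshold on q (default 0.1).
#' @param min_members Minimum category size inside and outside (default 5).
#' @return A tibble: `category`, `n_members`, `s`, `p`, `q`, `significant`;
#'   zero rows when no category is testable.
#' @export
enrichment_1d <- function(stats, annotations, fdr = 0.1, min_members = 5L) {
  df <- stats |>
    filter(!is.na(.data$log2fc)) |>
    select("protein_id", "log2fc")
  if (nrow(df) < 2L) abort("need at least 2 proteins with a fold change")
  cats <- annotations |>
    filter(.data$protein_id %in% df$protein_id) |>
    dplyr::distinct(.data$protein_id, .data$category)
  out <- cats |>
    group_by(.data$category) |>
    dplyr::group_map(function(g, key) {
      members <- df$protein_id %in% g$protein_id
      n1 <- sum(members)
      n2 <- sum(!members)
      if (n1 < min_members || n2 < min_members) return(NULL)
      res <- mann_whitney_u(df$log2fc[members], df$log2fc[!members])
      tibble(category = key$category, n_members = n1,
             s = 2 * res$u / (n1 * n2) - 1, p = res$p)
    }) |>
    purrr::compact() |>
    bind_rows()
  if (nrow(out) == 0L) {
    return(tibble(category = character(), n_members = integer(),
                  s = numeric(), p = numeric(), q = numeric(),
                  significant = logical()))
  }
  out |>
    mutate(q = stats::p.adjust(.data$p, method = "BH"),
           significant = .data$q < fdr) |>
    arrange(.data$q, .data$category)
}

#' Localization fractions of a protein set
#'
#' Multi-label proteins are counted fractionally (1/k per label); proteins
#' without any label count as `"unknown"`. Fractions sum to 1.
#'
#' @param proteins Character vector of protein identifiers (nonempty).
#' @param annotations Tibble with `protein_id` and `localization` columns.
#' @return A tibble with `localization` and `fraction`, sorted by
#'   decreasing fraction.
#' @export
localization_fractions <- function(proteins, annotations) {
  if (length(proteins) == 0L) {
    abort("cannot compute fractions over an empty protein set")
  }
  labs <- tibble(protein_id = proteins) |>
    left_join(
      annotations |> dplyr::distinct(.data$protein_id, .data$localization),
      by = "protein_id"
    ) |>
    mutate(localization = dplyr::coalesce(.data$localization, "unknown")) |>
    group_by(.data$protein_id) |>
    mutate(weight = 1 / n()) |>
    ungroup()
  labs |>
    group_by(.data$localization) |>
    summarise(fraction = sum(.data$weight) / length(proteins)) |>
    arrange(dplyr::desc(.data$fraction))
}

#' Read a combined intensity CSV and split it by genotype and fraction
#'
#' The CSV must have a `protein_id` column plus replicate columns named
#' `<genotype>_<fraction>_<rep>` with genotype in `WT`/`dtisB` and fraction
#' in `SN`/`PF`; empty cells are missing values.
#'
#' @param path CSV file path.
#' @return A named list of four tibbles: `sn_wt`, `sn_del`, `pf_wt`,
#'   `pf_del`.
#' @export
read_intensity_tables <- function(path) {
  tbl <- utils::read.csv(path, check.names = FALSE) |> as_tibble()
  if (!"protein_id" %in% names(tbl)) abort("CSV needs a protein_id column")
  pick <- function(genotype, fraction) {
    cols <- grep(paste0("^", genotype, "_", fraction, "_"), names(tbl),
                 value = TRUE)
    if (length(cols) == 0L) {
      abort(paste0("no columns match ", genotype, "_", fraction, "_<rep>"))
    }
    tbl[c("protein_id", cols)]
  }
  list(
    sn_wt = pick("WT", "SN"), sn_del = pick("dtisB", "SN"),
    pf_wt = pick("WT", "PF"), pf_del = pick("dtisB", "PF")
  )
}
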