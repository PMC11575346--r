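# five-protein toy tables exercising every TdPA rule at once:
#   A: strongly enriched; B: WT-only (exclusive); C: identical in both;
#   D: enriched with one missing WT value; E: below the fold-change cut
toy_pf <- function() {
  wt <- intensity_tbl(rbind(
    c(1000, 1100, 900),
    c(500, 520, 480),
    c(200, 200, 200),
    c(300, 310, NA),
    c(300, 305, 295)
  ), ids = LETTERS[1:5])
  del <- intensity_tbl(rbind(
    c(100, 110, 90),
    c(NA, NA, NA),
    c(200, 200, 200),
    c(100, 105, 95),
    c(200, 203, 197)
  ), ids = LETTERS[1:5])
  list(wt = wt, del = del)
}

test_that("combined supernatant applies the two-replicate identification rule", {
  sn_wt <- intensity_tbl(rbind(c(10, 12, NA), c(10, NA, NA), c(NA, NA, NA)),
                         ids = c("A", "B", "C"))
  sn_del <- intensity_tbl(rbind(c(NA, NA, NA), c(9, NA, NA), c(8, 9, 10)),
                          ids = c("A", "B", "C"))
  # A: 2 WT replicates; B: 1 + 1 (excluded); C: 3 mutant replicates
  expect_equal(combined_supernatant(sn_wt, sn_del), c("A", "C"))

  set.seed(14)
  wt <- random_intensity_tbl(500, na_prob = 0.5)
  del <- random_intensity_tbl(500, na_prob = 0.5)
  want <- oracle_tdpa(wt, del, wt, del)$csn
  expect_equal(combined_supernatant(wt, del), want)
})

test_that("identical groups are never called enriched", {
  tbl <- intensity_tbl(matrix(2^runif(9, 10, 20), 3, 3))
  de <- differential_enrichment(tbl, tbl)
  expect_equal(de$log2fc, rep(0, 3))
  expect_false(any(de$enriched))
})

test_that("the Welch statistic matches its textbook value", {
  # intensities chosen so the log2 values are exactly 10,12,14 vs 20,21,22
  wt <- intensity_tbl(matrix(2^c(10, 12, 14), 1))
  del <- intensity_tbl(matrix(2^c(20, 21, 22), 1))
  de <- differential_enrichment(wt, del)
  expect_equal(de$t, -6.9714, tolerance = 1e-4)
  expect_equal(de$df, 2.9412, tolerance = 1e-4)
  expect_false(de$enriched) # negative fold change
})

test_that("the toy table yields exactly the expected calls", {
  pf <- toy_pf()
  de <- differential_enrichment(pf$wt, pf$del)
  expect_equal(de$protein_id[de$enriched], c("A", "D"))
  expect_false("B" %in% de$protein_id[de$tested]) # too few mutant values
  expect_equal(exclusive_proteins(pf$wt, pf$del), "B")
})

test_that("exclusive presence follows the present/absent replicate rules", {
  wt <- intensity_tbl(rbind(c(10, 11, 12), c(10, 11, 12)), ids = c("A", "B"))
  del <- intensity_tbl(rbind(c(NA, NA, NA), c(9, NA, NA)), ids = c("A", "B"))
  expect_equal(exclusive_proteins(wt, del), "A")
  expect_equal(exclusive_proteins(wt, del, absent_max = 1L), c("A", "B"))

  set.seed(15)
  w <- random_intensity_tbl(300, na_prob = 0.45)
  d <- random_intensity_tbl(300, na_prob = 0.45)
  expect_equal(exclusive_proteins(w, d), oracle_tdpa(w, d, w, d)$exclusive)
})

test_that("build_tdpa combines the rules and keeps its invariants", {
  pf <- toy_pf()
  sn <- intensity_tbl(matrix(2^rnorm(15, 20), 5, 3), ids = LETTERS[1:5])
  res <- build_tdpa(sn, sn, pf$wt, pf$del)
  expect_s3_class(res, "tdpa_result")
  expect_equal(res$tdpa, c("A", "B", "D"))
  expect_length(intersect(res$enriched, res$exclusive), 0)
  expect_true(all(res$tdpa %in% pf$wt$protein_id))
  expect_equal(glance(res)$n_tdpa, 3L)
  expect_equal(nrow(tidy(res)), 5L)

  # no planted signal: both sets empty
  set.seed(16)
  flat <- random_intensity_tbl(60, na_prob = 0)
  none <- build_tdpa(flat, flat, flat, flat)
  expect_length(none$enriched, 0)
  expect_length(none$exclusive, 0)
})

test_that("1D annotation enrichment scores rank shifts", {
  # members hold all top ranks: maximal score 1
  stats <- tibble::tibble(protein_id = sprintf("P%02d", 1:10),
                          log2fc = 1:10)
  ann <- tibble::tibble(protein_id = sprintf("P%02d", 6:10),
                        category = "top")
  res <- enrichment_1d(stats, ann, min_members = 5L)
  expect_equal(res$s, 1)

  # hand-counted example: values 1..5, members at values 2 and 5 -> U = 4
  stats5 <- tibble::tibble(protein_id = letters[1:5], log2fc = 1:5)
  ann5 <- tibble::tibble(protein_id = c("b", "e"), category = "pair")
  res5 <- enrichment_1d(stats5, ann5, min_members = 2L)
  expect_equal(res5$s, 2 * 4 / 6 - 1)

  # categories too small to test yield an empty result
  empty <- enrichment_1d(stats5, ann5, min_members = 3L)
  expect_equal(nrow(empty), 0L)
})

test_that("localization fractions tally multi-label proteins fractionally", {
  ann <- tibble::tibble(
    protein_id = c("A", "B", "B"),
    localization = c("cytoplasm", "inner membrane", "cytoplasm")
  )
  one <- localization_fractions("A", ann)
  expect_equal(one$fraction, 1)

  two <- localization_fractions(c("A", "B"), ann)
  expect_equal(two$fraction[two$localization == "cytoplasm"], 0.75)
  expect_equal(sum(two$fraction), 1)

  # unlabeled proteins count as unknown
  three <- localization_fractions(c("A", "Z"), ann)
  expect_equal(three$fraction[three$localization == "unknown"], 0.5)
  expect_error(localization_fractions(character(0), ann), "empty")

  # random labelings against a hand tally
  set.seed(17)
  for (i in 1:20) {
    prots <- sprintf("Q%02d", 1:20)
    ann_r <- tibble::tibble(
      protein_id = sample(prots, 40, replace = TRUE),
      localization = sample(c("C", "IM", "OM", "P"), 40, replace = TRUE)
    ) |> dplyr::distinct()
    got <- localization_fractions(prots, ann_r)
    labs <- split(ann_r$localization, ann_r$protein_id)
    tally <- list()
    for (p in prots) {
      ls <- labs[[p]]
      if (is.null(ls)) ls <- "unknown"
      for (l in ls) tally[[l]] <- (tally[[l]] %||% 0) + 1 / length(ls)
    }
    for (l in names(tally)) {
      expect_equal(got$fraction[got$localization == l],
                   tally[[l]] / length(prots))
    }
  }
})

test_that("intensity CSVs split into the four genotype/fraction tables", {
  sim <- simulate_proteome(proteome_sim_spec(n_proteins = 12L, n_enriched = 4L,
                                         n_exclusive = 3L, seed = 3))
  wide <- sim$sn_wt
  names(wide)[-1] <- paste0("WT_SN_", 1:3)
  for (nm in list(c("sn_del", "dtisB_SN"), c("pf_wt", "WT_PF"),
                  c("pf_del", "dtisB_PF"))) {
    t2 <- sim[[nm[1]]][, -1]
    names(t2) <- paste0(nm[2], "_", 1:3)
    wide <- dplyr::bind_cols(wide, t2)
  }
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  tables <- read_intensity_tables(path)
  expect_equal(unname(as.matrix(tables$pf_wt[, -1])),
               unname(as.matrix(sim$pf_wt[, -1])))
  expect_equal(tables$sn_del$protein_id, sim$sn_del$protein_id)
})
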