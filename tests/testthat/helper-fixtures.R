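# Shared fixtures and independent brute-force oracles. The default microscopy
# benchmark is expensive, so it is computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

benchmark_microscopy <- function() {
  cached("benchmark_microscopy", {
    sim <- simulate_microscopy(microscopy_sim_spec(seed = 7))
    seg <- segment_cells(sim$phase)
    qc <- apply_qc(seg$regions)
    det <- detect_foci(sim$fluor, seg$mask, qc)
    list(sim = sim, seg = seg, qc = qc, det = det)
  })
}

benchmark_scan <- function() {
  cached("benchmark_scan", {
    sim <- simulate_scan(scan_sim_spec(n_colonies = 30L, lag_mean = 800,
                                       lag_sd = 150, seed = 3))
    tracks <- detect_and_track(sim$series)
    list(sim = sim, tracks = tracks)
  })
}

# small intensity tibble from a numeric matrix (NA = missing)
intensity_tbl <- function(m, ids = sprintf("P%02d", seq_len(nrow(m)))) {
  colnames(m) <- paste0("rep_", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(protein_id = ids),
                   tibble::as_tibble(as.data.frame(m)))
}

random_intensity_tbl <- function(n, reps = 3L, na_prob = 0.15,
                                 ids = sprintf("P%03d", seq_len(n))) {
  m <- matrix(2^rnorm(n * reps, 20, 2), n, reps)
  m[matrix(runif(n * reps) < na_prob, n, reps)] <- NA
  intensity_tbl(m, ids)
}

# Brute-force TdPA oracle: per-protein loop, stats::t.test, hand step-up BH.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

oracle_tdpa <- function(sn_wt, sn_del, pf_wt, pf_del,
                        min_valid = 2L, log2fc_thr = 1, fdr = 0.05,
                        present_min = 2L, absent_max = 0L, sn_min_reps = 2L) {
  ids <- sort(union(pf_wt$protein_id, pf_del$protein_id))
  get_row <- function(tbl, id) {
    r <- tbl[tbl$protein_id == id, -1, drop = FALSE]
    if (nrow(r) == 0) return(numeric(0))
    v <- as.numeric(r[1, ])
    v[!is.na(v)]
  }
  res <- lapply(ids, function(id) {
    wv <- log2(get_row(pf_wt, id))
    dv <- log2(get_row(pf_del, id))
    tested <- length(wv) >= min_valid && length(dv) >= min_valid
    if (!tested) {
      return(list(id = id, tested = FALSE, t = NA, p = NA, fc = NA))
    }
    tt <- stats::t.test(wv, dv, var.equal = FALSE)
    list(id = id, tested = TRUE, t = unname(tt$statistic),
         p = tt$p.value, fc = mean(wv) - mean(dv))
  })
  tested <- vapply(res, `[[`, TRUE, "tested")
  p <- vapply(res, function(r) ifelse(r$tested, r$p, NA_real_), 0)
  q <- rep(NA_real_, length(ids))
  q[tested] <- oracle_bh(p[tested])
  fc <- vapply(res, function(r) ifelse(r$tested, r$fc, NA_real_), 0)
  tval <- vapply(res, function(r) ifelse(r$tested, r$t, NA_real_), 0)
  enriched <- ids[tested & !is.na(q) & fc > log2fc_thr & q < fdr]

  n_valid <- function(tbl, id) length(get_row(tbl, id))
  exclusive <- ids[vapply(ids, function(id) {
    n_valid(pf_wt, id) >= present_min && n_valid(pf_del, id) <= absent_max
  }, TRUE)]

  sn_ids <- sort(union(sn_wt$protein_id, sn_del$protein_id))
  csn <- sn_ids[vapply(sn_ids, function(id) {
    n_valid(sn_wt, id) >= sn_min_reps || n_valid(sn_del, id) >= sn_min_reps
  }, TRUE)]

  list(csn = csn, enriched = sort(enriched), exclusive = sort(exclusive),
       tdpa = sort(union(enriched, exclusive)),
       stats = tibble::tibble(protein_id = ids, t = tval, q = q,
                              tested = tested))
}

# Brute-force first-crossing scans (no running-maximum shortcut).
oracle_appearance <- function(areas, times, thr) {
  for (i in seq_along(areas)) {
    if (max(areas[seq_len(i)]) >= thr) return(times[i])
  }
  NA_real_
}

oracle_growth <- function(areas, times, low, high) {
  tl <- oracle_appearance(areas, times, low)
  th <- oracle_appearance(areas, times, high)
  if (is.na(tl) || is.na(th)) NA_real_ else th - tl
}

random_monotone_series <- function(n_frames = 25L) {
  cummax(round(runif(n_frames, 0, 1)^2 * 250))
}
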