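# Per-cell counting of punctate fluorescent foci (protein aggregates) inside
# segmented cells: spot-enhancing spatial filter, local-maximum peak finding,
# per-cell robust thresholding, and population histograms.

#' Foci detection parameters
#'
#' @param filter_sigma Scale (pixels) of the Laplacian-of-Gaussian
#'   spot-enhancing filter.
#' @param min_separation Minimum distance between accepted peaks, pixels.
#' @param threshold_k A peak is kept when its measured intensity exceeds the
#'   cell median plus `threshold_k` robust SDs (median absolute deviation
#'   scaled by 1.4826).
#' @param max_bin Top histogram category; per-cell counts at or above it are
#'   pooled (default 4, i.e. bins 0,1,2,3,>=4).
#' @param intensity_smoothing Gaussian sigma (pixels) of the light denoising
#'   applied before intensities are measured and thresholded; 0 measures the
#'   raw image.
#' @param measure Which value is thresholded: `"both"` (default: a peak
#'   must pass the median + k x MAD rule on the denoised intensity and on
#'   the filter response), `"intensity"`, or `"response"`.
#' @return A validated list of class `foci_params`.
#' @export
foci_params <- function(filter_sigma = 2,
                        min_separation = 3,
                        threshold_k = 3,
                        max_bin = 4L,
                        intensity_smoothing = 1,
                        measure = c("both", "intensity", "response")) {
  measure <- match.arg(measure)
  if (filter_sigma <= 0) abort("filter_sigma must be > 0")
  if (min_separation < 1) abort("min_separation must be >= 1")
  if (threshold_k < 0) abort("threshold_k must be >= 0")
  structure(
    list(filter_sigma = filter_sigma, min_separation = min_separation,
         threshold_k = threshold_k, max_bin = as.integer(max_bin),
         intensity_smoothing = intensity_smoothing, measure = measure),
    class = "foci_params"
  )
}

# Negated Laplacian-of-Gaussian kernel: positive response on bright blobs of
# scale ~sigma.
log_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  ax <- -half:half
  r2 <- outer(ax^2, ax^2, "+")
  k <- -(r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k) # zero-sum: flat regions give exactly zero response
}

#' Detect fluorescent foci per segmented cell
#'
#' Uses the segmented cell shapes as masks on the fluorescence channel: for
#' each kept cell the padded bounding box is extracted, pixels outside the
#' cell are replaced by the cell's median intensity (so the cell edge
#' produces no filter response), and the subimage is filtered with a
#' Laplacian-of-Gaussian at `filter_sigma`. Local response maxima at least
#' `min_separation` apart are kept when their measured intensity exceeds
#' the cell's median + `threshold_k` x robust SD (MAD x 1.4826), both
#' statistics taken over that cell's pixels. Cells excluded by QC contribute
#' no counts. Ties between equal-response maxima are broken by smallest
#' (row, col) for determinism.
#'
#' @param fluorescence_image Numeric matrix, same shape as `label_mask`.
#' @param label_mask Integer label matrix from segmentation.
#' @param regions Region tibble; if it carries a `qc_status` column only
#'   `kept` cells are analysed.
#' @param params A [foci_params()].
#' @return A list with `peaks` (tibble: `cell_id`, `row`, `col`, `response`,
#'   `raw_intensity`) and `counts` (tibble: `cell_id`, `n_foci`, one row per
#'   analysed cell, zeros included).
#' @export
detect_foci <- function(fluorescence_image, label_mask, regions,
                        params = foci_params()) {
  if (!identical(dim(fluorescence_image), dim(label_mask))) {
    abort("fluorescence image and label mask must have the same shape")
  }
  if ("qc_status" %in% names(regions)) {
    regions <- filter(regions, .data$qc_status == "kept")
  }
  h <- nrow(fluorescence_image)
  w <- ncol(fluorescence_image)
  kern <- log_kernel(params$filter_sigma)
  pad <- max(ceiling(3 * params$filter_sigma),
             ceiling(params$min_separation)) + 1L
  win <- 2L * ceiling(params$min_separation) + 1L
  brush <- EBImage::makeBrush(win, "disc")

  idx <- which(label_mask > 0L)
  pix_by_cell <- split(idx, label_mask[idx])

  per_cell <- purrr::map(regions$cell_id, function(id) {
    pix <- pix_by_cell[[as.character(id)]]
    if (is.null(pix)) {
      return(list(peaks = NULL, count = 0L))
    }
    pr <- (pix - 1L) %% h + 1L
    pc <- (pix - 1L) %/% h + 1L
    r0 <- max(1L, min(pr) - pad)
    r1 <- min(h, max(pr) + pad)
    c0 <- max(1L, min(pc) - pad)
    c1 <- min(w, max(pc) + pad)
    sub <- fluorescence_image[r0:r1, c0:c1, drop = FALSE]
    inside <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    inside[cbind(pr - r0 + 1L, pc - c0 + 1L)] <- TRUE
    cell_median <- stats::median(sub[inside])
    filled <- sub
    filled[!inside] <- cell_median

    resp <- EBImage::filter2(filled, kern, boundary = "replicate")
    meas <- if (params$intensity_smoothing > 0) {
      EBImage::gblur(filled, sigma = params$intensity_smoothing)
    } else {
      filled
    }
    eps <- 1e-6 * max(diff(range(filled)), 1e-3)
    local_max <- EBImage::dilate(resp, brush)
    cand <- which(inside & resp >= local_max - 1e-12 & resp > eps)
    # robust references: iterated upper sigma-clipping removes focus pixels
    # from the cell's own background estimate (negligible bias when the
    # cell has no foci; see the clipped-normal expectation)
    if (params$measure %in% c("both", "intensity")) {
      ref <- clipped_stats(meas[inside])
      # floor the scale at a ppm of the cell level so that, in noise-free
      # cells (MAD = 0), sub-resolution spillover from neighbouring cells'
      # focus tails cannot pass the gate
      rsd <- max(ref$rsd, 1e-5 * max(abs(ref$med), 1))
      cand <- cand[meas[cand] > ref$med + params$threshold_k * rsd]
    }
    if (params$measure %in% c("both", "response")) {
      ref <- clipped_stats(resp[inside])
      cand <- cand[resp[cand] > ref$med + params$threshold_k * ref$rsd]
    }
    if (length(cand) == 0L) {
      return(list(peaks = NULL, count = 0L))
    }
    nr <- r1 - r0 + 1L
    peaks <- tibble(
      cell_id = id,
      row = as.integer((cand - 1L) %% nr + 1L) + r0 - 1L,
      col = as.integer((cand - 1L) %/% nr + 1L) + c0 - 1L,
      response = resp[cand],
      raw_intensity = meas[cand]
    ) |>
      arrange(dplyr::desc(.data$response), .data$row, .data$col)
    peaks <- enforce_separation(peaks, params$min_separation)
    list(peaks = peaks, count = nrow(peaks))
  })

  peaks <- bind_rows(purrr::compact(purrr::map(per_cell, "peaks")))
  if (nrow(peaks) == 0L) {
    peaks <- tibble(cell_id = integer(), row = integer(), col = integer(),
                    response = numeric(), raw_intensity = numeric())
  }
  counts <- tibble(
    cell_id = regions$cell_id,
    n_foci = purrr::map_int(per_cell, "count")
  )
  list(peaks = peaks, counts = counts)
}

# Median/MAD with iterated upper sigma-clipping: values above
# median + clip_k * MAD are discarded and the statistics recomputed, until
# stable. Bright focus pixels (an upward contamination) are excluded from
# the background estimate; for an uncontaminated Gaussian sample the clip
# removes only the extreme upper tail, leaving the estimate essentially
# unbiased.
clipped_stats <- function(v, clip_k = 3, max_iter = 10L) {
  for (i in seq_len(max_iter)) {
    med <- stats::median(v)
    rsd <- stats::mad(v)
    keep <- v <= med + clip_k * rsd
    if (all(keep)) break
    v <- v[keep]
  }
  list(med = stats::median(v), rsd = stats::mad(v))
}

# Greedy min-separation filter on peaks already sorted by decreasing
# response (ties by row, col).
enforce_separation <- function(df, min_sep) {
  if (nrow(df) <= 1L) return(df)
  keep <- logical(nrow(df))
  kr <- numeric(0)
  kc <- numeric(0)
  for (i in seq_len(nrow(df))) {
    if (length(kr) == 0L ||
        min((kr - df$row[i])^2 + (kc - df$col[i])^2) >= min_sep^2) {
      keep[i] <- TRUE
      kr <- c(kr, df$row[i])
      kc <- c(kc, df$col[i])
    }
  }
  df[keep, , drop = FALSE]
}

#' Summarise per-cell focus counts as a population histogram
#'
#' @param counts Tibble with an `n_foci` column (or a bare integer vector).
#' @param max_bin Top category; counts `>= max_bin` are pooled into it.
#' @return A tibble of class `foci_distribution` with columns `bin`
#'   (`"0"`..`">=4"`), `count` and `fraction`; the number of cells is
#'   attached as attribute `n_cells`.
#' @export
summarize_foci <- function(counts, max_bin = 4L) {
  n_foci <- if (is.data.frame(counts)) counts$n_foci else counts
  if (length(n_foci) == 0L) {
    abort("cannot summarise a distribution over zero cells")
  }
  if (any(n_foci < 0)) abort("focus counts must be >= 0")
  binned <- pmin(n_foci, max_bin)
  levels <- c(as.character(seq_len(max_bin) - 1L), paste0(">=", max_bin))
  tab <- tabulate(binned + 1L, nbins = max_bin + 1L)
  out <- tibble(
    bin = factor(levels, levels = levels),
    count = as.integer(tab),
    fraction = tab / length(n_foci)
  )
  attr(out, "n_cells") <- length(n_foci)
  class(out) <- c("foci_distribution", class(out))
  out
}

#' Score detected focus counts against planted ground truth
#'
#' Matches segmented cells to ground-truth cells by nearest centroid within
#' `max_dist` (greedy one-to-one, closest pairs first) and compares counts.
#'
#' @param counts Per-cell counts tibble from [detect_foci()].
#' @param regions Region tibble carrying centroids for the counted cells.
#' @param truth Ground-truth tibble from [simulate_microscopy()] (`cell_id`,
#'   `row`, `col`, `foci_count`).
#' @param max_dist Maximum centroid distance for a match, pixels.
#' @return A list with `exact_match_rate`, `n_matched`, and `confusion`
#'   (tibble: `planted`, `detected`, `n`).
#' @export
score_detection <- function(counts, regions, truth, max_dist = 5) {
  det <- counts |> left_join(regions, by = "cell_id")
  if (nrow(det) == 0L || nrow(truth) == 0L) abort("no cells to match")
  pairs <- tidyr::crossing(det_idx = seq_len(nrow(det)),
                           truth_idx = seq_len(nrow(truth))) |>
    mutate(d = sqrt((det$row[.data$det_idx] - truth$row[.data$truth_idx])^2 +
                      (det$col[.data$det_idx] - truth$col[.data$truth_idx])^2)) |>
    filter(.data$d <= max_dist) |>
    arrange(.data$d)
  used_det <- logical(nrow(det))
  used_truth <- logical(nrow(truth))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    di <- pairs$det_idx[i]
    ti <- pairs$truth_idx[i]
    if (!used_det[di] && !used_truth[ti]) {
      keep[i] <- TRUE
      used_det[di] <- TRUE
      used_truth[ti] <- TRUE
    }
  }
  matched <- pairs[keep, , drop = FALSE]
  if (nrow(matched) == 0L) abort("no cells matched within max_dist")
  planted <- truth$foci_count[matched$truth_idx]
  detected <- det$n_foci[matched$det_idx]
  confusion <- tibble(planted = planted, detected = detected) |>
    dplyr::count(.data$planted, .data$detected, name = "n")
  list(
    exact_match_rate = mean(planted == detected),
    n_matched = nrow(matched),
    confusion = confusion
  )
}
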