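# Cell segmentation from phase-contrast images, plus the shape-quality
# exclusions applied before any per-cell measurement. The classical splitter
# mirrors the circumference/interior two-label idea: touching cells are cut
# at their contact neck, where the distance-to-background saddle is deepest,
# by a depth-limited watershed on the distance transform.

#' Segmentation parameters
#'
#' @param method `"classical"` (threshold + erosion split) or `"imported"`
#'   (masks supplied via [import_mask()]).
#' @param smoothing_sigma Gaussian pre-smoothing sigma in pixels (0 = none).
#' @param threshold_policy `"global-otsu"` or `"local-mean"`.
#' @param local_window Window size (pixels, odd) for the local-mean policy.
#' @param local_offset Offset below the local mean (fraction of the image
#'   intensity range) a pixel must fall to count as cell.
#' @param boundary_erosion Depth (pixels) of the distance-transform saddle
#'   at which touching cells are split by watershed; 0 disables splitting.
#'   Small values split shallower necks but may oversplit bumpy single
#'   cells.
#' @param min_area,max_area Area bounds in pixels; regions with
#'   `area < min_area` or `area > max_area` are excluded (bounds inclusive
#'   on the kept side).
#' @param min_solidity Minimum solidity; below it a region is excluded as
#'   crooked.
#' @param border_margin Regions with pixels within this many pixels of the
#'   image border are excluded.
#' @return A validated list of class `segmentation_params`.
#' @export
segmentation_params <- function(method = c("classical", "imported"),
                                smoothing_sigma = 0.5,
                                threshold_policy = c("global-otsu", "local-mean"),
                                local_window = 31L,
                                local_offset = 0.1,
                                boundary_erosion = 2L,
                                min_area = 50,
                                max_area = 2000,
                                min_solidity = 0.85,
                                border_margin = 1L) {
  method <- match.arg(method)
  threshold_policy <- match.arg(threshold_policy)
  if (min_area >= max_area) abort("min_area must be < max_area")
  if (min_solidity <= 0 || min_solidity > 1) {
    abort("min_solidity must be in (0, 1]")
  }
  if (boundary_erosion < 0) abort("boundary_erosion must be >= 0")
  structure(
    list(
      method = method, smoothing_sigma = smoothing_sigma,
      threshold_policy = threshold_policy,
      local_window = as.integer(local_window), local_offset = local_offset,
      boundary_erosion = as.integer(boundary_erosion),
      min_area = min_area, max_area = max_area,
      min_solidity = min_solidity, border_margin = as.integer(border_margin)
    ),
    class = "segmentation_params"
  )
}

# Region properties for every positive label in a mask.
region_table <- function(mask, border_margin = 1L) {
  h <- nrow(mask)
  w <- ncol(mask)
  idx <- which(mask > 0L)
  if (length(idx) == 0L) {
    return(tibble(
      cell_id = integer(), area = integer(), row = numeric(), col = numeric(),
      solidity = numeric(), eccentricity = numeric(), touches_border = logical()
    ))
  }
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  lab <- mask[idx]
  by_lab <- split(seq_along(idx), lab)
  out <- purrr::map(names(by_lab), function(l) {
    sel <- by_lab[[l]]
    r <- rows[sel]
    c <- cols[sel]
    tibble(
      cell_id = as.integer(l),
      area = length(sel),
      row = mean(r),
      col = mean(c),
      solidity = pixel_solidity(r, c),
      eccentricity = pixel_eccentricity(r, c),
      touches_border = min(r) <= border_margin || max(r) > h - border_margin ||
        min(c) <= border_margin || max(c) > w - border_margin
    )
  })
  bind_rows(out) |> arrange(.data$cell_id)
}

# Solidity of a pixel set: pixel count over the pixel area of its convex
# hull. The hull polygon through pixel centres is corrected by half the
# perimeter plus one (Pick-style) so a convex pixel blob scores ~1.
pixel_solidity <- function(r, c) {
  n <- length(r)
  if (n <= 3L) return(1)
  pts <- unique(cbind(r, c))
  if (nrow(pts) <= 3L) return(1)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[hull, , drop = FALSE]
  k <- nrow(hp)
  if (k < 3L) return(1)
  nxt <- c(2:k, 1L)
  poly_area <- abs(sum(hp[, 2] * hp[nxt, 1] - hp[nxt, 2] * hp[, 1])) / 2
  peri <- sum(sqrt(rowSums((hp - hp[nxt, , drop = FALSE])^2)))
  min(n / (poly_area + peri / 2 + 1), 1)
}

# Eccentricity from central second moments (0 = circle, -> 1 elongated).
pixel_eccentricity <- function(r, c) {
  if (length(r) < 2L) return(0)
  mu20 <- stats::var(r) + 1 / 12
  mu02 <- stats::var(c) + 1 / 12
  mu11 <- stats::cov(r, c)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(1 - l2 / l1, 0))
}

#' Segment cells in a phase-contrast image
#'
#' Smooths, thresholds (dark interiors = cell), optionally splits touching
#' cells by a depth-limited watershed on the distance transform of the
#' binary mask, and measures every labelled region.
#'
#' @param phase_image Single-channel numeric matrix.
#' @param params A [segmentation_params()].
#' @return A list with `mask` (integer label matrix, 0 = background) and
#'   `regions` (tibble: `cell_id`, `area`, centroid `row`/`col`, `solidity`,
#'   `eccentricity`, `touches_border`).
#' @export
segment_cells <- function(phase_image, params = segmentation_params()) {
  if (!is.matrix(phase_image) || !is.numeric(phase_image)) {
    abort("phase_image must be a single-channel numeric matrix")
  }
  if (length(phase_image) == 0L) abort("phase_image is empty")
  rng <- range(phase_image)
  if (diff(rng) == 0) {
    # featureless image: nothing to segment
    mask <- matrix(0L, nrow(phase_image), ncol(phase_image))
    return(list(mask = mask, regions = region_table(mask, params$border_margin)))
  }
  x <- (phase_image - rng[1]) / diff(rng)
  if (params$smoothing_sigma > 0) {
    x <- EBImage::gblur(x, sigma = params$smoothing_sigma)
  }
  if (params$threshold_policy == "global-otsu") {
    th <- EBImage::otsu(EBImage::Image(x))
    binary <- x < th
  } else {
    win <- params$local_window
    box <- matrix(1 / win^2, win, win)
    local_mean <- EBImage::filter2(x, box)
    binary <- x < local_mean - params$local_offset
  }
  mask <- label_with_split(binary, params$boundary_erosion, x)
  list(mask = mask, regions = region_table(mask, params$border_margin))
}

label_with_split <- function(binary, boundary_erosion, x) {
  storage.mode(binary) <- "double"
  if (boundary_erosion > 0) {
    # split touching cells at their contact neck: watershed on the distance
    # transform, with the erosion radius as the minimal basin depth so the
    # flat ridge of a single rod is not oversplit
    dm <- EBImage::distmap(binary)
    mask <- EBImage::watershed(dm, tolerance = boundary_erosion)
  } else {
    mask <- EBImage::bwlabel(binary)
  }
  mask <- as.matrix(mask)
  # relabel to consecutive integers for stable downstream ids
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) > 0L && !identical(as.integer(labs), seq_along(labs))) {
    remap <- integer(max(labs))
    remap[labs] <- seq_along(labs)
    pos <- mask > 0
    mask[pos] <- remap[mask[pos]]
  }
  storage.mode(mask) <- "integer"
  mask
}

#' Apply shape-quality exclusions to segmented regions
#'
#' Excludes regions touching the image border, very small or very large
#' regions, and crooked (low-solidity) regions. Each excluded region carries
#' exactly one reason, assigned in the fixed priority order border > small >
#' large > crooked; kept regions satisfy all four criteria. Idempotent.
#'
#' @param regions Region tibble from [segment_cells()] or [import_mask()].
#' @param params A [segmentation_params()].
#' @return The regions tibble with a `qc_status` column
#'   (`kept`, `excluded:border`, `excluded:small`, `excluded:large`,
#'   `excluded:crooked`).
#' @export
apply_qc <- function(regions, params = segmentation_params()) {
  regions |>
    mutate(qc_status = dplyr::case_when(
      .data$touches_border ~ "excluded:border",
      .data$area < params$min_area ~ "excluded:small",
      .data$area > params$max_area ~ "excluded:large",
      .data$solidity < params$min_solidity ~ "excluded:crooked",
      TRUE ~ "kept"
    ))
}

#' Import an externally produced label mask
#'
#' Lets masks from any external segmenter (for example a trained neural
#' network) enter the pipeline with the same downstream contract as
#' [segment_cells()].
#'
#' @param mask An integer-labelled matrix, or the path of a TIFF file
#'   holding one (16-bit grayscale).
#' @param reference_image Optional image whose shape the mask must match.
#' @param border_margin Border margin used for the `touches_border` flag.
#' @return A list with `mask` and `regions`, as for [segment_cells()].
#' @export
import_mask <- function(mask, reference_image = NULL, border_margin = 1L) {
  if (is.character(mask)) {
    mask <- tiff::readTIFF(mask, as.is = TRUE)
  }
  if (!is.matrix(mask) || !is.numeric(mask)) {
    abort("mask must be a 2-D numeric matrix or a TIFF path")
  }
  if (any(is.na(mask)) || any(mask < 0) || any(abs(mask - round(mask)) > 1e-6)) {
    abort("mask must contain nonnegative integer labels")
  }
  if (!is.null(reference_image) &&
      !identical(dim(mask), dim(reference_image))) {
    abort("mask shape does not match the reference image")
  }
  storage.mode(mask) <- "integer"
  list(mask = mask, regions = region_table(mask, border_margin))
}

#' Write a label mask as 16-bit grayscale TIFF
#'
#' Round-trips exactly through [import_mask()] for labels up to 65535.
#'
#' @param mask Integer label matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535L) abort("labels exceed the 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
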