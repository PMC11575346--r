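# Colony appearance/growth-time extraction from scanner time-lapse stacks:
# background subtraction against the first frame, thresholding, connected
# components, nearest-centroid linking, and threshold-crossing scans at the
# classical ScanLag definitions (appearance = 10 px, growth = 80 -> 160 px,
# one frame every 20 min).

#' Build a frame series
#'
#' @param frames List of numeric matrices, all the same shape.
#' @param interval Minutes between frames (constant spacing).
#' @param start Time of the first frame, minutes.
#' @param times Alternatively, an explicit vector of frame times; must be
#'   strictly increasing with constant step.
#' @return A list of class `frame_series` with `times` and `frames`.
#' @export
frame_series <- function(frames, interval = 20, start = 0, times = NULL) {
  if (length(frames) == 0L) abort("a frame series needs at least one frame")
  dims <- unique(purrr::map(frames, dim))
  if (length(dims) != 1L) abort("all frames must have the same shape")
  if (is.null(times)) {
    times <- start + interval * (seq_along(frames) - 1L)
  }
  if (length(times) != length(frames)) {
    abort("times and frames must have equal length")
  }
  if (length(times) > 1L) {
    steps <- diff(times)
    if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-9) {
      abort("frame times must be strictly increasing with a constant step")
    }
  }
  structure(list(times = as.numeric(times), frames = frames),
            class = "frame_series")
}

#' Detect and track colonies across a frame series
#'
#' Subtracts the first frame as background reference, thresholds, labels
#' connected components of at least `min_blob_px` pixels, and links
#' components across frames to the nearest existing track centroid within
#' `link_radius_px`. Unlinked components open new tracks; tracks whose
#' nearest component is claimed by another track are flagged `merged`
#' (tracking ambiguity) and excluded from summaries. Area series are
#' backfilled with 0 before first detection.
#'
#' @param series A [frame_series()] with at least 2 frames.
#' @param min_blob_px Minimum component size, pixels.
#' @param link_radius_px Maximum centroid displacement for linking, pixels.
#' @param intensity_threshold Background-subtracted intensity above which a
#'   pixel counts as colony.
#' @return A tibble of class `colony_tracks`: `colony_id`, centroid
#'   `row`/`col`, `merged`, and list-column `area_series` (pixels per
#'   frame); frame times are attached as attribute `times`.
#' @export
detect_and_track <- function(series, min_blob_px = 2L, link_radius_px = 15,
                             intensity_threshold = 0.5) {
  stopifnot(inherits(series, "frame_series"))
  if (length(series$frames) < 2L) abort("need at least 2 frames to track")
  ref <- series$frames[[1]]
  n_frames <- length(series$frames)

  tracks <- list() # each: row, col, merged, areas (numeric n_frames)
  for (f in seq_len(n_frames)) {
    diffimg <- series$frames[[f]] - ref
    binary <- diffimg > intensity_threshold
    storage.mode(binary) <- "double"
    lab <- EBImage::bwlabel(binary)
    comp <- region_table(lab, border_margin = 0L) |>
      filter(.data$area >= min_blob_px)
    if (nrow(comp) == 0L) next

    assigned <- rep(NA_integer_, nrow(comp))
    if (length(tracks) > 0L) {
      # each live track claims its nearest component within the link radius
      claims <- purrr::map_int(tracks, function(tr) {
        d2 <- (comp$row - tr$row)^2 + (comp$col - tr$col)^2
        j <- which.min(d2)
        if (d2[j] <= link_radius_px^2) j else NA_integer_
      })
      for (j in unique(stats::na.omit(claims))) {
        claimants <- which(claims == j)
        if (length(claimants) > 1L) {
          for (ti in claimants) tracks[[ti]]$merged <- TRUE
        }
        winner <- claimants[1L]
        tracks[[winner]]$row <- comp$row[j]
        tracks[[winner]]$col <- comp$col[j]
        tracks[[winner]]$areas[f] <- comp$area[j]
        assigned[j] <- winner
      }
    }
    for (j in which(is.na(assigned))) {
      tracks[[length(tracks) + 1L]] <- list(
        row = comp$row[j], col = comp$col[j], merged = FALSE,
        areas = c(rep(0, f - 1L), comp$area[j], rep(0, n_frames - f))
      )
    }
  }

  out <- tibble(
    colony_id = seq_along(tracks),
    row = purrr::map_dbl(tracks, "row"),
    col = purrr::map_dbl(tracks, "col"),
    merged = purrr::map_lgl(tracks, "merged"),
    area_series = purrr::map(tracks, "areas")
  )
  attr(out, "times") <- series$times
  class(out) <- c("colony_tracks", class(out))
  out
}

# Running-maximum cleaning: the threshold definitions presuppose monotone
# growth, so flicker is removed before scanning for crossings.
clean_area_series <- function(areas) cummax(areas)

#' Colony appearance time
#'
#' Time of the first frame at which the (running-maximum cleaned) colony
#' area reaches `threshold_px` pixels; `NA` (censored) if never reached.
#' No interpolation: resolution equals the frame interval.
#'
#' @param area_series Numeric vector of per-frame areas (pixels).
#' @param times Frame times, minutes.
#' @param threshold_px Appearance threshold, pixels (default 10).
#' @return Appearance time in minutes, or `NA` if censored.
#' @export
appearance_time <- function(area_series, times, threshold_px = 10) {
  a <- clean_area_series(area_series)
  i <- which(a >= threshold_px)[1]
  if (is.na(i)) NA_real_ else times[i]
}

#' Colony growth time
#'
#' Time needed for the colony area to increase from `low_px` to `high_px`
#' pixels: (first time area >= `high_px`) - (first time area >= `low_px`).
#' `NA` (censored) if `high_px` is never reached. Crossing both thresholds
#' in the same frame gives 0.
#'
#' @inheritParams appearance_time
#' @param low_px,high_px Area thresholds, pixels (defaults 80 and 160).
#' @return Growth time in minutes, or `NA` if censored.
#' @export
growth_time <- function(area_series, times, low_px = 80, high_px = 160) {
  a <- clean_area_series(area_series)
  i_low <- which(a >= low_px)[1]
  i_high <- which(a >= high_px)[1]
  if (is.na(i_high) || is.na(i_low)) NA_real_ else times[i_high] - times[i_low]
}

#' Summarise appearance and growth times over tracked colonies
#'
#' Merged tracks are dropped; the median is computed over uncensored
#' appearance times only.
#'
#' @param tracks A `colony_tracks` tibble from [detect_and_track()].
#' @param appearance_px,growth_low_px,growth_high_px Pixel thresholds.
#' @return A list of class `appearance_summary` with `times` (tibble:
#'   `colony_id`, `appearance_min`, `growth_min`, censoring flags),
#'   `n_colonies`, `n_censored` and `median_appearance`.
#' @export
summarize_appearance <- function(tracks, appearance_px = 10,
                                 growth_low_px = 80, growth_high_px = 160) {
  stopifnot(inherits(tracks, "colony_tracks"))
  times <- attr(tracks, "times")
  usable <- filter(tracks, !.data$merged)
  if (nrow(usable) == 0L) abort("no unmerged tracks to summarise")
  tbl <- usable |>
    mutate(
      appearance_min = purrr::map_dbl(.data$area_series, appearance_time,
                                      times = times,
                                      threshold_px = appearance_px),
      growth_min = purrr::map_dbl(.data$area_series, growth_time,
                                  times = times, low_px = growth_low_px,
                                  high_px = growth_high_px),
      appearance_censored = is.na(.data$appearance_min),
      growth_censored = is.na(.data$growth_min)
    ) |>
    select("colony_id", "appearance_min", "growth_min",
           "appearance_censored", "growth_censored")
  uncensored <- tbl$appearance_min[!tbl$appearance_censored]
  if (length(uncensored) == 0L) {
    abort("all appearance times are censored; no summary possible")
  }
  structure(
    list(
      times = tbl,
      n_colonies = nrow(tbl),
      n_censored = sum(tbl$appearance_censored),
      median_appearance = stats::median(uncensored)
    ),
    class = "appearance_summary"
  )
}

#' Compare appearance-time distributions between two conditions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact enumeration when
#' both groups have at most 8 uncensored colonies, tie-corrected normal
#' approximation otherwise.
#'
#' @param group_a,group_b Numeric vectors of appearance times, or
#'   `appearance_summary` objects (their uncensored appearance times are
#'   used).
#' @return A tibble with `u` (U statistic of group A), `p` (two-sided),
#'   `n_a`, `n_b` and `method`.
#' @export
compare_appearance <- function(group_a, group_b) {
  grab <- function(g) {
    if (inherits(g, "appearance_summary")) {
      g$times$appearance_min[!g$times$appearance_censored]
    } else {
      as.numeric(g[!is.na(g)])
    }
  }
  a <- grab(group_a)
  b <- grab(group_b)
  res <- mann_whitney_u(a, b)
  tibble(u = res$u, p = res$p, n_a = res$n_x, n_b = res$n_y,
         method = res$method)
}

#' Long-format export of colony tracks
#'
#' @param tracks A `colony_tracks` tibble.
#' @return A tibble with `colony_id`, `frame`, `time_min`, `area_px`.
#' @export
tracks_long <- function(tracks) {
  stopifnot(inherits(tracks, "colony_tracks"))
  times <- attr(tracks, "times")
  tracks |>
    select("colony_id", "area_series") |>
    mutate(frame = list(seq_along(times)), time_min = list(times)) |>
    tidyr::unnest(c("area_series", "frame", "time_min")) |>
    select("colony_id", "frame", "time_min", area_px = "area_series")
}
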