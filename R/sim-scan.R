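# Synthetic colony time-lapse (ScanLag-style) generator.
#
# Each colony sits at a fixed centre, stays invisible during its lag, then
# grows with a logistic area curve; frames render each colony as a filled
# disk of the matching area. The planted appearance time is read off the
# rendered pixel counts, so it agrees with what any detector can see.

logistic_area <- function(t, lag, rate, capacity, a0 = 1) {
  ifelse(t < lag, 0,
         capacity / (1 + (capacity / a0 - 1) * exp(-rate * (t - lag))))
}

disk_pixels <- function(row, col, radius, nrow_img, ncol_img) {
  if (radius <= 0) {
    return(matrix(numeric(0), ncol = 2L))
  }
  r0 <- max(1L, floor(row - radius))
  r1 <- min(nrow_img, ceiling(row + radius))
  c0 <- max(1L, floor(col - radius))
  c1 <- min(ncol_img, ceiling(col + radius))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  keep <- (rr - row)^2 + (cc - col)^2 <= radius^2
  cbind(rr[keep], cc[keep])
}

#' Simulate a colony time-lapse frame stack with ground truth
#'
#' Renders one frame per `frame_interval` minutes over `total_duration`.
#' Colony centres are placed at least `min_center_distance` apart (error on
#' failure after a bounded number of attempts, to avoid tracking ambiguity).
#' Lag times are Normal(`lag_mean`, `lag_sd`) truncated at 0; area follows a
#' logistic curve after the lag. The planted appearance time of a colony is
#' the first frame time at which its rendered pixel count reaches
#' `appearance_px`; colonies that never reach it are censored (`NA`).
#'
#' @param spec A [scan_sim_spec()].
#' @param appearance_px Appearance threshold in pixels used for the planted
#'   ground truth (default 10).
#' @return A list of class `scan_sim` with elements:
#'   * `series`: a [frame_series()] of rendered frames (background 0,
#'     colony intensity 1, plus optional Gaussian noise);
#'   * `colonies`: tibble (`colony_id`, `row`, `col`, `lag_min`,
#'     `growth_rate`, `appearance_min` with `NA` = censored);
#'   * `areas`: integer matrix of rendered pixel counts, colonies x frames;
#'   * `spec`: the input spec.
#' @export
simulate_scan <- function(spec, appearance_px = 10) {
  stopifnot(inherits(spec, "scan_sim_spec"))
  set.seed(spec$seed)
  h <- spec$plate_height
  w <- spec$plate_width
  n <- spec$n_colonies
  times <- seq(0, spec$total_duration, by = spec$frame_interval)
  n_frames <- length(times)

  margin <- spec$min_center_distance / 2
  centers <- matrix(numeric(0), ncol = 2L)
  attempts <- 0L
  max_attempts <- 500L * max(n, 1L)
  while (nrow(centers) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(paste0(
        "colony placement failed after ", max_attempts, " attempts: ",
        "colonies closer than min_center_distance would merge ",
        "(reduce n_colonies or min_center_distance)"
      ))
    }
    cand <- c(stats::runif(1, margin, h - margin),
              stats::runif(1, margin, w - margin))
    if (nrow(centers) > 0L) {
      d2 <- (centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2
      if (min(d2) < spec$min_center_distance^2) next
    }
    centers <- rbind(centers, cand)
  }

  lag <- pmax(stats::rnorm(n, spec$lag_mean, spec$lag_sd), 0)
  rate <- stats::runif(n, spec$growth_rate_range[1], spec$growth_rate_range[2])

  frames <- vector("list", n_frames)
  areas <- matrix(0L, nrow = n, ncol = n_frames)
  for (f in seq_len(n_frames)) {
    img <- matrix(0, h, w)
    if (n > 0L) {
      a <- logistic_area(times[f], lag, rate, spec$carrying_capacity)
      for (i in seq_len(n)) {
        px <- disk_pixels(centers[i, 1], centers[i, 2], sqrt(a[i] / pi), h, w)
        areas[i, f] <- nrow(px)
        if (nrow(px) > 0L) img[px] <- 1
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    }
    frames[[f]] <- img
  }
  # rendered pixel counts are nondecreasing because the radius is; guard anyway
  areas <- t(apply(areas, 1L, cummax))
  if (n == 0L) areas <- matrix(0L, 0L, n_frames)

  appearance <- apply(areas, 1L, function(a) {
    i <- which(a >= appearance_px)[1]
    if (is.na(i)) NA_real_ else times[i]
  })
  if (n == 0L) appearance <- numeric(0)

  colonies <- tibble(
    colony_id = seq_len(n),
    row = if (n > 0L) centers[, 1] else numeric(0),
    col = if (n > 0L) centers[, 2] else numeric(0),
    lag_min = lag,
    growth_rate = rate,
    appearance_min = appearance
  )

  structure(
    list(
      series = frame_series(frames, interval = spec$frame_interval),
      colonies = colonies,
      areas = areas,
      spec = spec
    ),
    class = "scan_sim"
  )
}
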