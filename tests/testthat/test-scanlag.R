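test_that("frame series validate spacing and shapes", {
  f <- replicate(3, matrix(0, 4, 4), simplify = FALSE)
  fs <- frame_series(f, interval = 20)
  expect_equal(fs$times, c(0, 20, 40))
  expect_error(frame_series(list(matrix(0, 2, 2), matrix(0, 3, 3))), "shape")
  expect_error(frame_series(f, times = c(0, 20, 30)), "constant step")
})

test_that("appearance time applies the 10-pixel first-crossing rule", {
  areas <- c(0, 0, 6, 12, 40, 90, 170)
  times <- seq(0, 120, by = 20)
  expect_equal(appearance_time(areas, times), 60)
  expect_true(is.na(appearance_time(rep(5, 7), times)))
})

test_that("growth time measures the 80-to-160-pixel increase", {
  areas <- c(0, 0, 6, 12, 40, 90, 170)
  times <- seq(0, 120, by = 20)
  expect_equal(growth_time(areas, times), 20)
  # both thresholds crossed within a single frame
  expect_equal(growth_time(c(0, 70, 200), c(0, 20, 40)), 0)
  expect_true(is.na(growth_time(c(0, 50, 100), c(0, 20, 40))))
})

test_that("threshold scans agree with a brute-force crossing search", {
  set.seed(7)
  times <- seq(0, 480, by = 20)
  for (i in 1:100) {
    areas <- random_monotone_series(length(times))
    expect_identical(appearance_time(areas, times),
                     oracle_appearance(areas, times, 10))
    expect_identical(growth_time(areas, times),
                     oracle_growth(areas, times, 80, 160))
  }
})

test_that("appearance time cannot increase when the threshold is lowered", {
  set.seed(8)
  times <- seq(0, 480, by = 20)
  for (i in 1:30) {
    areas <- random_monotone_series(length(times))
    t_low <- appearance_time(areas, times, threshold_px = 5)
    t_high <- appearance_time(areas, times, threshold_px = 20)
    if (!is.na(t_low) && !is.na(t_high)) expect_lte(t_low, t_high)
    g <- growth_time(areas, times)
    if (!is.na(g)) expect_gte(g, 0)
  }
})

test_that("an empty stack yields no tracks", {
  sim <- simulate_scan(scan_sim_spec(n_colonies = 0L, plate_height = 60L,
                                     plate_width = 60L, total_duration = 200,
                                     seed = 1))
  tracks <- detect_and_track(sim$series)
  expect_equal(nrow(tracks), 0L)
})

test_that("well-separated colonies are each tracked once, near their centre", {
  bench <- benchmark_scan()
  sim <- bench$sim
  tracks <- bench$tracks
  expect_equal(nrow(tracks), nrow(sim$colonies))
  expect_false(any(tracks$merged))
  nearest <- vapply(seq_len(nrow(tracks)), function(i) {
    min(sqrt((sim$colonies$row - tracks$row[i])^2 +
               (sim$colonies$col - tracks$col[i])^2))
  }, 0)
  expect_true(all(nearest <= 2))
})

test_that("tracking the same stack twice gives identical tracks", {
  sim <- simulate_scan(scan_sim_spec(n_colonies = 5L, plate_height = 250L,
                                     plate_width = 250L,
                                     total_duration = 1600, seed = 6))
  a <- detect_and_track(sim$series)
  b <- detect_and_track(sim$series)
  expect_identical(a, b)
})

test_that("extracted appearance times equal planted times on clean stacks", {
  bench <- benchmark_scan()
  summ <- summarize_appearance(bench$tracks)
  match_idx <- vapply(seq_len(nrow(bench$tracks)), function(i) {
    which.min((bench$sim$colonies$row - bench$tracks$row[i])^2 +
                (bench$sim$colonies$col - bench$tracks$col[i])^2)
  }, 0L)
  expect_equal(summ$times$appearance_min,
               bench$sim$colonies$appearance_min[match_idx])
  expect_equal(summ$median_appearance,
               median(bench$sim$colonies$appearance_min, na.rm = TRUE))
})

test_that("appearance summaries report medians over uncensored colonies", {
  mk_tracks <- function(area_lists, times) {
    out <- tibble::tibble(
      colony_id = seq_along(area_lists),
      row = 1, col = 1, merged = FALSE, area_series = area_lists
    )
    attr(out, "times") <- times
    class(out) <- c("colony_tracks", class(out))
    out
  }
  times <- seq(0, 900, by = 20)
  ramp <- function(at) ifelse(times < at, 0, 200)
  tr <- mk_tracks(list(ramp(800), ramp(820), ramp(840)), times)
  summ <- summarize_appearance(tr)
  expect_equal(summ$median_appearance, 820)

  single <- mk_tracks(list(ramp(60)), times)
  expect_equal(summarize_appearance(single)$median_appearance, 60)

  censored <- mk_tracks(list(rep(0, length(times))), times)
  expect_error(summarize_appearance(censored), "censored")
})

test_that("the rank-sum comparison matches exact and reference values", {
  res <- compare_appearance(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p, 0.1)

  same <- compare_appearance(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p, 1)

  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(30)
    b <- rnorm(30, 0.4)
    ref <- wilcox.test(a, b, correct = FALSE, exact = FALSE)
    got <- compare_appearance(a, b)
    expect_equal(got$p, ref$p.value, tolerance = 1e-6)
    expect_equal(got$u, unname(ref$statistic))
  }
})

test_that("long-format export matches the per-track series", {
  bench <- benchmark_scan()
  long <- tracks_long(bench$tracks)
  expect_equal(nrow(long),
               nrow(bench$tracks) * length(attr(bench$tracks, "times")))
  one <- long[long$colony_id == 1, ]
  expect_equal(one$area_px, bench$tracks$area_series[[1]])
})
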