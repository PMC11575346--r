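test_that("a featureless image yields an empty mask and no regions", {
  out <- segment_cells(matrix(500, 40, 40))
  expect_true(all(out$mask == 0L))
  expect_equal(nrow(out$regions), 0L)
})

test_that("multi-channel or empty input is rejected", {
  expect_error(segment_cells(array(0, c(4, 4, 3))), "matrix")
  expect_error(segment_cells(matrix(numeric(0), 0, 0)), "empty")
})

test_that("two planted non-touching rods are recovered with accurate areas", {
  spec <- microscopy_sim_spec(image_height = 200L, image_width = 200L,
                              n_cells = 2L, noise_sd = 0,
                              foci_count_probs = 1, seed = 2)
  sim <- simulate_microscopy(spec)
  out <- segment_cells(sim$phase)
  expect_equal(nrow(out$regions), 2L)
  planted <- sort(tabulate(sim$truth_mask[sim$truth_mask > 0]))
  found <- sort(out$regions$area)
  expect_true(all(abs(found / planted - 1) <= 0.10))
})

test_that("touching pairs split only when boundary splitting is enabled", {
  spec <- microscopy_sim_spec(image_height = 260L, image_width = 260L,
                              n_cells = 2L, n_touching_pairs = 1L,
                              noise_sd = 0, foci_count_probs = 1, seed = 5)
  sim <- simulate_microscopy(spec)
  merged <- segment_cells(sim$phase,
                          segmentation_params(boundary_erosion = 0L))
  split1 <- segment_cells(sim$phase,
                          segmentation_params(boundary_erosion = 1L))
  split2 <- segment_cells(sim$phase, segmentation_params())
  expect_equal(nrow(merged$regions), 1L)
  expect_equal(nrow(split1$regions), 2L)
  expect_equal(nrow(split2$regions), 2L)
})

test_that("mask and region list stay mutually consistent", {
  sim <- benchmark_microscopy()
  mask <- sim$seg$mask
  regions <- sim$seg$regions
  pix_counts <- tabulate(mask[mask > 0], nbins = max(mask))
  expect_equal(regions$area, pix_counts[regions$cell_id])
  expect_setequal(unique(mask[mask > 0]), regions$cell_id)
})

test_that("QC matches an independent predicate filter with fixed priority", {
  params <- segmentation_params(min_area = 50, max_area = 2000,
                                min_solidity = 0.85, border_margin = 1L)
  set.seed(99)
  regions <- tibble::tibble(
    cell_id = 1:100,
    area = sample(c(10, 50, 300, 2000, 5000), 100, replace = TRUE),
    row = runif(100, 1, 100), col = runif(100, 1, 100),
    solidity = runif(100, 0.5, 1),
    eccentricity = runif(100),
    touches_border = sample(c(TRUE, FALSE), 100, replace = TRUE,
                            prob = c(0.2, 0.8))
  )
  got <- apply_qc(regions, params)
  want <- vapply(seq_len(100), function(i) {
    if (regions$touches_border[i]) return("excluded:border")
    if (regions$area[i] < params$min_area) return("excluded:small")
    if (regions$area[i] > params$max_area) return("excluded:large")
    if (regions$solidity[i] < params$min_solidity) return("excluded:crooked")
    "kept"
  }, "")
  expect_equal(got$qc_status, want)
  # partition is exhaustive; kept regions satisfy all four criteria
  kept <- got[got$qc_status == "kept", ]
  expect_true(all(!kept$touches_border & kept$area >= params$min_area &
                    kept$area <= params$max_area &
                    kept$solidity >= params$min_solidity))
  # area exactly at min_area is kept when everything else passes
  edge <- tibble::tibble(cell_id = 1L, area = 50, row = 50, col = 50,
                         solidity = 1, eccentricity = 0,
                         touches_border = FALSE)
  expect_equal(apply_qc(edge, params)$qc_status, "kept")
})

test_that("QC is idempotent", {
  sim <- benchmark_microscopy()
  once <- apply_qc(sim$seg$regions)
  twice <- apply_qc(once)
  expect_equal(once, twice)
})

test_that("imported masks reproduce regions and round-trip through TIFF", {
  m <- matrix(0L, 5, 5)
  m[1:3, 1] <- 1L
  m[3:5, 4:5] <- 2L
  m[5, 5] <- 0L
  out <- import_mask(m)
  expect_equal(nrow(out$regions), 2L)
  expect_equal(sort(out$regions$area), c(3L, 5L))

  expect_equal(nrow(import_mask(matrix(0L, 4, 4))$regions), 0L)
  expect_error(import_mask(matrix(0.5, 4, 4)), "integer")
  expect_error(import_mask(m, reference_image = matrix(0, 9, 9)), "shape")

  seg <- benchmark_microscopy()$seg
  path <- withr::local_tempfile(fileext = ".tiff")
  write_label_mask(seg$mask, path)
  back <- import_mask(path)
  expect_identical(back$mask, seg$mask)
  expect_equal(back$regions, seg$regions)
})

test_that("most planted cells map one-to-one to kept regions", {
  bench <- benchmark_microscopy()
  sim <- bench$sim
  kept <- bench$qc[bench$qc$qc_status == "kept", ]
  mask <- bench$seg$mask
  iou_ok <- vapply(seq_len(nrow(sim$cells)), function(i) {
    truth_pix <- which(sim$truth_mask == i)
    labs <- mask[truth_pix]
    labs <- labs[labs > 0 & labs %in% kept$cell_id]
    if (length(labs) == 0) return(FALSE)
    lab <- as.integer(names(which.max(table(labs))))
    inter <- sum(mask[truth_pix] == lab)
    union <- length(truth_pix) + sum(mask == lab) - inter
    inter / union > 0.5
  }, TRUE)
  expect_gte(mean(iou_ok), 0.95)
})
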