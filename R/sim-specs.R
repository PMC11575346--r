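# Specification objects for the three synthetic-data generators. Each
# constructor validates its invariants eagerly so downstream code can assume
# a well-formed spec.

#' Specification for the synthetic microscopy generator
#'
#' Describes a field of rod-shaped (spherocylindrical) cells with diffuse
#' cytoplasmic fluorescence plus 0..K punctate Gaussian foci per cell,
#' rendered as a phase-contrast / fluorescence image pair with additive
#' Gaussian camera noise.
#'
#' @param image_height,image_width Image size in pixels.
#' @param n_cells Number of cells to place (rejection sampling,
#'   non-overlapping with 1 px clearance).
#' @param cell_length_range,cell_width_range Min/max cell length and width
#'   in pixels (total capsule length and diameter).
#' @param foci_count_probs Probability vector over per-cell focus counts
#'   0..K; must sum to 1.
#' @param focus_amplitude Peak height of a planted focus as a multiple of
#'   `noise_sd` (when `noise_sd` is 0 the multiplier base is 1 intensity
#'   unit, so noise-free fixtures stay expressible).
#' @param focus_sigma Gaussian sigma of a planted focus, pixels.
#' @param cytoplasm_level,background_level Mean fluorescence intensity inside
#'   and outside cells (arbitrary units).
#' @param noise_sd Additive Gaussian noise SD (both channels).
#' @param border_margin Clearance kept between cells and the image border,
#'   pixels.
#' @param min_focus_separation Minimum pairwise distance between planted
#'   foci within one cell, pixels.
#' @param n_touching_pairs Number of cell pairs planted touching cap-to-cap
#'   (1 px overlap) to exercise boundary splitting.
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return A validated list of class `microscopy_sim_spec`.
#' @export
microscopy_sim_spec <- function(image_height = 1280L,
                                image_width = 1280L,
                                n_cells = 500L,
                                cell_length_range = c(35, 55),
                                cell_width_range = c(10, 14),
                                foci_count_probs = c(0.1, 0.2, 0.4, 0.2, 0.1),
                                focus_amplitude = 5,
                                focus_sigma = 2,
                                cytoplasm_level = 500,
                                background_level = 100,
                                noise_sd = 20,
                                border_margin = 10,
                                min_focus_separation = 10,
                                n_touching_pairs = 0L,
                                seed = 1L) {
  spec <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_cells = as.integer(n_cells),
    cell_length_range = as.numeric(cell_length_range),
    cell_width_range = as.numeric(cell_width_range),
    foci_count_probs = as.numeric(foci_count_probs),
    focus_amplitude = focus_amplitude,
    focus_sigma = focus_sigma,
    cytoplasm_level = cytoplasm_level,
    background_level = background_level,
    noise_sd = noise_sd,
    border_margin = border_margin,
    min_focus_separation = min_focus_separation,
    n_touching_pairs = as.integer(n_touching_pairs),
    seed = as.integer(seed)
  )
  if (spec$image_height <= 0L || spec$image_width <= 0L) {
    abort("image dimensions must be positive")
  }
  if (spec$n_cells < 0L) abort("n_cells must be >= 0")
  if (spec$n_touching_pairs < 0L || 2L * spec$n_touching_pairs > spec$n_cells) {
    abort("n_touching_pairs must satisfy 0 <= 2 * n_touching_pairs <= n_cells")
  }
  check_range <- function(r, what) {
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      abort(paste0(what, " must be (min, max) with 0 < min <= max"))
    }
  }
  check_range(spec$cell_length_range, "cell_length_range")
  check_range(spec$cell_width_range, "cell_width_range")
  p <- spec$foci_count_probs
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("foci_count_probs must be nonnegative and sum to 1")
  }
  if (spec$noise_sd < 0) abort("noise_sd must be >= 0")
  structure(spec, class = "microscopy_sim_spec")
}

#' Specification for the synthetic colony time-lapse generator
#'
#' Colonies appear after heterogeneous (normally distributed, truncated at 0)
#' lag times and then grow with a logistic area curve, rendered as disks on a
#' frame stack sampled at a fixed interval.
#'
#' @param n_colonies Number of colonies to place.
#' @param frame_interval Minutes between frames (default 20).
#' @param total_duration Total imaging time in minutes (default 2400 = 40 h);
#'   must be a multiple of `frame_interval`.
#' @param lag_mean,lag_sd Mean and SD of colony lag times, minutes.
#' @param growth_rate_range Min/max logistic growth rate, per minute.
#' @param carrying_capacity Logistic plateau area, pixels.
#' @param plate_height,plate_width Frame size in pixels.
#' @param min_center_distance Minimum distance between colony centres,
#'   pixels; placement failure beyond `max_attempts` raises.
#' @param noise_sd Additive Gaussian noise SD on rendered frames (default 0).
#' @param seed Integer seed.
#' @return A validated list of class `scan_sim_spec`.
#' @export
scan_sim_spec <- function(n_colonies = 30L,
                          frame_interval = 20,
                          total_duration = 2400,
                          lag_mean = 800,
                          lag_sd = 150,
                          growth_rate_range = c(0.004, 0.008),
                          carrying_capacity = 400,
                          plate_height = 600L,
                          plate_width = 600L,
                          min_center_distance = 50,
                          noise_sd = 0,
                          seed = 1L) {
  spec <- list(
    n_colonies = as.integer(n_colonies),
    frame_interval = frame_interval,
    total_duration = total_duration,
    lag_mean = lag_mean,
    lag_sd = lag_sd,
    growth_rate_range = as.numeric(growth_rate_range),
    carrying_capacity = carrying_capacity,
    plate_height = as.integer(plate_height),
    plate_width = as.integer(plate_width),
    min_center_distance = min_center_distance,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (spec$frame_interval <= 0) abort("frame_interval must be > 0")
  if (spec$total_duration %% spec$frame_interval != 0) {
    abort("total_duration must be a multiple of frame_interval")
  }
  if (spec$n_colonies < 0L) abort("n_colonies must be >= 0")
  if (length(spec$growth_rate_range) != 2L ||
      any(spec$growth_rate_range <= 0) ||
      spec$growth_rate_range[1] > spec$growth_rate_range[2]) {
    abort("growth_rate_range must be (min, max) with 0 < min <= max")
  }
  if (spec$carrying_capacity <= 1) abort("carrying_capacity must be > 1")
  structure(spec, class = "scan_sim_spec")
}

#' Specification for the synthetic proteomics generator
#'
#' Emulates replicate label-free intensity tables for two genotypes
#' (`WT`, `dtisB`) and two fractions (supernatant `SN`, pellet fraction
#' `PF`): log-normal baseline intensities, a planted group shift for
#' "enriched" proteins in the WT pellet fraction, total absence of
#' "exclusive" proteins from the mutant pellet fraction, and independent
#' dropouts elsewhere.
#'
#' Defaults describe a small aggregate-focused pellet-fraction table: only
#' aggregation-prone proteins are recovered in washed pellets, so the table
#' is dominated by planted aggregate proteins over a modest background.
#'
#' @param n_proteins Number of proteins.
#' @param n_replicates Replicates per (genotype, fraction) group.
#' @param baseline_log2_mean,baseline_log2_sd Between-protein distribution of
#'   baseline log2 intensity.
#' @param n_enriched Proteins shifted up by `enrichment_log2fc` in the WT
#'   pellet fraction.
#' @param enrichment_log2fc Planted shift, log2 units (> 1 to be recoverable
#'   by the default criteria).
#' @param n_exclusive Proteins fully absent from the mutant pellet fraction.
#' @param replicate_log2_sd Within-group replicate noise SD, log2 units.
#' @param dropout_rate Probability that any other value is missing.
#' @param seed Integer seed.
#' @return A validated list of class `proteome_sim_spec`.
#' @export
proteome_sim_spec <- function(n_proteins = 80L,
                              n_replicates = 3L,
                              baseline_log2_mean = 23,
                              baseline_log2_sd = 2,
                              n_enriched = 30L,
                              enrichment_log2fc = 3,
                              n_exclusive = 20L,
                              replicate_log2_sd = 0.5,
                              dropout_rate = 0,
                              seed = 1L) {
  spec <- list(
    n_proteins = as.integer(n_proteins),
    n_replicates = as.integer(n_replicates),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    n_enriched = as.integer(n_enriched),
    enrichment_log2fc = enrichment_log2fc,
    n_exclusive = as.integer(n_exclusive),
    replicate_log2_sd = replicate_log2_sd,
    dropout_rate = dropout_rate,
    seed = as.integer(seed)
  )
  if (spec$n_proteins < 0L) abort("n_proteins must be >= 0")
  if (spec$n_replicates < 1L) abort("n_replicates must be >= 1")
  if (spec$n_enriched < 0L || spec$n_exclusive < 0L ||
      spec$n_enriched + spec$n_exclusive > spec$n_proteins) {
    abort("n_enriched + n_exclusive must be <= n_proteins")
  }
  if (spec$dropout_rate < 0 || spec$dropout_rate >= 1) {
    abort("dropout_rate must be in [0, 1)")
  }
  if (spec$replicate_log2_sd < 0 || spec$baseline_log2_sd < 0) {
    abort("standard deviations must be >= 0")
  }
  structure(spec, class = "proteome_sim_spec")
}

#' Read a simulation spec from a YAML config file
#'
#' The file is a flat key/value mapping with a `modality` key naming the
#' generator (`microscopy`, `scan` or `proteome`); remaining keys are passed
#' to the matching spec constructor.
#'
#' @param path Path to a YAML file.
#' @return A `microscopy_sim_spec`, `scan_sim_spec` or `proteome_sim_spec`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modality <- cfg$modality %||% abort("config must name a 'modality'")
  cfg$modality <- NULL
  ctor <- switch(modality,
    microscopy = microscopy_sim_spec,
    scan = scan_sim_spec,
    proteome = proteome_sim_spec,
    abort(paste0("unknown modality: ", modality))
  )
  do.call(ctor, cfg)
}
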