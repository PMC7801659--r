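# Validated specification objects for the synthetic-data generators. Each
# generator takes one of these plus nothing else, and a given spec (seed
# included) fully determines its output.

#' Acquisition schedule for a FRAP experiment
#'
#' The default mirrors a typical confocal FRAP protocol for condensates:
#' 5 pre-bleach frames every 2 s, a bleach event, then 12 post-bleach frames
#' every 5 s (first minute, dense sampling of the rising phase) followed by
#' 36 frames every 10 s (the subsequent 6 minutes). Time zero is the first
#' post-bleach frame; pre-bleach frames carry negative timestamps.
#'
#' @param n_prebleach number of pre-bleach frames.
#' @param prebleach_interval_s seconds between pre-bleach frames.
#' @param fast_n,fast_interval_s count and spacing of the early post-bleach
#'   frames.
#' @param slow_n,slow_interval_s count and spacing of the late post-bleach
#'   frames.
#' @return A list with `timestamps_s` (strictly increasing), `n_prebleach`
#'   and `bleach_frame_index` (index of the first post-bleach frame).
#' @export
frap_schedule <- function(n_prebleach = 5, prebleach_interval_s = 2,
                          fast_n = 12, fast_interval_s = 5,
                          slow_n = 36, slow_interval_s = 10) {
  stopifnot(n_prebleach >= 1, fast_n + slow_n >= 1)
  pre <- -(n_prebleach:1) * prebleach_interval_s
  fast <- seq(0, by = fast_interval_s, length.out = fast_n)
  slow_start <- if (fast_n > 0) fast[fast_n] + slow_interval_s else 0
  slow <- seq(slow_start, by = slow_interval_s, length.out = slow_n)
  ts <- c(pre, fast, slow)
  list(timestamps_s = ts, n_prebleach = as.integer(n_prebleach),
       bleach_frame_index = as.integer(n_prebleach + 1L))
}

#' Ground truth for a simulated FRAP experiment
#'
#' @param mobile_fraction asymptotic recoverable fraction `A`, in `[0, 1]`.
#' @param half_time_s recovery time constant `tau` in seconds (the
#'   single-exponential model is `A * (1 - exp(-t / tau))`).
#' @param bleach_depth post-bleach intensity inside the stimulation ROI as a
#'   fraction of its pre-bleach value, in `[0, 1)`. The achieved laser
#'   bleach depth is instrument-specific; 0.1 (90% signal loss) is used as
#'   a representative default.
#' @param punctum_center `(row, col)` pixel coordinates of the punctum.
#' @param punctum_radius_px punctum disc radius in pixels.
#' @param stimulation_roi_area_um2 area of the circular bleach ROI, in um^2.
#'   Protocols for condensate FRAP bleach only the punctum centre; the ROI
#'   must cover at most 2/3 of the punctum area.
#' @param background_level,punctum_level intensities (arbitrary units) of
#'   the background and of the punctum disc.
#' @param drift_per_frame_px `(row, col)` rigid drift applied cumulatively
#'   per frame, in pixels.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param acquisition_bleach_tau_s time constant of optional whole-frame
#'   acquisition photobleaching decay, or `NULL` for none.
#' @param pixel_size_um micrometres per pixel.
#' @param seed integer seed; fully determines the simulated stack.
#' @return A validated `frap_ground_truth` list.
#' @export
frap_ground_truth <- function(mobile_fraction, half_time_s,
                              bleach_depth = 0.1,
                              punctum_center = c(32, 32),
                              punctum_radius_px = 12,
                              stimulation_roi_area_um2 = 5.5,
                              background_level = 20, punctum_level = 200,
                              drift_per_frame_px = c(0, 0), noise_sd = 0,
                              acquisition_bleach_tau_s = NULL,
                              pixel_size_um = 0.2, seed = 1) {
  assert_scalar_number(mobile_fraction, "mobile_fraction", 0, 1)
  assert_scalar_number(half_time_s, "half_time_s", 0, strict_lower = TRUE)
  assert_scalar_number(bleach_depth, "bleach_depth", 0, 1,
                       strict_upper = TRUE)
  assert_scalar_number(punctum_radius_px, "punctum_radius_px", 0,
                       strict_lower = TRUE)
  assert_scalar_number(stimulation_roi_area_um2, "stimulation_roi_area_um2",
                       0, strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  assert_scalar_number(pixel_size_um, "pixel_size_um", 0,
                       strict_lower = TRUE)
  if (!is.null(acquisition_bleach_tau_s))
    assert_scalar_number(acquisition_bleach_tau_s, "acquisition_bleach_tau_s",
                         0, strict_lower = TRUE)
  punctum_area_um2 <- pi * punctum_radius_px^2 * pixel_size_um^2
  if (stimulation_roi_area_um2 > (2 / 3) * punctum_area_um2)
    warning("stimulation ROI covers more than 2/3 of the punctum area; ",
            "this deviates from the bleach-centre-only protocol",
            call. = FALSE)
  structure(
    list(mobile_fraction = mobile_fraction, half_time_s = half_time_s,
         bleach_depth = bleach_depth, punctum_center = punctum_center,
         punctum_radius_px = punctum_radius_px,
         stimulation_roi_area_um2 = stimulation_roi_area_um2,
         background_level = background_level, punctum_level = punctum_level,
         drift_per_frame_px = drift_per_frame_px, noise_sd = noise_sd,
         acquisition_bleach_tau_s = acquisition_bleach_tau_s,
         pixel_size_um = pixel_size_um, seed = as.integer(seed)),
    class = "frap_ground_truth")
}

#' Specification of a univariate normal mixture of punctum areas
#'
#' @param weights component probabilities; must sum to 1.
#' @param means component means (um^2).
#' @param sds component standard deviations (um^2), all positive.
#' @param n number of areas to draw.
#' @param seed integer seed.
#' @param truncate_at_zero if `TRUE`, negative draws are rejected and
#'   redrawn. Statistical-recovery fixtures use untruncated normals (the
#'   model actually fitted to area data), so maximum-likelihood recovery
#'   stays unbiased; truncation exists only for image-geometry use where a
#'   negative area is meaningless.
#' @return A validated `mixture_spec` list.
#' @export
mixture_spec <- function(weights, means, sds, n, seed = 1,
                         truncate_at_zero = FALSE) {
  if (length(weights) != length(means) || length(means) != length(sds))
    stop("`weights`, `means` and `sds` must have equal length", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("`weights` must be non-negative and sum to 1", call. = FALSE)
  if (any(sds <= 0)) stop("all `sds` must be positive", call. = FALSE)
  assert_scalar_number(n, "n", lower = 0)
  assert_flag(truncate_at_zero, "truncate_at_zero")
  structure(
    list(weights = as.numeric(weights), means = as.numeric(means),
         sds = as.numeric(sds), n = as.integer(n), seed = as.integer(seed),
         truncate_at_zero = truncate_at_zero),
    class = "mixture_spec")
}

#' Specification of a sigmoidal ThT aggregation trace
#'
#' @param baseline,plateau pre- and post-transition fluorescence (arbitrary
#'   units); must differ.
#' @param t_half_h time of half transition, in hours; must lie inside the
#'   sampled time range.
#' @param steepness_per_h logistic steepness (1/hours).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param timepoints_h sampling times in hours (at least 3, increasing).
#' @param seed integer seed.
#' @return A validated `tht_spec` list.
#' @export
tht_spec <- function(baseline = 0, plateau = 100, t_half_h = 12,
                     steepness_per_h = 0.8, noise_sd = 0,
                     timepoints_h = seq(0, 48, by = 0.25), seed = 1) {
  if (plateau == baseline)
    stop("`plateau` must differ from `baseline`", call. = FALSE)
  if (length(timepoints_h) < 3L)
    stop("at least 3 timepoints are required", call. = FALSE)
  if (any(diff(timepoints_h) <= 0))
    stop("`timepoints_h` must be strictly increasing", call. = FALSE)
  if (t_half_h < min(timepoints_h) || t_half_h > max(timepoints_h))
    stop("`t_half_h` must lie within the sampled time range", call. = FALSE)
  assert_scalar_number(steepness_per_h, "steepness_per_h", 0,
                       strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  structure(
    list(baseline = baseline, plateau = plateau, t_half_h = t_half_h,
         steepness_per_h = steepness_per_h, noise_sd = noise_sd,
         timepoints_h = as.numeric(timepoints_h), seed = as.integer(seed)),
    class = "tht_spec")
}

#' Ground truth for a simulated solubility fractionation
#'
#' @param sample_id identifier shared by the soluble and insoluble rows.
#' @param percent_insoluble true percentage of the protein in the pellet
#'   (insoluble) fraction, in `[0, 100]`.
#' @param total_abundance total protein amount (arbitrary units).
#' @param loading_noise_sd standard deviation of the multiplicative
#'   lane-loading factor (mean 1) shared by a lane's band and its loading
#'   normalizer.
#' @param band_noise_sd standard deviation of additive band-density noise.
#' @param volume_factor_s,volume_factor_p lysate-volume correction factors
#'   for the soluble and pellet lanes.
#' @param protein,condition optional group labels carried into the rows.
#' @param seed integer seed.
#' @return A validated `solubility_truth` list.
#' @export
solubility_truth <- function(sample_id, percent_insoluble,
                             total_abundance = 100,
                             loading_noise_sd = 0, band_noise_sd = 0,
                             volume_factor_s = 1, volume_factor_p = 1,
                             protein = NA_character_,
                             condition = NA_character_, seed = 1) {
  assert_scalar_number(percent_insoluble, "percent_insoluble", 0, 100)
  assert_scalar_number(total_abundance, "total_abundance", 0,
                       strict_lower = TRUE)
  assert_scalar_number(loading_noise_sd, "loading_noise_sd", 0)
  assert_scalar_number(band_noise_sd, "band_noise_sd", 0)
  assert_scalar_number(volume_factor_s, "volume_factor_s", 0,
                       strict_lower = TRUE)
  assert_scalar_number(volume_factor_p, "volume_factor_p", 0,
                       strict_lower = TRUE)
  structure(
    list(sample_id = sample_id, percent_insoluble = percent_insoluble,
         total_abundance = total_abundance,
         loading_noise_sd = loading_noise_sd, band_noise_sd = band_noise_sd,
         volume_factor_s = volume_factor_s, volume_factor_p = volume_factor_p,
         protein = protein, condition = condition, seed = as.integer(seed)),
    class = "solubility_truth")
}
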