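# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth, so each analysis stage can be
# validated in closed loop. All randomness is local to the spec's seed.

#' Sample punctum areas from a normal mixture
#'
#' Draws `spec$n` areas from the K-component univariate normal mixture
#' described by `spec`, recording for each draw the component that generated
#' it. Used to emulate the two-population (small P1 / large P2) punctum-area
#' distributions observed for condensate-forming proteins.
#'
#' @param spec a [mixture_spec()].
#' @return A data frame with columns `area` (um^2) and `component`
#'   (1-based index into `spec$means`).
#' @export
sample_puncta_areas <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (spec$n == 0L)
    return(data.frame(area = numeric(0), component = integer(0)))
  with_local_seed(spec$seed, {
    comp <- sample.int(length(spec$weights), spec$n, replace = TRUE,
                       prob = spec$weights)
    area <- rnorm(spec$n, mean = spec$means[comp], sd = spec$sds[comp])
    if (spec$truncate_at_zero) {
      bad <- which(area < 0)
      guard <- 0L
      while (length(bad) > 0L && guard < 1000L) {
        area[bad] <- rnorm(length(bad), mean = spec$means[comp[bad]],
                           sd = spec$sds[comp[bad]])
        bad <- bad[area[bad] < 0]
        guard <- guard + 1L
      }
      if (length(bad) > 0L)
        stop("could not draw non-negative areas; check the mixture spec",
             call. = FALSE)
    }
    data.frame(area = area, component = comp)
  })
}

#' Simulate a FRAP image stack with known recovery parameters
#'
#' Renders a disc-shaped punctum of `punctum_level` on `background_level`,
#' bleaches the circular stimulation ROI at the scheduled bleach event
#' (multiplying its pixels by `bleach_depth`), and lets each bleached pixel
#' recover along the single-exponential model
#' `I(t) = I_bleached + A * (I_pre - I_bleached) * (1 - exp(-t / tau))`,
#' with `t` measured from the first post-bleach frame. Optional whole-frame
#' acquisition photobleaching, rigid per-frame drift (the bleached region
#' travels with the punctum) and additive Gaussian noise can be layered on
#' top. With zero noise, zero drift and no acquisition bleaching, intensity
#' outside the stimulation ROI is constant across frames.
#'
#' @param truth a [frap_ground_truth()].
#' @param schedule an acquisition schedule from [frap_schedule()]; must have
#'   at least 5 pre-bleach frames and at least one post-bleach frame.
#' @param dims image dimensions `(rows, cols)` in pixels.
#' @return A list with elements `stack` (an [image_stack()] carrying the
#'   bleach frame index and stimulation ROI) and `truth` (the input, echoed
#'   alongside so downstream recovery can be scored).
#' @export
simulate_frap_stack <- function(truth, schedule = frap_schedule(),
                                dims = c(64, 64)) {
  stopifnot(inherits(truth, "frap_ground_truth"))
  if (schedule$n_prebleach < 5L)
    stop("the bleach protocol requires at least 5 pre-bleach frames",
         call. = FALSE)
  ts <- schedule$timestamps_s
  nt <- length(ts)
  if (nt <= schedule$n_prebleach)
    stop("schedule has no post-bleach frames", call. = FALSE)
  stim_radius_px <- sqrt(truth$stimulation_roi_area_um2 / pi) /
    truth$pixel_size_um
  if (stim_radius_px <= 0 || truth$punctum_radius_px <= 0)
    stop("radii must be positive", call. = FALSE)
  ctr0 <- truth$punctum_center
  if (ctr0[1] - stim_radius_px < 1 || ctr0[1] + stim_radius_px > dims[1] ||
      ctr0[2] - stim_radius_px < 1 || ctr0[2] + stim_radius_px > dims[2])
    stop("stimulation ROI falls outside the image", call. = FALSE)

  bleach_idx <- schedule$bleach_frame_index
  A <- truth$mobile_fraction
  tau <- truth$half_time_s
  depth <- truth$bleach_depth
  frames <- with_local_seed(truth$seed, {
    lapply(seq_len(nt), function(i) {
      ctr <- ctr0 + (i - 1) * truth$drift_per_frame_px
      punctum <- disc_mask(dims, ctr, truth$punctum_radius_px)
      img <- matrix(truth$background_level, dims[1], dims[2])
      img[punctum] <- truth$punctum_level
      if (i >= bleach_idx) {
        # bleached molecules travel with the punctum
        stim <- disc_mask(dims, ctr, stim_radius_px)
        t_rec <- ts[i] - ts[bleach_idx]
        i_pre <- img[stim]
        i_bleached <- i_pre * depth
        img[stim] <- i_bleached +
          A * (i_pre - i_bleached) * (1 - exp(-t_rec / tau))
      }
      if (!is.null(truth$acquisition_bleach_tau_s))
        img <- img * exp(-(ts[i] - ts[1]) / truth$acquisition_bleach_tau_s)
      if (truth$noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, truth$noise_sd),
                            dims[1], dims[2])
      img
    })
  })
  stim0 <- disc_mask(dims, ctr0 + (bleach_idx - 1) * truth$drift_per_frame_px,
                     stim_radius_px)
  stack <- image_stack(frames, timestamps = ts,
                       pixel_size_um = truth$pixel_size_um,
                       bleach_frame_index = bleach_idx,
                       stimulation_roi = stim0)
  list(stack = stack, truth = truth)
}

#' Simulate a raw FRAP trace directly from the recovery model
#'
#' Convenience generator for fitting studies that bypasses image rendering:
#' pre-bleach ratios sit at 1, and post-bleach ratios follow
#' `d + (1 - d) * A * (1 - exp(-t / tau))` where `d` is the bleach depth,
#' so that two-anchor normalization recovers `A * (1 - exp(-t / tau))`
#' exactly in the noiseless case. Additive Gaussian noise of `noise_sd` is
#' applied to every point.
#'
#' @param mobile_fraction,half_time_s recovery parameters `A` and `tau`.
#' @param schedule acquisition schedule from [frap_schedule()].
#' @param bleach_depth first post-bleach ratio, in `[0, 1)`.
#' @param noise_sd additive Gaussian noise on the ratio scale.
#' @param seed integer seed.
#' @return A [frap_trace()].
#' @export
simulate_frap_trace <- function(mobile_fraction, half_time_s,
                                schedule = frap_schedule(),
                                bleach_depth = 0.1, noise_sd = 0, seed = 1) {
  assert_scalar_number(mobile_fraction, "mobile_fraction", 0, 1)
  assert_scalar_number(half_time_s, "half_time_s", 0, strict_lower = TRUE)
  ts <- schedule$timestamps_s
  npre <- schedule$n_prebleach
  post_t <- ts[(npre + 1L):length(ts)] - ts[npre + 1L]
  value <- c(rep(1, npre),
             bleach_depth + (1 - bleach_depth) * mobile_fraction *
               (1 - exp(-post_t / half_time_s)))
  if (noise_sd > 0)
    value <- value + with_local_seed(seed, rnorm(length(value), 0, noise_sd))
  frap_trace(timestamps_s = ts, value = value, n_prebleach = npre)
}

#' Simulate a fixed-cell image with known puncta and punctate fraction
#'
#' Renders a disc-shaped cell filled with diffuse signal, places
#' non-overlapping disc puncta inside it, and returns the image together
#' with the exact per-punctum geometry and the true punctate-fluorescence
#' percentage, defined exactly as the downstream statistic computes it:
#' background-corrected punctum signal summed over puncta, divided by the
#' background-corrected whole-cell signal (background estimated outside the
#' cell). Puncta that touch the cell boundary or image border are flagged.
#'
#' @param n_puncta number of puncta to place.
#' @param punctum_radii_px punctum radii in pixels (recycled to `n_puncta`).
#' @param diffuse_fraction design fraction of cell signal that is diffuse
#'   (non-punctate), in `(0, 1]`; with `1` no punctum signal is rendered.
#' @param dims image dimensions `(rows, cols)`.
#' @param cell_center,cell_radius_px cell disc geometry.
#' @param background_level,diffuse_level intensity outside the cell, and the
#'   diffuse intensity added inside it.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param pixel_size_um micrometres per pixel.
#' @param seed integer seed.
#' @return A list with `image`, `pixel_size_um`, `cell_mask`,
#'   `background_mask` (outside-cell pixels), `puncta` (data frame:
#'   `punctum_id`, `centroid_row`, `centroid_col`, `radius_px`, `area_px`,
#'   `area_um2`, `border_warning`), and `true_percent_punctate`.
#' @export
simulate_fixed_cell_image <- function(n_puncta, punctum_radii_px = 4,
                                      diffuse_fraction = 0.6,
                                      dims = c(128, 128),
                                      cell_center = c(64, 64),
                                      cell_radius_px = 50,
                                      background_level = 5,
                                      diffuse_level = 50,
                                      noise_sd = 0, pixel_size_um = 0.2,
                                      seed = 1) {
  assert_scalar_number(n_puncta, "n_puncta", lower = 0)
  assert_scalar_number(diffuse_fraction, "diffuse_fraction", 0, 1,
                       strict_lower = TRUE)
  n_puncta <- as.integer(n_puncta)
  radii <- rep_len(punctum_radii_px, max(n_puncta, 1L))
  if (n_puncta > 0 && any(radii >= cell_radius_px))
    stop("puncta must fit inside the cell mask", call. = FALSE)

  cell_mask <- disc_mask(dims, cell_center, cell_radius_px)
  background_mask <- !cell_mask
  a_cell <- sum(cell_mask)

  # Place non-overlapping puncta fully inside the cell by rejection.
  placement <- with_local_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n_puncta && tries < 20000L) {
      tries <- tries + 1L
      i <- nrow(centers) + 1L
      ang <- runif(1, 0, 2 * pi)
      rad <- sqrt(runif(1)) * (cell_radius_px - radii[i] - 1)
      cand <- cell_center + rad * c(cos(ang), sin(ang))
      ok <- TRUE
      if (nrow(centers) > 0) {
        dmin <- sqrt((centers[, 1] - cand[1])^2 +
                     (centers[, 2] - cand[2])^2)
        ok <- all(dmin > radii[seq_len(nrow(centers))] + radii[i] + 2)
      }
      if (ok) centers <- rbind(centers, cand)
    }
    centers
  })
  if (n_puncta > 0 && nrow(placement) < n_puncta)
    stop("could not place the requested puncta without overlap", call. = FALSE)

  img <- matrix(background_level, dims[1], dims[2])
  img[cell_mask] <- background_level + diffuse_level

  puncta <- data.frame(punctum_id = integer(0), centroid_row = numeric(0),
                       centroid_col = numeric(0), radius_px = numeric(0),
                       area_px = integer(0), area_um2 = numeric(0),
                       border_warning = logical(0))
  punctate_signal <- 0
  if (n_puncta > 0 && diffuse_fraction < 1) {
    masks <- lapply(seq_len(n_puncta), function(i)
      disc_mask(dims, placement[i, ], radii[i]))
    a_puncta <- vapply(masks, sum, integer(1))
    # Choose the punctum surplus level so that the design fraction of the
    # background-corrected cell signal is punctate:
    #   sum(A_p) * (diffuse + extra) = (1 - f) * (A_cell * diffuse
    #                                   + sum(A_p) * extra)
    f <- diffuse_fraction
    extra <- diffuse_level * ((1 - f) * a_cell - sum(a_puncta)) /
      (f * sum(a_puncta))
    if (extra <= 0)
      stop("diffuse_fraction too low for this puncta geometry; ",
           "puncta cannot hold that much of the cell signal", call. = FALSE)
    for (i in seq_len(n_puncta)) img[masks[[i]]] <- img[masks[[i]]] + extra
    border <- vapply(seq_len(n_puncta), function(i) {
      any(masks[[i]] & !cell_mask) ||
        any(masks[[i]][c(1, dims[1]), ]) || any(masks[[i]][, c(1, dims[2])])
    }, logical(1))
    if (any(border))
      warning(sum(border), " punctum/puncta overlap the cell or image ",
              "border; affected records are flagged", call. = FALSE)
    punctate_signal <- sum(a_puncta * (diffuse_level + extra))
    puncta <- data.frame(
      punctum_id = seq_len(n_puncta),
      centroid_row = placement[, 1], centroid_col = placement[, 2],
      radius_px = radii[seq_len(n_puncta)], area_px = a_puncta,
      area_um2 = a_puncta * pixel_size_um^2, border_warning = border)
  }
  cell_signal <- sum(img[cell_mask]) - a_cell * background_level
  true_percent <- if (nrow(puncta) == 0) 0 else
    100 * punctate_signal / cell_signal

  if (noise_sd > 0)
    img <- img + with_local_seed(seed + 1L,
      matrix(rnorm(length(img), 0, noise_sd), dims[1], dims[2]))

  list(image = img, pixel_size_um = pixel_size_um, cell_mask = cell_mask,
       background_mask = background_mask, puncta = puncta,
       true_percent_punctate = true_percent)
}

#' Simulate a ThT aggregation kinetic trace
#'
#' Generates a logistic (sigmoidal) fluorescence-versus-time curve
#' `baseline + (plateau - baseline) / (1 + exp(-k * (t - t_half)))` with
#' additive Gaussian noise, emulating a plate-reader thioflavin-T assay of
#' amyloid fibril formation.
#'
#' @param spec a [tht_spec()].
#' @param replicate_id identifier stored on the trace.
#' @return A [kinetic_trace()].
#' @export
simulate_tht_curve <- function(spec, replicate_id = "r1") {
  stopifnot(inherits(spec, "tht_spec"))
  t <- spec$timepoints_h
  y <- spec$baseline + (spec$plateau - spec$baseline) /
    (1 + exp(-spec$steepness_per_h * (t - spec$t_half_h)))
  if (spec$noise_sd > 0)
    y <- y + with_local_seed(spec$seed, rnorm(length(y), 0, spec$noise_sd))
  kinetic_trace(timestamps_h = t, fluorescence = y,
                replicate_id = replicate_id)
}

#' Simulate soluble/pellet densitometry rows
#'
#' Splits `total_abundance` into soluble and insoluble masses according to
#' the true `percent_insoluble`, then renders each as a gel-band density:
#' a lane-loading factor (mean 1, sd `loading_noise_sd`) multiplies the
#' band and is reported as that lane's loading normalizer, the lysate
#' volume factor divides the band, and additive band noise
#' (`band_noise_sd`) is applied last. The corrected ratio
#' `100 * P / (S + P)` computed by [percent_insoluble()] therefore
#' recovers the true percentage in expectation.
#'
#' @param truth a [solubility_truth()].
#' @return A two-row data frame (fractions `"S"` then `"P"`) with columns
#'   `sample_id`, `protein`, `condition`, `fraction`, `band_density`,
#'   `loading_normalizer`, `volume_factor`.
#' @export
simulate_densitometry <- function(truth) {
  stopifnot(inherits(truth, "solubility_truth"))
  mass_p <- truth$total_abundance * truth$percent_insoluble / 100
  mass_s <- truth$total_abundance - mass_p
  with_local_seed(truth$seed, {
    loading <- pmax(1 + rnorm(2, 0, truth$loading_noise_sd), 0.05)
    band <- c(mass_s / truth$volume_factor_s * loading[1],
              mass_p / truth$volume_factor_p * loading[2])
    if (truth$band_noise_sd > 0)
      band <- band + rnorm(2, 0, truth$band_noise_sd)
    band <- pmax(band, 0)
    data.frame(
      sample_id = rep(truth$sample_id, 2),
      protein = rep(truth$protein, 2), condition = rep(truth$condition, 2),
      fraction = c("S", "P"), band_density = band,
      loading_normalizer = loading,
      volume_factor = c(truth$volume_factor_s, truth$volume_factor_p))
  })
}
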