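# Generators: validation, determinism, and agreement of their output with
# the ground truth they advertise.

test_that("mixture area sampling honours the spec and is reproducible", {
  # degenerate variance pins all draws to the mean
  sp <- mixture_spec(1, 5, 1e-12, n = 3, seed = 1)
  expect_equal(sample_puncta_areas(sp)$area, rep(5, 3), tolerance = 1e-9)

  expect_identical(nrow(sample_puncta_areas(
    mixture_spec(1, 5, 1, n = 0))), 0L)

  # identical spec + seed => bit-identical output
  sp2 <- mixture_spec(c(0.4, 0.6), c(1, 10), c(0.5, 3), 200, seed = 42)
  expect_identical(sample_puncta_areas(sp2), sample_puncta_areas(sp2))

  # invalid specs are rejected
  expect_error(mixture_spec(c(0.5, 0.6), c(1, 2), c(1, 1), 10), "sum to 1")
  expect_error(mixture_spec(1, 1, 0, 10), "positive")
  expect_error(mixture_spec(1, 1, 1, -5))
})

test_that("component-labeled draws match the two-population parameters", {
  # small-puncta population P1: mean 0.8, sd 0.6 um^2 at weight 0.40
  sp <- mixture_spec(c(0.4, 0.6), c(0.8, 11.2), c(0.6, 10.1), 2000,
                     seed = 1)
  draws <- sample_puncta_areas(sp)
  p1 <- draws$area[draws$component == 1]
  expect_lt(abs(mean(p1) - 0.8), 3 * 0.6 / sqrt(length(p1)))
  p2 <- draws$area[draws$component == 2]
  expect_lt(abs(mean(p2) - 11.2), 3 * 10.1 / sqrt(length(p2)))
  expect_lt(abs(length(p1) / 2000 - 0.4), 3 * sqrt(0.4 * 0.6 / 2000))

  # truncation variant never yields negative areas
  spt <- mixture_spec(c(0.4, 0.6), c(0.8, 11.2), c(0.6, 10.1), 500,
                      seed = 2, truncate_at_zero = TRUE)
  expect_true(all(sample_puncta_areas(spt)$area >= 0))
})

test_that("FRAP stack simulation reproduces its own recovery model", {
  sched <- frap_schedule()
  roi_mean <- function(sim) {
    stim <- sim$stack$stimulation_roi
    vapply(seq_along(sim$stack$timestamps),
           function(i) mean(sim$stack$pixels[, , i][stim]), numeric(1))
  }

  # immobile punctum: no recovery at all
  sim0 <- simulate_frap_stack(frap_ground_truth(0, 60, noise_sd = 0))
  m0 <- roi_mean(sim0)
  post <- seq(sched$bleach_frame_index, length(m0))
  expect_equal(diff(range(m0[post])), 0, tolerance = 1e-9)

  # fully mobile punctum approaches its pre-bleach level
  sim1 <- simulate_frap_stack(frap_ground_truth(1, 30, noise_sd = 0))
  m1 <- roi_mean(sim1)
  expect_equal(tail(m1, 1), m1[1], tolerance = 1e-4 * m1[1])

  # conservation: intensity outside the stimulation ROI never changes
  simc <- simulate_frap_stack(frap_ground_truth(0.5, 60, noise_sd = 0))
  outside <- !simc$stack$stimulation_roi
  tot <- vapply(seq_along(simc$stack$timestamps),
                function(i) sum(simc$stack$pixels[, , i][outside]),
                numeric(1))
  expect_equal(diff(range(tot)), 0, tolerance = 1e-9)

  # determinism with noise
  tr <- frap_ground_truth(0.6, 45, noise_sd = 2, seed = 11)
  expect_identical(simulate_frap_stack(tr)$stack$pixels,
                   simulate_frap_stack(tr)$stack$pixels)

  # stimulation ROI outside the frame is rejected
  expect_error(
    simulate_frap_stack(frap_ground_truth(0.5, 60,
                                          punctum_center = c(2, 2))),
    "outside")
})

test_that("closed loop: simulated stack -> analysis recovers the truth", {
  sim <- simulate_frap_stack(frap_ground_truth(0.7, 60, noise_sd = 0))
  stk <- sim$stack
  pre_mask <- stk$pixels[, , 1] >
    (sim$truth$background_level + sim$truth$punctum_level) / 2
  post_mask <- stk$pixels[, , stk$bleach_frame_index] >
    (sim$truth$background_level + sim$truth$punctum_level) / 2
  froi <- build_frap_roi(pre_mask, post_mask)
  fit <- fit_recovery(normalize_trace(extract_trace(stk, froi, pre_mask)))
  expect_equal(fit$mobile_fraction, 0.7, tolerance = 1e-3)
  expect_equal(fit$half_time_s, 60, tolerance = 1e-3 * 60)
})

test_that("fixed-cell simulator reports exact geometry and fraction", {
  # no punctate signal: zero percent punctate, and segmentation of the
  # cell interior finds nothing
  sim0 <- simulate_fixed_cell_image(n_puncta = 0, seed = 3)
  expect_equal(sim0$true_percent_punctate, 0)
  flat <- sim0$image
  flat[sim0$background_mask] <- flat[sim0$cell_mask][1]
  expect_identical(nrow(segment_puncta(flat)$records), 0L)

  sim1 <- suppressWarnings(
    simulate_fixed_cell_image(n_puncta = 1, punctum_radii_px = 5,
                              diffuse_fraction = 0.6, seed = 4))
  expect_equal(sim1$puncta$area_px,
               sum(condensr:::disc_mask(c(128, 128), c(64, 64), 5)),
               tolerance = 0.15 * pi * 25)
  expect_equal(sim1$true_percent_punctate, 40, tolerance = 1e-9)

  expect_identical(
    nrow(simulate_fixed_cell_image(1, diffuse_fraction = 1)$puncta), 0L)
})

test_that("ThT curve generation is seeded and validated", {
  sp <- tht_spec(t_half_h = 5, noise_sd = 0)
  tr <- simulate_tht_curve(sp)
  expect_s3_class(tr, "kinetic_trace")
  # midpoint of the noiseless logistic sits at t_half
  mid <- (sp$baseline + sp$plateau) / 2
  i <- which(tr$points$fluorescence >= mid)[1]
  expect_equal(tr$points$time_h[i], 5, tolerance = 0.25)

  # steepness -> infinity approaches a step at t_half
  stp <- simulate_tht_curve(tht_spec(t_half_h = 5, steepness_per_h = 500))
  y <- stp$points$fluorescence
  t <- stp$points$time_h
  expect_true(all(y[t < 4.5] < 1e-6) && all(y[t > 5.5] > 100 - 1e-6))

  expect_error(tht_spec(baseline = 1, plateau = 1), "differ")
  expect_error(tht_spec(t_half_h = 100), "range")
  s2 <- tht_spec(t_half_h = 5, noise_sd = 3, seed = 9)
  expect_identical(simulate_tht_curve(s2)$points,
                   simulate_tht_curve(s2)$points)
})

test_that("densitometry generator encodes the insolubility ground truth", {
  d0 <- simulate_densitometry(solubility_truth("a", 0))
  expect_equal(d0$band_density[d0$fraction == "P"], 0)

  d50 <- simulate_densitometry(solubility_truth("b", 50))
  corr <- d50$band_density / d50$loading_normalizer * d50$volume_factor
  expect_equal(corr[1], corr[2])

  expect_error(solubility_truth("c", 120))

  # Monte-Carlo: noisy draws recover the truth in expectation
  est <- vapply(1:100, function(s) {
    d <- simulate_densitometry(
      solubility_truth("d", 30, loading_noise_sd = 0.1, band_noise_sd = 2,
                       seed = s))
    percent_insoluble(d[d$fraction == "S", ], d[d$fraction == "P", ])
  }, numeric(1))
  expect_lt(abs(mean(est) - 30), 3 * sd(est) / sqrt(length(est)))
})

test_that("TIFF round trip preserves the stack and its sidecar metadata", {
  sim <- simulate_frap_stack(frap_ground_truth(0.5, 60, noise_sd = 1,
                                               seed = 5))
  tf <- tempfile(fileext = ".tif")
  write_image_stack(sim$stack, tf)
  back <- read_image_stack(tf)
  expect_equal(back$timestamps, sim$stack$timestamps)
  expect_identical(back$bleach_frame_index, sim$stack$bleach_frame_index)
  expect_identical(back$stimulation_roi, sim$stack$stimulation_roi)
  # 16-bit quantization: relative error bounded by 1/65535 of the range
  expect_lt(max(abs(back$pixels - sim$stack$pixels)),
            2 * max(sim$stack$pixels) / 65535)
  unlink(c(tf, sub("\\.tif$", ".json", tf)))
})
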