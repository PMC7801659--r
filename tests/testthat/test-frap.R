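# FRAP quantification: candidate filters, ROI arithmetic, trace
# extraction, two-anchor normalization and recovery fitting.

make_candidates <- function() {
  # isolated large, isolated small, and a close pair
  data.frame(
    area_um2 = c(10, 6, 9, 8.5),
    centroid_row = c(10, 40, 70, 72),
    centroid_col = c(10, 40, 70, 72),
    stringsAsFactors = FALSE)
}

test_that("bleach-candidate selection applies the documented filters", {
  rec <- make_candidates()
  out <- select_bleach_candidates(rec, stimulation_roi_area_um2 = 5.5,
                                  pixel_size_um = 1,
                                  exclusion_radius_um = 10)
  # punctum 1: fraction 0.55 <= 0.80 and isolated -> kept
  expect_true(out$selected[1])
  # punctum 2: fraction 5.5/6 = 0.92 -> rejected for bleach fraction
  expect_false(out$selected[2])
  expect_identical(out$rejection_reason[2], "bleach_fraction")
  # puncta 3 and 4 are ~2.8 um apart -> both rejected as neighbours
  expect_identical(out$rejection_reason[3], "neighbor")
  expect_identical(out$rejection_reason[4], "neighbor")

  empty <- select_bleach_candidates(rec[0, ], 5.5)
  expect_identical(nrow(empty), 0L)

  banded <- select_bleach_candidates(rec, 2, pixel_size_um = 1,
                                     exclusion_radius_um = 1,
                                     size_band_um2 = c(7, 9.5))
  expect_identical(banded$rejection_reason[1], "size_band")  # area 10
  expect_true(banded$selected[3])
})

test_that("FRAP ROI construction is the pre/post mask set difference", {
  pre <- matrix(FALSE, 9, 9); pre[3:7, 3:7] <- TRUE
  post <- pre; post[4:6, 4:6] <- FALSE
  froi <- build_frap_roi(pre, post)
  expect_identical(sum(froi), 9L)
  expect_true(all(which(froi, arr.ind = TRUE)[, 1] %in% 4:6))

  expect_error(build_frap_roi(pre, pre), "no bleached signal")
  disjoint <- matrix(FALSE, 9, 9); disjoint[1, 1] <- TRUE
  expect_warning(out <- build_frap_roi(pre, disjoint), "disjoint")
  expect_identical(out, pre)
})

test_that("trace extraction divides integrated densities", {
  # two-frame toy stack with hand-computable sums
  f1 <- matrix(1, 10, 10)          # pre-bleach ROI sum = 100 over all
  f2 <- matrix(1, 10, 10); f2[1:3, 1:3] <- 0  # bleach a corner
  pre_roi <- matrix(TRUE, 10, 10)
  froi <- matrix(FALSE, 10, 10); froi[1:3, 1:3] <- TRUE
  stk <- image_stack(list(f1, f1, f2), timestamps = c(0, 2, 4),
                     pixel_size_um = 1, bleach_frame_index = 3)
  # denominator = mean pre-bleach integrated density of pre-bleach ROI
  tr <- extract_trace(stk, froi, pre_roi)
  expect_equal(tr$points$value, c(9 / 100, 9 / 100, 0))

  # uniform stack with FRAP ROI = pre-bleach ROI gives all ones
  stku <- image_stack(list(f1, f1, f1), c(0, 2, 4), 1,
                      bleach_frame_index = 2)
  expect_equal(extract_trace(stku, pre_roi, pre_roi)$points$value,
               rep(1, 3))

  # noiseless simulation: raw post-bleach series follows the generating
  # model curve exactly
  truth <- frap_ground_truth(0.6, 40, noise_sd = 0)
  sim <- simulate_frap_stack(truth)
  stk2 <- sim$stack
  lvl <- (truth$background_level + truth$punctum_level) / 2
  pre_mask <- stk2$pixels[, , 1] > lvl
  post_mask <- stk2$pixels[, , stk2$bleach_frame_index] > lvl
  froi2 <- build_frap_roi(pre_mask, post_mask)
  tr2 <- extract_trace(stk2, froi2, pre_mask)
  post <- tr2$points[tr2$points$phase == "post", ]
  t <- post$time_s
  model <- truth$bleach_depth +
    (1 - truth$bleach_depth) * 0.6 * (1 - exp(-t / 40))
  ratio0 <- post$value[1] / truth$bleach_depth  # ROI-to-ROI area factor
  expect_equal(post$value / ratio0, model, tolerance = 1e-6)

  zero <- image_stack(list(matrix(0, 10, 10), f1), c(0, 1), 1,
                      bleach_frame_index = 2)
  expect_error(extract_trace(zero, froi, pre_roi), "zero integrated")
})

test_that("two-anchor normalization holds exactly and is idempotent", {
  tr <- frap_trace(timestamps_s = c(-10, -8, -6, -4, -2, 0, 5),
                   value = c(100, 102, 98, 101, 99, 40, 70),
                   n_prebleach = 5)
  nt <- normalize_trace(tr)
  expect_equal(nt$points$normalized[7], 0.5)  # (70-40)/(100-40)
  expect_equal(mean(nt$points$normalized[1:5]), 1)
  expect_identical(nt$points$normalized[6], 0)

  # idempotence: a second application changes nothing
  expect_equal(normalize_trace(nt)$points$normalized,
               nt$points$normalized)

  flat <- frap_trace(c(-2, 0, 5), c(1, 1, 1), n_prebleach = 1)
  expect_error(normalize_trace(flat), "no bleach contrast")
})

test_that("normalization contract holds for arbitrary noisy traces", {
  for (seed in 1:10) {
    tr <- simulate_frap_trace(runif(1, 0, 1), runif(1, 10, 200),
                              noise_sd = 0.05, seed = seed)
    nt <- normalize_trace(tr)
    pre <- nt$points$normalized[nt$points$phase == "pre"]
    first_post <- nt$points$normalized[nt$n_prebleach + 1L]
    expect_equal(mean(pre), 1, tolerance = 1e-12)
    expect_identical(first_post, 0)
  }
})

test_that("recovery fitting is exact on model data and flags flat traces", {
  fit <- fit_recovery(normalize_trace(simulate_frap_trace(0.7, 60)))
  expect_equal(fit$mobile_fraction, 0.7, tolerance = 1e-3)
  expect_equal(fit$half_time_s, 60, tolerance = 60 * 1e-3)
  expect_equal(fit$t_half_ln2_s, fit$half_time_s * log(2))
  expect_lt(fit$rss, 1e-10)
  expect_true(fit$converged)
  expect_false(fit$identifiability_flag)

  # immobile punctum: A ~ 0, tau unidentifiable
  flat <- fit_recovery(normalize_trace(
    simulate_frap_trace(0, 60, noise_sd = 0.005, seed = 2)))
  expect_lt(flat$mobile_fraction, 0.02)
  expect_true(flat$identifiability_flag)

  expect_error(
    fit_recovery(frap_trace(c(-2, 0, 5, 10), c(1, 0.1, 0.2, 0.3), 1)),
    "4 post-bleach")
})

test_that("fitted tau increases strictly with the true tau", {
  taus <- c(20, 40, 80, 160)
  fitted <- vapply(taus, function(tau)
    fit_recovery(normalize_trace(
      simulate_frap_trace(0.6, tau)))$half_time_s, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("group summaries aggregate converged fits", {
  mk <- function(a, tau) structure(
    list(mobile_fraction = a, half_time_s = tau,
         t_half_ln2_s = tau * log(2), rss = 0, converged = TRUE,
         identifiability_flag = FALSE, n_points = 48), class = "frap_fit")
  bad <- mk(0.5, 50); bad$converged <- FALSE

  sm <- summarize_frap(list(mk(0.5, 40), mk(0.7, 60), bad, mk(0.9, 100)),
                       c("a", "a", "a", "b"))
  a_row <- sm[sm$group == "a", ]
  expect_equal(a_row$mean_mobile_fraction, 0.6)
  expect_equal(a_row$sem_mobile_fraction, 0.1)
  expect_identical(a_row$n, 2L)
  expect_identical(a_row$n_excluded, 1L)
  # single-fit group: SEM undefined
  expect_true(is.na(sm[sm$group == "b", "sem_mobile_fraction"]))

  expect_warning(summarize_frap(list(bad), "c"), "no converged")
})
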