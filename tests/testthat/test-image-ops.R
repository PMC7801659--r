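# Registration, segmentation, morphometry and fluorescence statistics.

test_that("translation registration recovers known shifts", {
  set.seed(7)
  base <- make_disc_image(c(64, 64), list(c(25, 30)), 8, fg = 5, bg = 0) +
    matrix(runif(64 * 64, 0, 0.5), 64, 64)

  shifted <- condensr:::translate_image(base, c(3, -2), fill = 0)
  st <- image_stack(list(base, shifted), c(0, 1), 1)
  reg <- register_stack(st)
  expect_equal(unname(reg$shifts[2, ]), c(-3, 2), tolerance = 0.05)
  inner <- 10:54
  expect_lt(max(abs(reg$stack$pixels[inner, inner, 2] -
                    base[inner, inner])), 0.05)

  # identical frames give zero shifts
  st0 <- image_stack(list(base, base, base), 0:2, 1)
  expect_equal(max(abs(register_stack(st0)$shifts)), 0, tolerance = 1e-6)

  # subpixel shift recovered within a quarter pixel
  sub <- condensr:::translate_image(base, c(0.5, 0), fill = 0)
  sts <- image_stack(list(base, sub), c(0, 1), 1)
  expect_equal(unname(register_stack(sts)$shifts[2, 1]), -0.5,
               tolerance = 0.25)

  # re-registration of an already registered stack is near-identity
  rereg <- register_stack(reg$stack)
  expect_lt(max(abs(rereg$shifts)), 0.25)

  expect_warning(register_stack(image_stack(list(base), 0, 1)),
                 "single-frame")
})

test_that("segmentation finds discs, drops specks, ignores blank images", {
  img <- make_disc_image(c(80, 80), list(c(20, 20), c(55, 55)), c(3, 5))
  seg <- segment_puncta(img, pixel_size_um = 1)
  expect_identical(nrow(seg$records), 2L)
  expect_equal(sort(seg$records$area_px), sort(c(pi * 9, pi * 25)),
               tolerance = 0.15)

  expect_identical(nrow(segment_puncta(matrix(0, 50, 50))$records), 0L)
  expect_identical(nrow(segment_puncta(matrix(3.7, 50, 50))$records), 0L)

  # a 2-pixel speck is removed by the minimum-area filter
  sp <- matrix(0, 30, 30); sp[10, 10:11] <- 10
  expect_identical(nrow(segment_puncta(sp, min_area_px = 4)$records), 0L)

  # labels partition the above-threshold pixels
  expect_lte(sum(seg$labels > 0), length(img))
  expect_identical(sum(seg$records$area_px), sum(seg$labels > 0))
})

test_that("labeling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # touch only diagonally
  lab <- condensr:::label_components(m)
  expect_identical(max(lab), 1L)
})

test_that("shape descriptors behave like their analytic definitions", {
  disc <- make_disc_image(c(29, 29), list(c(15, 15)), 10) > 0
  rd <- measure_punctum(disc, pixel_size_um = 0.2)
  expect_gt(rd$circularity, 0.9)   # ideal disc maximizes circularity
  expect_lte(rd$circularity, 1)
  expect_equal(rd$roundness, 1, tolerance = 0.05)
  expect_equal(rd$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(rd$solidity, 1, tolerance = 0.02)  # convex
  expect_equal(rd$area_um2, pi * 100 * 0.04, tolerance = 0.05 * pi * 4)

  # square: circularity = 4*pi*s^2 / (4s)^2 = pi/4 analytically; the
  # pixelated contour convention inflates it somewhat
  sq <- matrix(FALSE, 40, 40); sq[10:29, 10:29] <- TRUE
  rs <- measure_punctum(sq)
  expect_equal(4 * pi * 20^2 / (4 * 20)^2, pi / 4, tolerance = 1e-12)
  expect_equal(rs$circularity, pi / 4, tolerance = 0.2)
  expect_equal(rs$solidity, 1, tolerance = 0.01)

  # single-pixel convention: circularity 1 by definition
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_equal(measure_punctum(px)$circularity, 1)

  # elongated bar: aspect ratio matches side ratio direction
  bar <- matrix(FALSE, 40, 40); bar[18:21, 5:34] <- TRUE
  expect_gt(measure_punctum(bar)$aspect_ratio, 5)
})

test_that("descriptors are invariant to translation and 90-degree rotation", {
  blob <- matrix(FALSE, 50, 50)
  blob[10:18, 12:16] <- TRUE; blob[14:22, 15:24] <- TRUE
  keep <- c("area_px", "perimeter_um", "circularity", "roundness",
            "aspect_ratio", "solidity")
  ref <- measure_punctum(blob)[keep]

  shift <- matrix(FALSE, 50, 50)
  shift[(10:22) + 15, ] <- blob[10:22, ]
  expect_equal(measure_punctum(shift)[keep], ref, tolerance = 1e-9)

  rot <- matrix(FALSE, 50, 50)
  rot[1:50, 1:50] <- t(blob)[50:1, ]  # 90-degree rotation
  expect_equal(measure_punctum(rot)[keep], ref, tolerance = 1e-9)
})

test_that("CTCF follows the background-corrected integrated density", {
  img <- matrix(2, 20, 20)
  cell <- matrix(FALSE, 20, 20); cell[1:10, 1:10] <- TRUE
  img[cell] <- 10  # integrated density 1000 over 100 px
  bg <- matrix(FALSE, 20, 20); bg[15:20, 15:20] <- TRUE
  expect_equal(compute_ctcf(img, cell, bg), 1000 - 100 * 2)

  imgz <- img; imgz[bg] <- 0
  expect_equal(compute_ctcf(imgz, cell, bg), 1000)

  # uniform image: background equals cell level, CTCF cancels to zero
  expect_equal(compute_ctcf(matrix(5, 20, 20), cell, bg), 0)

  expect_error(compute_ctcf(img, cell, matrix(FALSE, 20, 20)), "empty")
  expect_error(compute_ctcf(img, cell, cell), "disjoint")
  expect_warning(compute_ctcf(-img, cell, bg), "negative")
})

test_that("percent punctate fluorescence matches ground truth", {
  expect_equal(percent_punctate_fluorescence(c(20, 30), 200), 25)
  expect_equal(percent_punctate_fluorescence(numeric(0), 200), 0)
  expect_error(percent_punctate_fluorescence(10, 0), "positive")

  sim <- simulate_fixed_cell_image(n_puncta = 4, punctum_radii_px = 4,
                                   diffuse_fraction = 0.6, seed = 8)
  ctcf <- compute_ctcf(sim$image, sim$cell_mask, sim$background_mask)
  bg_mean <- mean(sim$image[sim$background_mask])
  ctfp <- vapply(seq_len(nrow(sim$puncta)), function(i) {
    m <- condensr:::disc_mask(dim(sim$image),
                              c(sim$puncta$centroid_row[i],
                                sim$puncta$centroid_col[i]),
                              sim$puncta$radius_px[i])
    sum(sim$image[m]) - sum(m) * bg_mean
  }, numeric(1))
  expect_equal(percent_punctate_fluorescence(ctfp, ctcf),
               sim$true_percent_punctate, tolerance = 0.02 * 40)
})

test_that("area-circularity trend recovers linear structure", {
  rec <- data.frame(area_um2 = c(1, 2, 3, 4, 5),
                    circularity = 1 - 0.01 * c(1, 2, 3, 4, 5))
  # exact lines trigger R's perfect-fit note; the estimates stay exact
  tr <- suppressWarnings(area_circularity_trend(rec))
  expect_equal(tr$slope, -0.01, tolerance = 1e-10)
  expect_equal(tr$intercept, 1, tolerance = 1e-10)

  recc <- data.frame(area_um2 = 1:5, circularity = rep(0.8, 5))
  expect_equal(suppressWarnings(area_circularity_trend(recc))$slope, 0,
               tolerance = 1e-12)

  # generated puncta with a built-in negative size-shape dependence
  set.seed(21)
  area <- runif(60, 0.5, 15)
  recg <- data.frame(area_um2 = area,
                     circularity = pmin(1, 0.98 - 0.02 * area +
                                          rnorm(60, 0, 0.02)))
  expect_lt(area_circularity_trend(recg)$slope, 0)

  expect_error(area_circularity_trend(rec[1:2, ]), "at least 3")
  expect_error(area_circularity_trend(
    data.frame(area_um2 = rep(2, 5), circularity = runif(5))), "identical")
})
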