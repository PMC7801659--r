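# Puncta segmentation and per-punctum morphometry.
#
# Conventions: coordinates are (row, column); areas are converted to um^2
# via pixel_size^2. Thresholding is Otsu on a 3x3-median-filtered image;
# connected components use 8-connectivity; components smaller than
# `min_area_px` are discarded.

# 8-connected labeling: EBImage::bwlabel (4-connected) followed by a
# union-find merge of labels that touch diagonally.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  d <- dim(lab)
  for (off in list(c(1, 1), c(1, -1))) {
    r1 <- seq_len(d[1] - 1)
    c1 <- if (off[2] > 0) seq_len(d[2] - 1) else 2:d[2]
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + 1, c1 + off[2], drop = FALSE]
    touch <- which(a > 0 & b > 0 & a != b)
    if (length(touch))
      for (k in touch) union_(a[k], b[k])
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Contour length by Moore-neighbour boundary tracing with the
# Vossepoel-Smeulders step weights (0.980 axial, 1.406 diagonal), which
# debias the staircase overestimate of smooth contours. Single-pixel
# convention: a 1-pixel component is assigned perimeter 2*sqrt(pi), which
# makes its circularity exactly 1 by definition.
moore_perimeter <- function(mask) {
  area <- sum(mask)
  if (area == 0L) return(0)
  if (area == 1L) return(2 * sqrt(pi))
  d <- dim(mask)
  m <- matrix(FALSE, d[1] + 2, d[2] + 2)
  m[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  # clockwise neighbour offsets starting West: W NW N NE E SE S SW
  offs <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1,
                   0, 1, 1, 1, 1, 0, 1, -1), ncol = 2, byrow = TRUE)
  idx <- which(m, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  start <- idx[ord[1], ]  # topmost then leftmost: W neighbour is background
  p <- start
  back_dir <- 1L  # came from the West
  perim <- 0
  steps <- 0L
  first_move <- NULL
  repeat {
    found <- FALSE
    for (k in 1:8) {
      dir <- ((back_dir - 1L + k - 1L) %% 8L) + 1L
      q <- p + offs[dir, ]
      if (m[q[1], q[2]]) {
        step_len <- if (sum(abs(offs[dir, ])) == 2) 1.406 else 0.980
        prev_dir <- ((dir - 2L) %% 8L) + 1L
        # backtrack for next pixel: the neighbour just before the hit,
        # expressed as a direction from the new pixel
        bq <- p + offs[prev_dir, ]
        rel <- bq - q
        back_dir <- which(offs[, 1] == rel[1] & offs[, 2] == rel[2])
        if (is.null(first_move)) first_move <- dir
        p <- q
        perim <- perim + step_len
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel cluster fallback
    steps <- steps + 1L
    if (all(p == start) && steps > 1L) break
    if (steps > 8L * area + 8L) break  # safeguard
  }
  perim
}

# Convex-hull area over pixel centres by the shoelace formula. Pairing a
# centre-based hull with a full pixel-count area makes convex pixelated
# shapes come out at (or slightly above, hence the clip) solidity 1.
hull_area <- function(rows, cols) {
  h <- grDevices::chull(rows, cols)
  x <- rows[h]; y <- cols[h]
  n <- length(h)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Morphometry of a single punctum
#'
#' Shape descriptors of one connected component:
#' \itemize{
#'   \item circularity `= 4 * pi * area / perimeter^2`, clipped at 1
#'     (pixelated discs can exceed 1 under any discrete perimeter
#'     convention);
#'   \item roundness `= 4 * area / (pi * major_axis^2)`;
#'   \item aspect ratio `= major_axis / minor_axis` (>= 1);
#'   \item solidity `= area / convex hull area`, clipped at 1.
#' }
#' Axes come from the ellipse with the component's second central moments;
#' each pixel is treated as a unit square (variance 1/12 added per axis),
#' so single-pixel and single-row components have finite axes. Perimeter is
#' the Moore boundary-trace contour length with Vossepoel-Smeulders step
#' weights (0.980 axial, 1.406 diagonal); a single-pixel component is
#' assigned perimeter `2*sqrt(pi)` so that its circularity is 1 by
#' definition.
#'
#' @param mask logical matrix containing exactly one connected component.
#' @param image optional intensity image (same shape) for integrated
#'   density.
#' @param pixel_size_um micrometres per pixel.
#' @param background_mean mean background intensity; used for the corrected
#'   total punctum fluorescence `ctfp = integrated_density - area_px *
#'   background_mean`.
#' @return One-row data frame: `area_px`, `area_um2`, `perimeter_um`,
#'   `circularity`, `roundness`, `aspect_ratio`, `solidity`,
#'   `centroid_row`, `centroid_col`, `integrated_density`, `ctfp`.
#' @export
measure_punctum <- function(mask, image = NULL, pixel_size_um = 1,
                            background_mean = 0) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("empty component", call. = FALSE)
  area_px <- nrow(px)
  perim_px <- moore_perimeter(mask)
  circularity <- min(1, 4 * pi * area_px / perim_px^2)
  mu_r <- mean(px[, 1]); mu_c <- mean(px[, 2])
  m20 <- mean((px[, 1] - mu_r)^2) + 1 / 12
  m02 <- mean((px[, 2] - mu_c)^2) + 1 / 12
  m11 <- mean((px[, 1] - mu_r) * (px[, 2] - mu_c))
  common <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (m20 + m02 + common) / 2
  l2 <- (m20 + m02 - common) / 2
  major <- 4 * sqrt(l1)  # full axis of the moment-equivalent ellipse
  minor <- 4 * sqrt(max(l2, 1e-12))
  solidity <- if (area_px <= 2) 1 else
    min(1, area_px / hull_area(px[, 1], px[, 2]))
  int_den <- if (is.null(image)) NA_real_ else sum(image[mask])
  ctfp <- if (is.null(image)) NA_real_ else
    int_den - area_px * background_mean
  data.frame(
    area_px = area_px, area_um2 = area_px * pixel_size_um^2,
    perimeter_um = perim_px * pixel_size_um,
    circularity = circularity,
    roundness = 4 * area_px / (pi * major^2),
    aspect_ratio = major / minor, solidity = solidity,
    centroid_row = mu_r, centroid_col = mu_c,
    integrated_density = int_den, ctfp = ctfp)
}

#' Segment puncta in a fluorescence image
#'
#' Global automatic thresholding (Otsu computed on a 3x3-median-filtered
#' copy, applied to the unfiltered image), 8-connected component labeling,
#' and removal of components smaller than `min_area_px`, followed by
#' per-component morphometry. A blank or constant image yields zero puncta
#' without error.
#'
#' @param image 2-D numeric intensity matrix.
#' @param pixel_size_um micrometres per pixel.
#' @param min_area_px minimum component size kept, in pixels.
#' @param background_mean mean background intensity passed to
#'   [measure_punctum()] for corrected punctum fluorescence.
#' @param median_filter apply the 3x3 median prefilter before thresholding.
#' @return A list with `labels` (integer label matrix, relabeled 1..n after
#'   size filtering) and `records` (data frame, one row per punctum with a
#'   `punctum_id` column plus the [measure_punctum()] descriptors).
#' @export
segment_puncta <- function(image, pixel_size_um = 1, min_area_px = 4,
                           background_mean = 0, median_filter = TRUE) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  empty <- list(labels = matrix(0L, nrow(image), ncol(image)),
                records = cbind(data.frame(punctum_id = integer(0)),
                                measure_punctum(matrix(TRUE, 1, 1))[0, ]))
  if (rng[1] == rng[2]) return(empty)
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  work <- if (median_filter) EBImage::medianFilter(norm, size = 1) else norm
  th <- EBImage::otsu(EBImage::Image(work), range = c(0, 1), levels = 256L)
  # the median prefilter stabilizes the threshold estimate against shot
  # noise; the mask is cut on the unfiltered image so small puncta are not
  # eroded (isolated noise pixels are removed by the min-area filter)
  mask <- norm > th
  if (!any(mask) || all(mask)) return(empty)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0L) return(empty)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(image), ncol(image))
  out[lab > 0] <- relab[lab[lab > 0]]
  records <- do.call(rbind, lapply(seq_along(keep), function(i) {
    rec <- measure_punctum(out == i, image = image,
                           pixel_size_um = pixel_size_um,
                           background_mean = background_mean)
    cbind(data.frame(punctum_id = i), rec)
  }))
  list(labels = out, records = records)
}
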