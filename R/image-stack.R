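#' Time-lapse image stack container
#'
#' Bundles a single-channel time-lapse as a `Y x X x T` numeric array with
#' acquisition timestamps, the physical pixel size, and (for photobleaching
#' experiments) the index of the first post-bleach frame plus the stimulation
#' ROI that was bleached. Coordinates are 0-based `(row, column)` when
#' reported; internally R's 1-based matrix indexing is used.
#'
#' @param pixels numeric `Y x X x T` array, or a list of `Y x X` matrices
#'   (one per timepoint).
#' @param timestamps numeric vector of acquisition times in seconds, one per
#'   frame, strictly increasing.
#' @param pixel_size_um physical size of one pixel in micrometres.
#' @param bleach_frame_index integer index (1-based) of the first frame
#'   acquired after the bleach event, or `NULL` for stacks without one.
#' @param stimulation_roi logical matrix congruent with one frame marking the
#'   bleached (laser-stimulated) region, or `NULL`.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, timestamps, pixel_size_um,
                        bleach_frame_index = NULL, stimulation_roi = NULL) {
  if (is.list(pixels)) {
    dims <- unique(lapply(pixels, dim))
    if (length(dims) != 1L)
      stop("all frames must share the same dimensions", call. = FALSE)
    pixels <- array(unlist(pixels, use.names = FALSE),
                    dim = c(dims[[1]], length(pixels)))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("`pixels` must be a Y x X x T array or list of matrices",
         call. = FALSE)
  nt <- dim(pixels)[3]
  if (length(timestamps) != nt)
    stop("`timestamps` must have one entry per frame", call. = FALSE)
  if (nt > 1L && any(diff(timestamps) <= 0))
    stop("`timestamps` must be strictly increasing", call. = FALSE)
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 0,
                       strict_lower = TRUE)
  if (!is.null(bleach_frame_index)) {
    assert_scalar_number(bleach_frame_index, "bleach_frame_index",
                         lower = 1, upper = nt)
    bleach_frame_index <- as.integer(bleach_frame_index)
  }
  if (!is.null(stimulation_roi)) {
    stimulation_roi <- as_roi_mask(stimulation_roi, dim(pixels)[1:2])
  }
  structure(
    list(pixels = pixels, timestamps = as.numeric(timestamps),
         pixel_size_um = pixel_size_um,
         bleach_frame_index = bleach_frame_index,
         stimulation_roi = stimulation_roi),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d frames of %d x %d px (%.3f um/px)\n",
              d[3], d[1], d[2], x$pixel_size_um))
  if (!is.null(x$bleach_frame_index))
    cat(sprintf("  bleach event before frame %d (t = %.1f s)\n",
                x$bleach_frame_index, x$timestamps[x$bleach_frame_index]))
  invisible(x)
}

n_frames <- function(stack) dim(stack$pixels)[3]

get_frame <- function(stack, i) stack$pixels[, , i]

# Coerce to a logical ROI mask congruent with `dims`.
as_roi_mask <- function(mask, dims) {
  if (!is.matrix(mask)) stop("ROI mask must be a matrix", call. = FALSE)
  if (!identical(dim(mask), as.integer(dims)))
    stop("ROI mask dimensions do not match the frame", call. = FALSE)
  mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  mask
}

#' Area of an ROI mask in square micrometres
#'
#' @param mask logical matrix marking ROI membership.
#' @param pixel_size_um micrometres per pixel.
#' @return Scalar area: true-pixel count times `pixel_size_um^2`.
#' @export
roi_area_um2 <- function(mask, pixel_size_um) {
  sum(mask) * pixel_size_um^2
}

# Disc-shaped mask on a `dims[1] x dims[2]` grid; a pixel belongs to the disc
# when its centre is within `radius_px` of `center` = c(row, col).
disc_mask <- function(dims, center, radius_px) {
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius_px^2
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages hold one timepoint each, single channel, 16-bit. Intensities are
#' scaled by the stack maximum before quantization; the scale is stored in
#' the sidecar (`intensity_scale`) so that ratio-based downstream analysis
#' is unaffected and absolute units can be restored on read. The sidecar
#' also records `timestamps_s`, `bleach_frame_index` (0-based, or `null`),
#' the `stimulation_roi` (as 0-based true-pixel indices) and
#' `pixel_size_um`.
#'
#' @param stack an [image_stack()].
#' @param tiff_path output TIFF file path.
#' @param sidecar_path output JSON path; defaults to `tiff_path` with a
#'   `.json` extension.
#' @return Invisibly, the two paths written.
#' @export
write_image_stack <- function(stack, tiff_path,
                              sidecar_path = sub("\\.tiff?$", ".json",
                                                 tiff_path)) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(stack$pixels, 1e-12)
  pages <- lapply(seq_len(n_frames(stack)), function(i) {
    p <- get_frame(stack, i) / scale
    p[p < 0] <- 0
    p
  })
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  roi <- NULL
  if (!is.null(stack$stimulation_roi)) {
    idx <- which(stack$stimulation_roi, arr.ind = TRUE) - 1L
    roi <- list(rows = unname(idx[, 1]), cols = unname(idx[, 2]),
                shape = dim(stack$stimulation_roi))
  }
  side <- list(
    timestamps_s = stack$timestamps,
    bleach_frame_index = if (is.null(stack$bleach_frame_index)) NULL else
      stack$bleach_frame_index - 1L,
    stimulation_roi = roi,
    pixel_size_um = stack$pixel_size_um,
    intensity_scale = scale)
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(tiff = tiff_path, sidecar = sidecar_path))
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param tiff_path multi-page TIFF path.
#' @param sidecar_path JSON sidecar path; defaults to `tiff_path` with a
#'   `.json` extension.
#' @return An [image_stack()] with intensities restored to their original
#'   scale (up to 16-bit quantization).
#' @export
read_image_stack <- function(tiff_path,
                             sidecar_path = sub("\\.tiff?$", ".json",
                                                tiff_path)) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  scale <- side$intensity_scale %||% 1
  pages <- lapply(pages, function(p) p * scale)
  roi <- NULL
  if (!is.null(side$stimulation_roi) && length(side$stimulation_roi)) {
    shp <- side$stimulation_roi$shape
    roi <- matrix(FALSE, shp[1], shp[2])
    roi[cbind(side$stimulation_roi$rows + 1L,
              side$stimulation_roi$cols + 1L)] <- TRUE
  }
  bfi <- side$bleach_frame_index
  image_stack(pages, timestamps = side$timestamps_s,
              pixel_size_um = side$pixel_size_um,
              bleach_frame_index = if (is.null(bfi)) NULL else bfi + 1L,
              stimulation_roi = roi)
}
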