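# Rigid (translation) registration of time-lapse stacks by cross-correlation.
# Puncta drift in live-cell FRAP stacks is predominantly translational, so
# translation-only alignment is the default; rotation is out of scope.

# Cross-correlation of two equally sized matrices via FFT; returns the
# (dy, dx) translation that aligns `img` onto `ref` (the negated apparent
# displacement), with optional subpixel parabolic refinement of the
# correlation peak.
xcorr_shift <- function(ref, img, subpixel = TRUE) {
  a <- ref - mean(ref)
  b <- img - mean(img)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  d <- dim(cc)
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # wrap indices to signed displacements
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dy <- wrap(peak[1], d[1])
  dx <- wrap(peak[2], d[2])
  if (subpixel) {
    refine <- function(center, axis_n, get_val) {
      cm <- get_val(-1); c0 <- get_val(0); cp <- get_val(1)
      denom <- cm - 2 * c0 + cp
      if (denom < 0) center + 0.5 * (cm - cp) / denom else center
    }
    at <- function(i, j) {
      ii <- ((peak[1] - 1 + i) %% d[1]) + 1
      jj <- ((peak[2] - 1 + j) %% d[2]) + 1
      cc[ii, jj]
    }
    dy <- refine(dy, d[1], function(k) at(k, 0))
    dx <- refine(dx, d[2], function(k) at(0, k))
  }
  c(dy = unname(dy), dx = unname(dx))
}

# Translate an image by (dy, dx) (possibly fractional) using bilinear
# interpolation; pixels sampled outside the field are filled with `fill`.
translate_image <- function(img, shift, fill = stats::median(img)) {
  d <- dim(img)
  rr <- matrix(seq_len(d[1]), d[1], d[2]) - shift[1]
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - shift[2]
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  val <- function(r, c) {
    out <- r < 1 | r > d[1] | c < 1 | c > d[2]
    r[out] <- 1; c[out] <- 1
    v <- img[cbind(as.vector(r), as.vector(c))]
    v[as.vector(out)] <- fill
    matrix(v, d[1], d[2])
  }
  v <- (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
  v
}

#' Register a time-lapse stack by translation
#'
#' Aligns every frame to the first (pre-bleach) frame using FFT
#' cross-correlation with parabolic subpixel refinement, then resamples the
#' frames with bilinear interpolation. Out-of-field pixels are filled with
#' the frame's background median. The reported shift for frame i is the
#' correction that was applied to align it.
#'
#' @param stack an [image_stack()] with at least 2 frames (a single-frame
#'   stack is returned unchanged with a warning).
#' @param subpixel refine shifts below one pixel (default `TRUE`).
#' @return A list with `stack` (registered) and `shifts` (n x 2 matrix of
#'   applied `(dy, dx)` corrections).
#' @export
register_stack <- function(stack, subpixel = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- n_frames(stack)
  if (nt < 2L) {
    warning("single-frame stack: registration is a no-op", call. = FALSE)
    return(list(stack = stack,
                shifts = matrix(0, nt, 2,
                                dimnames = list(NULL, c("dy", "dx")))))
  }
  ref <- get_frame(stack, 1L)
  shifts <- matrix(0, nt, 2, dimnames = list(NULL, c("dy", "dx")))
  out <- stack
  for (i in 2:nt) {
    fr <- get_frame(stack, i)
    corr <- xcorr_shift(ref, fr, subpixel = subpixel)
    shifts[i, ] <- corr
    if (any(abs(corr) > 1e-9))
      out$pixels[, , i] <- translate_image(fr, corr)
  }
  list(stack = out, shifts = shifts)
}
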