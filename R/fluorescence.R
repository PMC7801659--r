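# Corrected fluorescence statistics: CTCF (per cell), CTFP (per punctum,
# see measure_punctum), percent punctate fluorescence, and the punctum
# size-shape trend.

#' Corrected total cell fluorescence (CTCF)
#'
#' `CTCF = integrated density over the cell mask - cell area (px) * mean
#' background intensity`, the standard background-corrected expression
#' measure. The background is a user-supplied ROI outside the cell; no
#' automatic background detection is attempted.
#'
#' @param image 2-D intensity matrix.
#' @param cell_mask logical matrix marking the cell.
#' @param background_mask logical matrix marking background pixels; must be
#'   non-empty and disjoint from `cell_mask`.
#' @return Scalar CTCF (arbitrary units). Negative values are allowed but
#'   flagged with a warning.
#' @export
compute_ctcf <- function(image, cell_mask, background_mask) {
  cell_mask <- as_roi_mask(cell_mask, dim(image))
  background_mask <- as_roi_mask(background_mask, dim(image))
  if (!any(background_mask))
    stop("background mask is empty", call. = FALSE)
  if (any(cell_mask & background_mask))
    stop("cell and background masks must be disjoint", call. = FALSE)
  ctcf <- sum(image[cell_mask]) -
    sum(cell_mask) * mean(image[background_mask])
  if (ctcf < 0)
    warning("negative CTCF: background exceeds cell signal", call. = FALSE)
  ctcf
}

#' Percent punctate fluorescence of a cell
#'
#' The sum of corrected total punctum fluorescence (CTFP) over all puncta
#' in a cell, divided by the cell's CTCF, times 100.
#'
#' @param ctfp numeric vector of per-punctum CTFP values (possibly empty).
#' @param ctcf the cell's CTCF; must be positive.
#' @return Percentage in `[0, 100]` up to noise (slightly larger values can
#'   occur when background correction overshoots).
#' @export
percent_punctate_fluorescence <- function(ctfp, ctcf) {
  assert_scalar_number(ctcf, "ctcf")
  if (ctcf <= 0)
    stop("`ctcf` must be positive to normalize punctum fluorescence",
         call. = FALSE)
  if (length(ctfp) == 0L) return(0)
  100 * sum(ctfp) / ctcf
}

#' Linear trend of punctum circularity against area
#'
#' Ordinary least-squares fit of `circularity ~ area`, used to test whether
#' larger puncta tend to be less circular (a negative slope).
#'
#' @param records data frame with columns `area_um2` and `circularity`.
#' @return A list with `slope` (1/um^2), `intercept`, `p_value` (slope
#'   t-test) and `n`.
#' @export
area_circularity_trend <- function(records) {
  stopifnot(all(c("area_um2", "circularity") %in% names(records)))
  ok <- complete.cases(records[, c("area_um2", "circularity")])
  records <- records[ok, ]
  if (nrow(records) < 3L)
    stop("at least 3 puncta are required", call. = FALSE)
  if (var(records$area_um2) == 0)
    stop("punctum areas are all identical; trend undefined", call. = FALSE)
  fit <- lm(circularity ~ area_um2, data = records)
  smry <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p_value = unname(smry[2, 4]), n = nrow(records))
}
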