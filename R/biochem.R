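# Non-imaging quantifications: percent-insoluble protein from densitometry
# tables and thioflavin-T time-to-half-transition estimation.

#' Kinetic trace container
#'
#' @param timestamps_h times in hours, strictly increasing, at least 3.
#' @param fluorescence fluorescence values (arbitrary units).
#' @param replicate_id replicate identifier.
#' @return An object of class `kinetic_trace` (data frame `time_h`,
#'   `fluorescence` plus a `replicate_id` attribute-like field).
#' @export
kinetic_trace <- function(timestamps_h, fluorescence, replicate_id = "r1") {
  if (length(timestamps_h) < 3L)
    stop("a kinetic trace needs at least 3 points", call. = FALSE)
  if (length(fluorescence) != length(timestamps_h))
    stop("`fluorescence` and `timestamps_h` lengths differ", call. = FALSE)
  if (any(diff(timestamps_h) <= 0))
    stop("`timestamps_h` must be strictly increasing", call. = FALSE)
  structure(list(points = data.frame(time_h = as.numeric(timestamps_h),
                                     fluorescence = as.numeric(fluorescence)),
                 replicate_id = replicate_id),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> '%s': %d points, t = %.2f..%.2f h\n",
              x$replicate_id, nrow(x$points), min(x$points$time_h),
              max(x$points$time_h)))
  invisible(x)
}

corrected_density <- function(row) {
  if (row$loading_normalizer <= 0)
    stop("loading normalizer must be positive", call. = FALSE)
  row$band_density / row$loading_normalizer * row$volume_factor
}

#' Percent of protein in the insoluble fraction
#'
#' Each band density is normalized by its own lane's loading normalizer
#' (total-protein stain or housekeeping band) and corrected by the
#' lysate-volume factor; the insoluble percentage is then
#' `100 * P / (S + P)` on the corrected densities.
#'
#' @param s_row,p_row one-row data frames (or lists) with fields
#'   `sample_id`, `fraction` (`"S"` / `"P"`), `band_density`,
#'   `loading_normalizer`, `volume_factor`, as produced by
#'   [simulate_densitometry()] or read from a densitometry CSV.
#' @return Percentage in `[0, 100]`.
#' @export
percent_insoluble <- function(s_row, p_row) {
  if (!identical(s_row$sample_id, p_row$sample_id))
    stop("soluble and pellet rows belong to different samples",
         call. = FALSE)
  if (!identical(toupper(s_row$fraction), "S") ||
      !identical(toupper(p_row$fraction), "P"))
    stop("expected fractions 'S' then 'P'", call. = FALSE)
  if (s_row$band_density < 0 || p_row$band_density < 0)
    stop("band densities must be non-negative", call. = FALSE)
  s_corr <- corrected_density(s_row)
  p_corr <- corrected_density(p_row)
  total <- s_corr + p_corr
  if (total <= 0)
    stop("corrected soluble + insoluble density is zero", call. = FALSE)
  100 * p_corr / total
}

#' Time to half transition to steady state of an aggregation trace
#'
#' Model-free estimator: the baseline is the mean of the first 5% of
#' points, the plateau the mean of the last 10%, and t50 the first time
#' the trace crosses their midpoint, linearly interpolated between the
#' bracketing samples. A steady state is declared when the least-squares
#' slope over the last 10% of points is below `steady_slope_tol` of the
#' dynamic range per hour; otherwise the flag is `FALSE` and t50 is
#' withheld (`NA`). An optional logistic-fit estimator is available for
#' cross-checking (`method = "logistic"`; it reports the fitted
#' half-transition time and requires the steady-state check to pass as
#' well).
#'
#' @param trace a [kinetic_trace()].
#' @param baseline_frac,plateau_frac fractions of points defining the
#'   baseline and plateau windows.
#' @param steady_slope_tol steady-state tolerance, as a fraction of the
#'   dynamic range per hour.
#' @param method `"midpoint"` (default, model-free) or `"logistic"`.
#' @return A list with `t50_h`, `baseline`, `plateau`,
#'   `steady_state_reached`.
#' @export
tht_t50 <- function(trace, baseline_frac = 0.05, plateau_frac = 0.10,
                    steady_slope_tol = 0.01,
                    method = c("midpoint", "logistic")) {
  stopifnot(inherits(trace, "kinetic_trace"))
  method <- match.arg(method)
  t <- trace$points$time_h
  y <- trace$points$fluorescence
  n <- length(t)
  n_base <- max(1L, ceiling(baseline_frac * n))
  n_plat <- max(2L, ceiling(plateau_frac * n))
  baseline <- mean(y[seq_len(n_base)])
  plateau <- mean(y[(n - n_plat + 1L):n])
  if (plateau <= baseline)
    stop("no upward transition: plateau does not exceed baseline",
         call. = FALSE)
  tail_idx <- (n - n_plat + 1L):n
  slope <- unname(coef(lm(y[tail_idx] ~ t[tail_idx]))[2])
  steady <- abs(slope) < steady_slope_tol * (plateau - baseline)
  if (!steady)
    return(list(t50_h = NA_real_, baseline = baseline, plateau = plateau,
                steady_state_reached = FALSE))
  if (method == "logistic") {
    mid0 <- (baseline + plateau) / 2
    t0 <- t[which(y >= mid0)[1]]
    fit <- minpack.lm::nlsLM(
      y ~ b + (p - b) / (1 + exp(-k * (t - th))),
      start = list(b = baseline, p = plateau, k = 1, th = t0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    t50 <- unname(coef(fit)["th"])
    return(list(t50_h = t50, baseline = baseline, plateau = plateau,
                steady_state_reached = TRUE))
  }
  mid <- (baseline + plateau) / 2
  i <- which(y >= mid)[1]
  if (is.na(i))
    stop("trace never reaches the baseline-plateau midpoint", call. = FALSE)
  t50 <- if (i == 1L) t[1L] else
    t[i - 1L] + (mid - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
  list(t50_h = t50, baseline = baseline, plateau = plateau,
       steady_state_reached = TRUE)
}

#' Pointwise mean and SEM of replicate kinetic traces
#'
#' @param traces list of [kinetic_trace()] objects sharing a common time
#'   grid (or set `interpolate = TRUE` to resample all traces onto the
#'   first trace's grid by linear interpolation).
#' @param interpolate allow traces on different grids.
#' @return A data frame with columns `time_h`, `mean`, `sem`, `n`. SEM is
#'   `NA` (with a warning) for a single replicate.
#' @export
average_replicates <- function(traces, interpolate = FALSE) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "kinetic_trace")))
  grid <- traces[[1]]$points$time_h
  ys <- lapply(traces, function(tr) {
    if (identical(tr$points$time_h, grid)) return(tr$points$fluorescence)
    if (!interpolate)
      stop("traces are on different time grids; set `interpolate = TRUE`",
           call. = FALSE)
    stats::approx(tr$points$time_h, tr$points$fluorescence, xout = grid,
                  rule = 2)$y
  })
  m <- do.call(cbind, ys)
  if (length(traces) == 1L)
    warning("single replicate: SEM is undefined", call. = FALSE)
  data.frame(time_h = grid,
             mean = rowMeans(m),
             sem = if (ncol(m) < 2L) NA_real_ else
               apply(m, 1, stats::sd) / sqrt(ncol(m)),
             n = ncol(m))
}
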