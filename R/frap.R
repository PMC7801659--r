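# FRAP quantification: candidate selection, FRAP-ROI construction by mask
# arithmetic, trace extraction, two-anchor normalization and bounded fitting
# of the single-exponential recovery model A * (1 - exp(-t / tau)).

#' FRAP trace container
#'
#' Holds the per-frame integrated-density ratio of a photobleached region,
#' with acquisition phases labeled. Time is re-anchored so that t = 0 is
#' the first post-bleach frame and pre-bleach frames carry negative
#' timestamps (the recovery model is defined on recovery time).
#'
#' @param timestamps_s acquisition times in seconds, strictly increasing.
#' @param value raw integrated-density ratios, one per frame.
#' @param n_prebleach number of leading pre-bleach frames (>= 1).
#' @param normalized optional normalized values (set by
#'   [normalize_trace()]).
#' @return An object of class `frap_trace` with columns `time_s`, `value`,
#'   `normalized` (NA until normalized) and `phase` (`"pre"`/`"post"`).
#' @export
frap_trace <- function(timestamps_s, value, n_prebleach,
                       normalized = NULL) {
  n <- length(timestamps_s)
  if (length(value) != n)
    stop("`value` and `timestamps_s` lengths differ", call. = FALSE)
  if (any(diff(timestamps_s) <= 0))
    stop("`timestamps_s` must be strictly increasing", call. = FALSE)
  n_prebleach <- as.integer(n_prebleach)
  if (n_prebleach < 1L || n_prebleach >= n)
    stop("need at least 1 pre-bleach and 1 post-bleach frame", call. = FALSE)
  time_s <- timestamps_s - timestamps_s[n_prebleach + 1L]
  df <- data.frame(
    time_s = time_s, value = value,
    normalized = if (is.null(normalized)) NA_real_ else normalized,
    phase = rep(c("pre", "post"), c(n_prebleach, n - n_prebleach)))
  structure(list(points = df, n_prebleach = n_prebleach),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d frames (%d pre-bleach), t = %.1f..%.1f s%s\n",
              nrow(x$points), x$n_prebleach, min(x$points$time_s),
              max(x$points$time_s),
              if (all(is.na(x$points$normalized))) "" else ", normalized"))
  invisible(x)
}

#' Filter puncta eligible for photobleaching
#'
#' Applies the candidate-selection rules used in condensate FRAP protocols:
#' the bleached (stimulation) area must be at most 80% of the punctum area,
#' the punctum must have no immediate neighbour (no other punctum centroid
#' within `exclusion_radius_um`, by default twice the candidate's
#' equivalent diameter), and optionally the punctum area must fall inside a
#' size band.
#'
#' @param records data frame of punctum records with columns `area_um2`,
#'   `centroid_row`, `centroid_col` (pixel coordinates).
#' @param stimulation_roi_area_um2 area of the bleach ROI in um^2.
#' @param pixel_size_um micrometres per pixel (to convert centroid
#'   distances).
#' @param exclusion_radius_um neighbour-exclusion radius in um, or `NULL`
#'   for the per-punctum default of 2 equivalent diameters.
#' @param size_band_um2 optional `c(min, max)` punctum-area band in um^2.
#' @param max_bleach_fraction maximum allowed stimulation-to-punctum area
#'   ratio (default 0.80).
#' @return The input records with logical column `selected` and character
#'   column `rejection_reason` (`NA` for kept records; otherwise
#'   `"bleach_fraction"`, `"neighbor"` or `"size_band"`, the first rule
#'   that failed).
#' @export
select_bleach_candidates <- function(records, stimulation_roi_area_um2,
                                     pixel_size_um = 1,
                                     exclusion_radius_um = NULL,
                                     size_band_um2 = NULL,
                                     max_bleach_fraction = 0.80) {
  if (nrow(records) == 0L) {
    records$selected <- logical(0)
    records$rejection_reason <- character(0)
    return(records)
  }
  stopifnot(all(c("area_um2", "centroid_row", "centroid_col") %in%
                names(records)))
  frac <- stimulation_roi_area_um2 / records$area_um2
  eq_diam_um <- 2 * sqrt(records$area_um2 / pi)
  excl <- if (is.null(exclusion_radius_um)) 2 * eq_diam_um else
    rep_len(exclusion_radius_um, nrow(records))
  d_um <- as.matrix(stats::dist(
    cbind(records$centroid_row, records$centroid_col))) * pixel_size_um
  diag(d_um) <- Inf
  has_neighbor <- apply(d_um, 1, min) < excl
  reason <- rep(NA_character_, nrow(records))
  reason[has_neighbor] <- "neighbor"
  if (!is.null(size_band_um2)) {
    out_band <- records$area_um2 < size_band_um2[1] |
      records$area_um2 > size_band_um2[2]
    reason[is.na(reason) & out_band] <- "size_band"
  }
  reason[frac > max_bleach_fraction] <- "bleach_fraction"
  records$selected <- is.na(reason)
  records$rejection_reason <- reason
  records
}

#' Construct the FRAP ROI from pre- and post-bleach signal masks
#'
#' The FRAP ROI is the region of bleached signal: pixels present in the
#' thresholded pre-bleach signal but absent from the post-bleach signal
#' (the set difference, equivalent to inverting the pre-bleach mask and
#' subtracting the post-bleach mask from it).
#'
#' @param prebleach_mask,postbleach_mask congruent logical matrices from
#'   thresholding the pre- and post-bleach frames.
#' @return A logical FRAP ROI mask.
#' @export
build_frap_roi <- function(prebleach_mask, postbleach_mask) {
  if (!identical(dim(prebleach_mask), dim(postbleach_mask)))
    stop("masks must be congruent", call. = FALSE)
  frap_roi <- prebleach_mask & !postbleach_mask
  if (!any(frap_roi))
    stop("no bleached signal detected: the post-bleach mask covers the ",
         "entire pre-bleach mask", call. = FALSE)
  if (!any(prebleach_mask & postbleach_mask))
    warning("pre- and post-bleach masks are disjoint; FRAP ROI equals the ",
            "pre-bleach mask", call. = FALSE)
  frap_roi
}

#' Extract a FRAP trace from a registered stack
#'
#' For every frame, the integrated density of the FRAP ROI is divided by
#' the integrated density of the pre-bleach ROI. With the default
#' `reference = "prebleach_mean"` the denominator is the pre-bleach ROI's
#' integrated density averaged over the pre-bleach frames, a fixed
#' reference that leaves the recovery kinetics of the bleached region
#' undistorted; `reference = "per_frame"` divides by the pre-bleach ROI's
#' density in the same frame instead, which cancels whole-frame
#' acquisition photobleaching at the cost of mixing the recovering region
#' into the denominator.
#'
#' @param stack a registered [image_stack()] with `bleach_frame_index` set.
#' @param frap_roi FRAP ROI mask from [build_frap_roi()].
#' @param prebleach_roi pre-bleach signal mask.
#' @param reference denominator convention, see above.
#' @return A [frap_trace()] of raw ratios.
#' @export
extract_trace <- function(stack, frap_roi, prebleach_roi,
                          reference = c("prebleach_mean", "per_frame")) {
  stopifnot(inherits(stack, "image_stack"))
  reference <- match.arg(reference)
  if (is.null(stack$bleach_frame_index))
    stop("stack has no bleach event", call. = FALSE)
  dims <- dim(stack$pixels)[1:2]
  frap_roi <- as_roi_mask(frap_roi, dims)
  prebleach_roi <- as_roi_mask(prebleach_roi, dims)
  nt <- n_frames(stack)
  npre <- stack$bleach_frame_index - 1L
  num <- vapply(seq_len(nt), function(i) sum(get_frame(stack, i)[frap_roi]),
                numeric(1))
  den_frame <- vapply(seq_len(nt),
                      function(i) sum(get_frame(stack, i)[prebleach_roi]),
                      numeric(1))
  den <- switch(reference,
                prebleach_mean = rep(mean(den_frame[seq_len(npre)]), nt),
                per_frame = den_frame)
  if (any(den == 0))
    stop("pre-bleach ROI has zero integrated density", call. = FALSE)
  frap_trace(timestamps_s = stack$timestamps, value = num / den,
             n_prebleach = npre)
}

#' Two-anchor normalization of a FRAP trace
#'
#' Maps the trace affinely so that the mean of the pre-bleach values is 1
#' and the first post-bleach value is 0:
#' `x -> (x - F0) / (Fpre - F0)` with `Fpre` the pre-bleach mean and `F0`
#' the first post-bleach value. The map is idempotent: normalizing an
#' already-normalized trace changes nothing.
#'
#' @param trace a [frap_trace()].
#' @return The trace with its `normalized` column filled.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  pts <- trace$points
  x <- if (all(is.na(pts$normalized))) pts$value else pts$normalized
  pre <- x[pts$phase == "pre"]
  f0 <- x[trace$n_prebleach + 1L]
  f_pre <- mean(pre)
  if (f_pre == f0)
    stop("no bleach contrast: pre-bleach mean equals first post-bleach ",
         "value", call. = FALSE)
  trace$points$normalized <- (x - f0) / (f_pre - f0)
  trace
}

#' Fit the single-exponential recovery model to a normalized FRAP trace
#'
#' Bounded nonlinear least squares of `A * (1 - exp(-t / tau))` over the
#' post-bleach points only (the model is a pure recovery curve). Bounds are
#' `A` in `[0, 1.5]` and `tau` in `(0, 10 * last timestamp]`. Starting
#' values: `A0` = mean of the last 3 normalized points, `tau0` = first time
#' the trace crosses `A0 / 2` (falling back to mid-span); on failure the
#' start is jittered over `restarts` attempts.
#'
#' `A` is the mobile fraction and `tau` the fitted time constant, reported
#' as `half_time_s` following the common labeling of tau as the recovery
#' half-time; the actual time to half recovery of this model is
#' `tau * log(2)`, exposed as `t_half_ln2_s`.
#'
#' @param trace a normalized [frap_trace()] with at least 4 post-bleach
#'   points (normalization is applied first if missing).
#' @param restarts number of jittered restarts after a failed fit.
#' @param identifiability_threshold mobile fractions below this leave `tau`
#'   unconstrained by the data; such fits are flagged.
#' @return An object of class `frap_fit`: list with `mobile_fraction`,
#'   `half_time_s`, `t_half_ln2_s`, `rss`, `converged`,
#'   `identifiability_flag`, `n_points`.
#' @export
fit_recovery <- function(trace, restarts = 5,
                         identifiability_threshold = 0.02) {
  stopifnot(inherits(trace, "frap_trace"))
  if (all(is.na(trace$points$normalized))) trace <- normalize_trace(trace)
  post <- trace$points[trace$points$phase == "post", ]
  if (nrow(post) < 4L)
    stop("at least 4 post-bleach points are required", call. = FALSE)
  t <- post$time_s
  y <- post$normalized
  upper_tau <- 10 * max(t)
  a0 <- mean(tail(y, 3))
  a0 <- min(max(a0, 0.01), 1.5)
  cross <- which(y >= a0 / 2 & t > 0)
  tau0 <- if (length(cross) > 0) max(t[cross[1]], 1e-3) else max(t) / 2
  tau0 <- min(tau0, upper_tau)

  do_fit <- function(a_start, tau_start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ A * (1 - exp(-t / tau)),
        start = list(A = a_start, tau = tau_start),
        lower = c(0, 1e-9), upper = c(1.5, upper_tau),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  # profile least squares over tau: A enters the model linearly, so for a
  # fixed tau the optimal A is closed-form. This both seeds the nonlinear
  # fit and serves as a deterministic fallback for near-flat traces, where
  # Levenberg-Marquardt meets a singular gradient.
  profile_fit <- function() {
    taus <- exp(seq(log(1e-2), log(upper_tau), length.out = 80))
    best <- c(a = 0, tau = taus[1], rss = Inf)
    for (tau in taus) {
      g <- 1 - exp(-t / tau)
      a <- min(max(sum(y * g) / sum(g * g), 0), 1.5)
      rss <- sum((y - a * g)^2)
      if (rss < best["rss"]) best <- c(a = a, tau = tau, rss = rss)
    }
    best
  }
  fit <- do_fit(a0, tau0)
  attempt <- 0L
  while (is.null(fit) && attempt < restarts) {
    attempt <- attempt + 1L
    if (attempt == 1L) {
      prof <- profile_fit()
      fit <- do_fit(max(prof["a"], 1e-3), prof["tau"])
    } else {
      jit <- with_local_seed(attempt, c(runif(1, 0, 1.2),
                                        runif(1, 1e-2, max(t))))
      fit <- do_fit(jit[1], jit[2])
    }
  }
  if (is.null(fit)) {
    prof <- profile_fit()
    a_hat <- unname(prof["a"])
    tau_hat <- unname(prof["tau"])
    return(structure(
      list(mobile_fraction = a_hat, half_time_s = tau_hat,
           t_half_ln2_s = tau_hat * log(2), rss = unname(prof["rss"]),
           converged = TRUE,
           identifiability_flag = a_hat < identifiability_threshold,
           n_points = nrow(post)),
      class = "frap_fit"))
  }
  cf <- coef(fit)
  a_hat <- unname(cf["A"])
  tau_hat <- unname(cf["tau"])
  structure(
    list(mobile_fraction = a_hat, half_time_s = tau_hat,
         t_half_ln2_s = tau_hat * log(2),
         rss = sum(stats::resid(fit)^2), converged = TRUE,
         identifiability_flag = a_hat < identifiability_threshold,
         n_points = nrow(post)),
    class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> A = %.3f, tau = %.2f s (t1/2 = %.2f s), rss = %.3g%s%s\n",
    x$mobile_fraction, x$half_time_s, x$t_half_ln2_s, x$rss,
    if (x$converged) "" else " [not converged]",
    if (x$identifiability_flag) " [tau unidentifiable]" else ""))
  invisible(x)
}

#' Summarize FRAP fits by experimental group
#'
#' Arithmetic mean, SEM and count of the mobile fraction and recovery time
#' constant per group. Non-converged fits are excluded (and counted);
#' groups with no converged fit are omitted with a warning.
#'
#' @param fits list of [fit_recovery()] results.
#' @param groups character/factor vector of group labels, one per fit.
#' @return Data frame with one row per group: `group`, `n`, `n_excluded`,
#'   `mean_mobile_fraction`, `sem_mobile_fraction`, `mean_half_time_s`,
#'   `sem_half_time_s`. SEM is `NA` for single-fit groups.
#' @export
summarize_frap <- function(fits, groups) {
  stopifnot(length(fits) == length(groups))
  groups <- as.character(groups)
  rows <- lapply(unique(groups), function(g) {
    fg <- fits[groups == g]
    conv <- vapply(fg, function(f) isTRUE(f$converged), logical(1))
    if (!any(conv)) {
      warning("group '", g, "' has no converged fits; omitted",
              call. = FALSE)
      return(NULL)
    }
    a <- vapply(fg[conv], `[[`, numeric(1), "mobile_fraction")
    tau <- vapply(fg[conv], `[[`, numeric(1), "half_time_s")
    data.frame(group = g, n = sum(conv), n_excluded = sum(!conv),
               mean_mobile_fraction = mean(a), sem_mobile_fraction = sem(a),
               mean_half_time_s = mean(tau), sem_half_time_s = sem(tau))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
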