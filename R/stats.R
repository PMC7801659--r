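# Rank-based and parametric group comparisons, implemented from their
# defining formulas (midranks for ties, tie-corrected variances). The
# corresponding base-R routines serve as independent cross-checks in the
# test suite, not as the implementation.

check_groups <- function(values, groups, min_groups = 2L) {
  if (length(values) != length(groups))
    stop("`values` and `groups` lengths differ", call. = FALSE)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < min_groups)
    stop("at least ", min_groups, " groups are required", call. = FALSE)
  list(values = values, groups = droplevels(groups))
}

tie_sizes <- function(x) {
  tab <- table(x)
  as.numeric(tab[tab > 1])
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H with midranks, and the chi-square
#' approximation for the p-value (`df = k - 1`). When all pooled values
#' are identical the convention `H = 0, p = 1` applies (no evidence of
#' group differences in a constant sample).
#'
#' @param values numeric observations.
#' @param groups group labels, at least 2 groups and 3 observations total.
#' @return A list with `H`, `df`, `p_value`, `n`, `mean_ranks`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- check_groups(values, groups)
  x <- g$values; grp <- g$groups
  N <- length(x)
  if (N < 3L) stop("at least 3 observations are required", call. = FALSE)
  r <- rank(x)  # midranks
  mean_ranks <- tapply(r, grp, mean)
  n_i <- tabulate(grp)
  H <- 12 / (N * (N + 1)) * sum(n_i * (mean_ranks - (N + 1) / 2)^2)
  ties <- tie_sizes(x)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (correction <= 0) {
    # all values identical: no rank variation at all
    H <- 0
    p <- 1
  } else {
    H <- H / correction
    p <- pchisq(H, df = nlevels(grp) - 1, lower.tail = FALSE)
  }
  list(H = unname(H), df = nlevels(grp) - 1L, p_value = unname(p), n = N,
       mean_ranks = mean_ranks)
}

#' Dunn's post-hoc test
#'
#' Pairwise z statistics on the pooled midranks following a Kruskal-Wallis
#' test:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' with tie term `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided normal
#' p-values, optionally Bonferroni-adjusted over the `k(k-1)/2`
#' comparisons (unadjusted by default).
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param adjustment `"none"` (default) or `"bonferroni"`.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups,
                         adjustment = c("none", "bonferroni")) {
  adjustment <- match.arg(adjustment)
  g <- check_groups(values, groups)
  x <- g$values; grp <- g$groups
  N <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, grp, mean)
  n_i <- tabulate(grp)
  ties <- tie_sizes(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  if (base_var <= 0)
    stop("degenerate rank variance (all values tied)", call. = FALSE)
  lev <- levels(grp)
  pairs <- utils::combn(seq_along(lev), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    z <- (mean_ranks[i] - mean_ranks[j]) /
      sqrt(base_var * (1 / n_i[i] + 1 / n_i[j]))
    pv <- 2 * pnorm(-abs(z))
    data.frame(group1 = lev[i], group2 = lev[j], z = unname(z),
               p_value = unname(pv))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjustment == "bonferroni")
    pmin(1, m * out$p_value) else out$p_value
  out
}

#' One-way analysis of variance with Bonferroni pairwise comparisons
#'
#' Classical between/within decomposition: `F = MSB / MSW` with
#' `df = (k - 1, N - k)`. Pairwise comparisons use t statistics on the
#' pooled within-group mean square, Bonferroni-adjusted.
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param posthoc include the Bonferroni pairwise table.
#' @return A list with `F`, `df1`, `df2`, `p_value`, `ss_between`,
#'   `ss_within`, and (if requested) `pairwise` (data frame `group1`,
#'   `group2`, `t`, `p_value`, `p_adjusted`).
#' @export
anova_oneway <- function(values, groups, posthoc = TRUE) {
  g <- check_groups(values, groups)
  x <- g$values; grp <- g$groups
  N <- length(x)
  k <- nlevels(grp)
  if (N <= k) stop("need more observations than groups", call. = FALSE)
  means <- tapply(x, grp, mean)
  n_i <- tabulate(grp)
  grand <- mean(x)
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum((x - means[grp])^2)
  if (ssw == 0)
    stop("zero within-group variance; F is undefined", call. = FALSE)
  df1 <- k - 1L
  df2 <- N - k
  msw <- ssw / df2
  f_stat <- (ssb / df1) / msw
  p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  res <- list(F = f_stat, df1 = df1, df2 = df2, p_value = p,
              ss_between = ssb, ss_within = ssw)
  if (posthoc) {
    lev <- levels(grp)
    pairs <- utils::combn(seq_len(k), 2)
    m <- ncol(pairs)
    rows <- lapply(seq_len(m), function(p_) {
      i <- pairs[1, p_]; j <- pairs[2, p_]
      t_stat <- (means[i] - means[j]) /
        sqrt(msw * (1 / n_i[i] + 1 / n_i[j]))
      pv <- 2 * pt(-abs(t_stat), df2)
      data.frame(group1 = lev[i], group2 = lev[j], t = unname(t_stat),
                 p_value = unname(pv))
    })
    pw <- do.call(rbind, rows)
    pw$p_adjusted <- pmin(1, m * pw$p_value)
    res$pairwise <- pw
  }
  res
}
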