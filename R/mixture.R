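# Maximum-likelihood fitting of K-component univariate normal mixtures by
# expectation-maximization, used to decompose punctum-area distributions
# into a small-puncta population (P1) and a larger, broader population
# (P2). The EM algorithm here is the package's own implementation; model
# containers report components sorted by ascending mean, so P1 is always
# the smallest-mean component.

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

mixture_loglik <- function(x, weights, means, sds) {
  lp <- vapply(seq_along(weights), function(k)
    log(weights[k]) + dnorm(x, means[k], sds[k], log = TRUE),
    numeric(length(x)))
  if (is.null(dim(lp))) lp <- matrix(lp, nrow = length(x))
  sum(log_sum_exp_rows(lp))
}

# One EM run from a given block assignment of the sorted data.
em_run <- function(x, K, init_groups, max_iter, tol, var_floor) {
  n <- length(x)
  w <- vapply(seq_len(K), function(k) mean(init_groups == k), numeric(1))
  w[w == 0] <- 1 / n
  w <- w / sum(w)
  mu <- vapply(seq_len(K), function(k) mean(x[init_groups == k]), numeric(1))
  s2 <- vapply(seq_len(K), function(k) {
    xi <- x[init_groups == k]
    max(stats::var(xi) * (length(xi) - 1) / max(length(xi), 1), var_floor)
  }, numeric(1))
  s2[!is.finite(s2)] <- var_floor
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    lp <- vapply(seq_len(K), function(k)
      log(w[k]) + dnorm(x, mu[k], sqrt(s2[k]), log = TRUE),
      numeric(n))
    if (is.null(dim(lp))) lp <- matrix(lp, nrow = n)
    lse <- log_sum_exp_rows(lp)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s2 <- vapply(seq_len(K), function(k)
      max(sum(resp[, k] * (x - mu[k])^2) / nk[k], var_floor), numeric(1))
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  ll_final <- mixture_loglik(x, w, mu, sqrt(s2))
  list(weights = w, means = mu, sds = sqrt(s2), log_likelihood = ll_final,
       ll_trace = ll_trace, n_iterations = iter, converged = converged)
}

#' Fit a univariate normal mixture by EM with restarts
#'
#' Best-of-restarts expectation-maximization. Initialization splits the
#' sorted data into K equal quantile blocks (block means and SDs, equal
#' weights); each restart jitters the block boundaries at random. A
#' variance floor of `1e-6 * range(x)^2` prevents degenerate collapse onto
#' single points, and the log-likelihood is non-decreasing across EM
#' iterations for every run. Components are reported sorted by ascending
#' mean, so component 1 is the small-area population P1.
#'
#' For `K = 1` the closed-form maximum-likelihood solution (sample mean,
#' 1/n-denominator standard deviation) is returned directly.
#'
#' @param values numeric sample (punctum areas, um^2).
#' @param K number of components (>= 1).
#' @param restarts number of EM starts (default 10).
#' @param seed integer seed controlling the restart jitter.
#' @param max_iter,tol EM stopping rule: at most `max_iter` iterations or
#'   relative log-likelihood change below `tol`.
#' @return An object of class `mixture_model`: list with `K`, `weights`,
#'   `means`, `sds`, `log_likelihood`, `ll_trace`, `n_iterations`,
#'   `converged`, `n`, `seed`.
#' @export
em_fit <- function(values, K, restarts = 10, seed = 1,
                   max_iter = 1000, tol = 1e-8) {
  x <- values[is.finite(values)]
  n <- length(x)
  K <- as.integer(K)
  if (K < 1L) stop("`K` must be >= 1", call. = FALSE)
  if (length(unique(x)) < 2L * K)
    stop("need at least 2K distinct values to fit ", K, " components",
         call. = FALSE)
  if (K == 1L) {
    mu <- mean(x)
    sd_ml <- sqrt(sum((x - mu)^2) / n)
    ll <- sum(dnorm(x, mu, sd_ml, log = TRUE))
    return(structure(
      list(K = 1L, weights = 1, means = mu, sds = sd_ml,
           log_likelihood = ll, ll_trace = ll, n_iterations = 0L,
           converged = TRUE, n = n, seed = as.integer(seed)),
      class = "mixture_model"))
  }
  var_floor <- 1e-6 * diff(range(x))^2
  ord <- order(x)
  xs <- x[ord]
  base_bounds <- round(seq(0, n, length.out = K + 1))
  runs <- with_local_seed(seed, {
    lapply(seq_len(restarts), function(r) {
      bounds <- base_bounds
      if (r > 1L) {
        jit <- round(runif(K - 1, -n / (4 * K), n / (4 * K)))
        bounds[2:K] <- pmin(pmax(base_bounds[2:K] + jit, 1), n - 1)
        bounds <- sort(bounds)
        # guarantee non-empty blocks
        for (k in 2:K) bounds[k] <- max(bounds[k], bounds[k - 1] + 1)
        bounds[K + 1] <- n
      }
      grp_sorted <- rep(seq_len(K), diff(bounds))
      grp <- integer(n)
      grp[ord] <- grp_sorted
      em_run(x, K, grp, max_iter, tol, var_floor)
    })
  })
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1),
                                 "log_likelihood"))]]
  o <- order(best$means)
  structure(
    list(K = K, weights = best$weights[o], means = best$means[o],
         sds = best$sds[o], log_likelihood = best$log_likelihood,
         ll_trace = best$ll_trace, n_iterations = best$n_iterations,
         converged = best$converged, n = n, seed = as.integer(seed)),
    class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, digits = 3, ...) {
  cat(sprintf("<mixture_model> K = %d, logLik = %.2f (n = %d)\n",
              x$K, x$log_likelihood, x$n))
  tab <- data.frame(component = seq_len(x$K),
                    weight = round(x$weights, digits),
                    mean = round(x$means, digits),
                    sd = round(x$sds, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Posterior classification of values under a fitted mixture
#'
#' Bayes-rule posterior membership probabilities
#' `r_k(x) = w_k f_k(x) / sum_j w_j f_j(x)` and their argmax hard labels.
#'
#' @param model a [em_fit()] result.
#' @param values numeric values to classify.
#' @return A list with `responsibilities` (n x K matrix) and `labels`
#'   (component indices, 1 = P1).
#' @export
classify_points <- function(model, values) {
  stopifnot(inherits(model, "mixture_model"))
  lp <- vapply(seq_len(model$K), function(k)
    log(model$weights[k]) +
      dnorm(values, model$means[k], model$sds[k], log = TRUE),
    numeric(length(values)))
  if (is.null(dim(lp))) lp <- matrix(lp, nrow = length(values))
  resp <- exp(lp - log_sum_exp_rows(lp))
  list(responsibilities = resp, labels = max.col(resp, ties.method = "first"))
}

#' Compare mixture sizes by information criteria
#'
#' Fits one mixture per candidate K and tabulates log-likelihood, AIC and
#' BIC (`df = 3K - 1` free parameters). The log-likelihood is
#' non-decreasing in K (models are nested); AIC/BIC penalize the extra
#' components.
#'
#' @param values numeric sample.
#' @param K_list integer vector of component counts to try.
#' @param restarts,seed passed to [em_fit()].
#' @return Data frame with columns `K`, `log_likelihood`, `df`, `AIC`,
#'   `BIC`.
#' @export
compare_components <- function(values, K_list = 1:3, restarts = 10,
                               seed = 1) {
  rows <- lapply(K_list, function(K) {
    m <- em_fit(values, K, restarts = restarts, seed = seed)
    df <- 3 * K - 1
    data.frame(K = K, log_likelihood = m$log_likelihood, df = df,
               AIC = 2 * df - 2 * m$log_likelihood,
               BIC = df * log(m$n) - 2 * m$log_likelihood)
  })
  do.call(rbind, rows)
}
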