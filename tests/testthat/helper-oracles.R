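# Independent oracles used to validate the package's own implementations.
# These deliberately use brute force / direct formula evaluation, never the
# code paths they check.

# Mixture log-likelihood evaluated directly from the density definition.
oracle_mix_loglik <- function(x, w, mu, s) {
  dens <- sapply(seq_along(w), function(k) w[k] * dnorm(x, mu[k], s[k]))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(rowSums(dens)))
}

# Dense grid search over two-component mixture parameters; returns the best
# log-likelihood found. Coarse by construction - EM must do at least this
# well (minus a small tolerance).
oracle_grid_gmm2 <- function(x) {
  rng <- range(x)
  mus <- seq(rng[1], rng[2], length.out = 12)
  sds <- diff(rng) * c(0.05, 0.1, 0.2, 0.35, 0.5)
  ws <- seq(0.1, 0.9, by = 0.2)
  best <- -Inf
  for (w in ws) for (m1 in mus) for (m2 in mus) {
    if (m2 < m1) next
    for (s1 in sds) for (s2 in sds) {
      ll <- oracle_mix_loglik(x, c(w, 1 - w), c(m1, m2), c(s1, s2))
      if (ll > best) best <- ll
    }
  }
  best
}

# Bayes responsibilities from first principles.
oracle_responsibility <- function(x, w, mu, s) {
  num <- sapply(seq_along(w), function(k) w[k] * dnorm(x, mu[k], s[k]))
  num / sum(num)
}

# Kruskal-Wallis H from the rank-sum definition (no tie correction; callers
# use tie-free data).
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  tapply(r, groups, sum) -> rs
  n <- tabulate(factor(groups))
  12 / (N * (N + 1)) * sum(rs^2 / n) - 3 * (N + 1)
}

# Exact permutation p-value of the Kruskal-Wallis H for small samples:
# enumerate all assignments of the pooled values to the group sizes.
oracle_kw_exact_p <- function(values, groups) {
  grp <- factor(groups)
  n <- tabulate(grp)
  N <- length(values)
  h_obs <- kruskal_wallis(values, groups)$H
  idx_all <- seq_len(N)
  count <- 0L
  total <- 0L
  pick <- function(remaining, sizes, labels) {
    if (length(sizes) == 1L) {
      lab <- labels
      lab[remaining] <- length(n)
      h <- kruskal_wallis(values, lab)$H
      total <<- total + 1L
      if (h >= h_obs - 1e-12) count <<- count + 1L
      return(invisible(NULL))
    }
    comb <- utils::combn(remaining, sizes[1])
    for (j in seq_len(ncol(comb))) {
      lab <- labels
      lab[comb[, j]] <- length(n) - length(sizes) + 1L
      pick(setdiff(remaining, comb[, j]), sizes[-1], lab)
    }
  }
  pick(idx_all, n, integer(N))
  count / total
}

# Rasterized disc mask for segmentation fixtures.
make_disc_image <- function(dims, centers, radii, fg = 10, bg = 0) {
  img <- matrix(bg, dims[1], dims[2])
  for (i in seq_along(radii)) {
    rr <- row(img); cc <- col(img)
    img[(rr - centers[[i]][1])^2 + (cc - centers[[i]][2])^2 <=
          radii[i]^2] <- fg
  }
  img
}
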