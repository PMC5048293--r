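# Small deterministic fixtures and independent oracles used across tests.

with_seed_rnorm <- function(seed, n) {
  set.seed(seed)
  rnorm(n)
}

# Build an expression matrix directly from a genes x samples matrix literal.
make_expr <- function(..., genes, samples) {
  m <- rbind(...)
  expression_matrix(m, gene_ids = genes, sample_ids = samples)
}

# Correlation profile literal (bypasses pearson_profile) for filter tests.
make_profile <- function(r, seed_gene, cohort = "c", n = 100L) {
  structure(list(r = r, n = n, seed_gene = seed_gene, cohort = cohort,
                 dropped = character()),
            class = "correlation_profile")
}

# Independent brute-force BH oracle: min over j >= i of m * p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent hypergeometric upper-tail oracle by direct enumeration.
fisher_oracle_greater <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Independent exact two-sided Spearman permutation oracle: recursive
# enumeration with cor() evaluated per permutation. Small n only.
spearman_perm_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- cor(rx, ry)
  enumerate <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (tail in enumerate(v[-i])) out[[length(out) + 1L]] <- c(v[i], tail)
    }
    out
  }
  rhos <- vapply(enumerate(seq_along(y)),
                 function(idx) cor(rx, ry[idx]), 0)
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# Independent Ward merge-height oracle: plain Lance-Williams recurrence on a
# dissimilarity matrix, nearest-pair agglomeration, returning sorted heights.
ward_heights_oracle <- function(d_mat) {
  n <- nrow(d_mat)
  size <- rep(1, n)
  active <- rep(TRUE, n)
  d <- d_mat
  diag(d) <- Inf
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    m <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- idx[min(m)]; j <- idx[max(m)]
    heights[step] <- d[i, j]
    # Lance-Williams update with Ward coefficients
    for (k in which(active)) {
      if (k == i || k == j) next
      ni <- size[i]; nj <- size[j]; nk <- size[k]
      d_new <- ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] -
                  nk * d[i, j]) / (ni + nj + nk)
      d[i, k] <- d[k, i] <- d_new
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    d[j, ] <- d[, j] <- Inf
  }
  sort(heights)
}

# Hand product-limit estimator for an uncensored/censored record set.
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}
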