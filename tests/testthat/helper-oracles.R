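# Independent brute-force oracles used to pin down the analytic
# implementations. Each oracle walks the definition step by step; none share
# code with the package internals they check.

# Recovery-curve AUC by explicit enumeration: R(j) counted at every step.
oracle_auc <- function(panel_ranks, n, top_fraction) {
  k <- ceiling(top_fraction * n)
  m <- length(panel_ranks)
  raw <- 0
  mx <- 0
  for (j in seq_len(k)) {
    raw <- raw + sum(panel_ranks <= j)
    mx <- mx + min(j, m)
  }
  raw / mx
}

# Tag-set KS statistic by an explicit loop over j.
oracle_ks_tag <- function(ranks, n) {
  v <- sort(ranks)
  t <- length(v)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  if (a > b) a else -b
}

oracle_ks_connectivity <- function(up_ranks, down_ranks, n) {
  ku <- oracle_ks_tag(up_ranks, n)
  kd <- oracle_ks_tag(down_ranks, n)
  if (sign(ku) == sign(kd)) 0 else (ku - kd) / 2
}

# Textbook pooled two-sample t-test, evaluated directly.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  t <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(abs(t), nx + ny - 2, lower.tail = FALSE))
}

# Running-sum enrichment by explicit stepping through the sorted list.
oracle_running_sum_es <- function(stat_sorted, hit_sorted, weight) {
  n <- length(stat_sorted)
  m <- sum(hit_sorted)
  wsum <- sum(abs(stat_sorted[hit_sorted])^weight)
  dev <- numeric(n)
  run <- 0
  for (i in seq_len(n)) {
    if (hit_sorted[i]) {
      run <- run + if (wsum > 0) abs(stat_sorted[i])^weight / wsum else 1 / m
    } else {
      run <- run - 1 / (n - m)
    }
    dev[i] <- run
  }
  dev[which.max(abs(dev))]
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# choose(nx+ny, nx) rank assignments.
oracle_ranksum_exact_p <- function(x, y) {
  all_vals <- c(x, y)
  n <- length(all_vals)
  r <- rank(all_vals)
  w_obs <- sum(r[seq_along(x)])
  combos <- utils::combn(n, length(x))
  w_null <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(w_null)
  min(1, 2 * min(mean(w_null <= w_obs), mean(w_null >= w_obs)))
}

# Small dense count matrix with dimnames, for ranking/scoring tests.
toy_counts <- function(n_genes = 20, n_cells = 10, seed = 1, lambda = 3) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes,
                dimnames = list(sprintf("Gene%04d", seq_len(n_genes)),
                                sprintf("cell%03d", seq_len(n_cells))))
  })
  m
}
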