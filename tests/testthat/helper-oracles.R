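# Independent brute-force oracles. These deliberately share no code with the
# package: direct pmf summation, full rank-assignment enumeration, and
# per-base interval scans.

# Exact two-sided binomial p: sum of P(X = j) over all j whose point
# probability is <= that of k (with the conventional relative fuzz).
oracle_binom_p <- function(k, n, p0 = 0.5) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all C(n1+n2, n1)
# assignments of the pooled ranks to group 1. Assumes no ties.
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- utils::combn(n1 + n2, n1)
  all_r <- rank(seq_len(n1 + n2))  # pooled ranks are 1..n
  w_null <- apply(picks, 2, function(i) sum(all_r[i])) - n1 * (n1 + 1) / 2
  if (w_obs > n1 * n2 / 2) {
    p1 <- mean(w_null >= w_obs)
  } else {
    p1 <- mean(w_null <= w_obs)
  }
  min(2 * p1, 1)
}

# Per-base overlap counts: how many features cover >= 1 bp of each window,
# checked base by base. Quadratic on purpose; only for genomes <= ~100 kb.
oracle_overlap_counts <- function(grid, features) {
  vapply(seq_len(nrow(grid)), function(i) {
    w_bases <- seq(grid$start[i], grid$end[i] - 1)
    hit <- 0L
    for (j in seq_len(nrow(features))) {
      if (features$chrom[j] != grid$chrom[i]) next
      f_bases <- seq(features$start[j], features$end[j] - 1)
      if (any(f_bases %in% w_bases)) hit <- hit + 1L
    }
    hit
  }, integer(1))
}

# Dense re-binning oracle: rebuild the upper-triangular matrix of unordered
# bin pairs at fine resolution and sum k x k blocks. Canonical records have
# start_a <= start_b, so the coarse result is upper-triangular too.
oracle_dense_rebin <- function(records, n_fine, resolution, window_size) {
  m <- matrix(0, n_fine, n_fine)
  for (i in seq_len(nrow(records))) {
    a <- records$start_a[i] / resolution + 1
    b <- records$start_b[i] / resolution + 1
    m[a, b] <- m[a, b] + records$frequency[i]
  }
  k <- window_size / resolution
  n_coarse <- ceiling(n_fine / k)
  out <- matrix(0, n_coarse, n_coarse)
  for (i in seq_len(n_fine)) {
    for (j in seq_len(n_fine)) {
      out[ceiling(i / k), ceiling(j / k)] <- out[ceiling(i / k), ceiling(j / k)] + m[i, j]
    }
  }
  out
}
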