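# Independent brute-force oracles used to pin expected values.

# Exact two-sided rank-sum p by full enumeration of all C(n, m) rank
# assignments (no ties assumed). Uses the symmetry of the U distribution.
enum_wilcoxon_p <- function(a, b) {
  ranks <- rank(c(a, b))
  m <- length(a); n <- length(b)
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  subsets <- utils::combn(m + n, m)
  all_ranks <- rank(c(a, b)) # identical; combined ranking is 1..(m+n) when no ties
  u_all <- apply(subsets, 2, function(idx) sum(seq_len(m + n)[idx]) - m * (m + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Upper-tail hypergeometric overlap p by enumerating every possible draw of
# |B| elements from the universe, with A fixed.
enum_hyper_p <- function(n_a, n_b, n_u, k_obs) {
  draws <- utils::combn(n_u, n_b)
  mean(apply(draws, 2, function(d) sum(d <= n_a)) >= k_obs)
}

# Two-sided Fisher p by enumerating all 2x2 tables with the observed margins.
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Globally optimal k-means within-cluster sum of squares by enumerating all
# assignments of n points to k non-empty clusters (n <= 8, k <= 3).
brute_kmeans_wss <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  assign_vec <- integer(n)
  rec <- function(i) {
    if (i > n) {
      if (length(unique(assign_vec)) < k) return()
      wss <- 0
      for (c in unique(assign_vec)) {
        pts <- x[assign_vec == c, , drop = FALSE]
        wss <- wss + sum(sweep(pts, 2, colMeans(pts))^2)
      }
      best <<- min(best, wss)
      return()
    }
    for (c in seq_len(k)) {
      assign_vec[i] <<- c
      rec(i + 1)
    }
  }
  rec(1)
  best
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
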