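# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Open-state probability at time t for one C <-> O -> I chain starting in
# C, from the matrix-exponential solution of the master equation.
master_eq_open_prob <- function(rate_co, rate_oc, rate_oi, rate_ic, times) {
  Q <- matrix(c(-rate_co,            rate_co,             0,
                rate_oc,  -(rate_oc + rate_oi),     rate_oi,
                rate_ic,                  0,        -rate_ic),
              nrow = 3, byrow = TRUE)
  p0 <- c(1, 0, 0)
  vapply(times, function(t)
    (p0 %*% as.matrix(Matrix::expm(Q * t)))[2], 0)
}

# Exhaustive piecewise-constant segmentation: dynamic programme over all
# split positions, minimizing RSS for each segment count, then the same
# Gaussian BIC stopping rule detect_steps uses. Only feasible for short
# traces.
dp_changepoints <- function(y) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  seg_rss <- function(i, j) {   # rss of y[i..j], 1-based inclusive
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  k_max <- min(n, 12L)
  # best[k][j]: min RSS of y[1..j] using k segments; trace back splits
  best <- matrix(Inf, nrow = k_max, ncol = n)
  back <- matrix(0L, nrow = k_max, ncol = n)
  for (j in 1:n) best[1, j] <- seg_rss(1, j)
  for (k in 2:k_max) {
    for (j in k:n) {
      cand <- vapply((k - 1):(j - 1), function(m)
        best[k - 1, m] + seg_rss(m + 1, j), 0)
      i <- which.min(cand)
      best[k, j] <- cand[i]
      back[k, j] <- ((k - 1):(j - 1))[i]
    }
  }
  bic <- n * log(pmax(best[, n], 1e-300) / n) +
    2 * seq_len(k_max) * log(n)
  # same sequential stopping rule as the greedy search: accept k + 1
  # segments only while the BIC keeps improving
  k_star <- 1L
  while (k_star < k_max && bic[k_star + 1] < bic[k_star]) {
    # also require an RSS gain, mirroring the greedy guard
    if (best[k_star + 1, n] >= best[k_star, n]) break
    k_star <- k_star + 1L
  }
  splits <- integer(0)
  j <- n
  k <- k_star
  while (k > 1) {
    m <- back[k, j]
    splits <- c(m, splits)
    j <- m
    k <- k - 1L
  }
  splits
}

# Zero-truncated binomial pmf by direct enumeration.
cond_binom_pmf <- function(k, n, p) {
  choose(n, k) * p^k * (1 - p)^(n - k) / (1 - (1 - p)^n)
}

# Coupled/uncoupled event classification computed straight from the
# simulator's noise-free ground-truth levels (majority-per-segment), an
# independent path from estimate_levels + idealize.
classify_from_truth <- function(ss, params = idealization_params()) {
  extract_events(ground_truth_labels(ss, params), params)
}
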