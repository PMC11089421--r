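# Shared fixtures and small oracles used across test files.

# adjusted Rand index between two labelings (closed-form pair counting)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# brute-force run-length dwell/occupancy oracle
brute_state_metrics <- function(labels, k, step_seconds) {
  runs <- rle(labels)
  dwell <- sapply(seq_len(k), function(s) {
    rl <- runs$lengths[runs$values == s]
    if (length(rl)) mean(rl) * step_seconds else NA_real_
  })
  occ <- sapply(seq_len(k), function(s) mean(labels == s))
  list(dwell = dwell, occupancy = occ)
}

# small stationary (single-state) cohort of component time courses
stationary_timecourses <- function(n = 5, tt = 295, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n * 2), n)
  cv <- tcrossprod(a) + diag(n)
  ch <- chol(cv)
  t(matrix(rnorm(tt * n), tt) %*% ch)
}

# well-separated Gaussian blobs in d dimensions
gaussian_blobs <- function(k, n_per, d = 5, sep = 8, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(j) {
    sweep(matrix(rnorm(n_per * d, sd = sd), n_per), 2, centers[j, ], "+")
  }))
  list(x = x, labels = rep(seq_len(k), each = n_per), centers = centers)
}
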