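test_that("the autoencoder reconstructs low-dimensional structure", {
  set.seed(31)
  n <- 600; d <- 20
  z <- matrix(rnorm(n * 5), n)
  x <- z %*% matrix(rnorm(5 * d), 5)   # exactly 5-dimensional subspace
  ae <- train_autoencoder(x, autoencoder_spec(encoder_units = c(32, 16, 8),
                                              epochs = 120, seed = 1))
  rec <- reconstruct_windows(ae, x)
  mse <- mean((rec - x)^2)
  expect_lt(mse, 0.05 * mean(apply(x, 2, var)))
  # no collapse: reconstruction variance within 2x of the input variance
  vr <- mean(apply(rec, 2, var)) / mean(apply(x, 2, var))
  expect_gt(vr, 0.5)
  expect_lt(vr, 2)
  expect_equal(ncol(ae$encoded), 8L)

  # capacity case: bottleneck >= input dimension makes identity achievable
  x5 <- z
  ae5 <- train_autoencoder(x5, autoencoder_spec(encoder_units = 6L,
                                                epochs = 200, seed = 2))
  mse5 <- mean((reconstruct_windows(ae5, x5) - x5)^2)
  expect_lt(mse5, 0.02 * mean(apply(x5, 2, var)))

  # reproducibility under a fixed seed
  ae_b <- train_autoencoder(x, autoencoder_spec(encoder_units = c(32, 16, 8),
                                                epochs = 120, seed = 1))
  expect_equal(ae$final_mse, ae_b$final_mse)
  expect_equal(ae$encoded, ae_b$encoded)
})

test_that("exemplars sit at strict local maxima of window variance", {
  # brute-force oracle on a prescribed variance series
  series <- c(1, 3, 2, 5, 4)
  base <- rnorm(12); base <- (base - mean(base)) / sd(base)
  m <- t(vapply(sqrt(series), function(a) a * base, numeric(12)))
  ex <- select_exemplars(list(list(windows = m)))
  expect_equal(ex$indices[[1]], c(2L, 4L))
  expect_false(ex$fallback[1])

  # monotone variance: no interior maxima, fallback triggers
  m2 <- t(vapply(sqrt(1:6), function(a) a * base, numeric(12)))
  ex2 <- select_exemplars(list(list(windows = m2)))
  expect_true(ex2$fallback[1])
  expect_gt(length(ex2$indices[[1]]), 0)

  # global row offsets across subjects
  ex3 <- select_exemplars(list(list(windows = m), list(windows = m)))
  expect_equal(ex3$global_rows, c(2L, 4L, 7L, 9L))
})

test_that("two-stage k-means recovers planted clusters", {
  blobs <- gaussian_blobs(4, 120, d = 6, sep = 6, seed = 41)
  sm <- cluster_states(blobs$x, 4, seed = 1, n_init = 32)
  expect_gt(ari(sm$assignments, blobs$labels), 0.95)

  # duplication invariance: doubling the data keeps the same centroids
  sm2 <- cluster_states(rbind(blobs$x, blobs$x), 4, seed = 1, n_init = 32)
  d <- as.matrix(dist(rbind(sm$centroids, sm2$centroids)))
  cross <- d[1:4, 5:8]
  perm <- match_components(-cross)
  expect_lt(max(cross[cbind(1:4, perm)]), 0.05)

  # degenerate single cluster: centroid is the data mean
  sm1 <- cluster_states(blobs$x, 1, seed = 1)
  expect_equal(as.numeric(sm1$centroids), colMeans(blobs$x))

  expect_error(cluster_states(blobs$x[1:3, ], 5, seed = 1), "exceeds")
})

test_that("the elbow criterion finds planted cluster counts", {
  blobs4 <- gaussian_blobs(4, 150, d = 6, sep = 6, seed = 51)
  e4 <- elbow_select_k(blobs4$x, k_range = 2:8, seed = 3, n_init = 16)
  expect_equal(e4$k, 4L)
  expect_true(e4$confident)

  blobs2 <- gaussian_blobs(2, 200, d = 6, sep = 6, seed = 52)
  e2 <- elbow_select_k(blobs2$x, k_range = 2:8, seed = 3, n_init = 16)
  expect_equal(e2$k, 2L)

  # a single Gaussian blob: smooth curve, selection flagged low-confidence
  set.seed(53)
  blob <- matrix(rnorm(600 * 6), 600)
  e1 <- elbow_select_k(blob, k_range = 2:8, seed = 3, n_init = 16)
  expect_false(e1$confident)

  expect_error(elbow_select_k(blobs4$x, k_range = 2:3, seed = 1), "3 candidate")
})

test_that("state metrics match the run-length oracle", {
  spec <- window_spec()
  lab <- c(1L, 1L, 1L, 2L, 2L, 1L, 1L)
  sm <- state_metrics(list(lab), spec, k = 2)
  expect_equal(unname(sm$dwell_time[1, 1]), 2.5 * 0.906)
  expect_equal(unname(sm$dwell_time[1, 2]), 2 * 0.906)
  expect_equal(sm$fractional_occupancy[1, ], c(5 / 7, 2 / 7),
               ignore_attr = TRUE)

  # constant labels: dwell equals total duration, occupancy 1
  sm2 <- state_metrics(list(rep(2L, 10)), spec, k = 2)
  expect_equal(unname(sm2$dwell_time[1, 2]), 10 * 0.906)
  expect_equal(unname(sm2$fractional_occupancy[1, 2]), 1)
  expect_true(is.na(sm2$dwell_time[1, 1]))
  expect_false(sm2$visited[1, 1])

  # alternating labels: one-window dwells, half occupancy each
  sm3 <- state_metrics(list(rep(c(1L, 2L), 10)), spec, k = 2)
  expect_equal(unname(sm3$dwell_time[1, ]), c(0.906, 0.906))
  expect_equal(unname(sm3$fractional_occupancy[1, ]), c(0.5, 0.5))

  # random labelings: agreement with the brute-force oracle, occupancies
  # sum to one, and metrics are label-permutation invariant
  set.seed(61)
  for (i in 1:5) {
    lab <- sample.int(3, 40, replace = TRUE)
    sm4 <- state_metrics(list(lab), spec, k = 3)
    oracle <- brute_state_metrics(lab, 3, spec$step_seconds)
    expect_equal(unname(sm4$dwell_time[1, ]), oracle$dwell)
    expect_equal(unname(sm4$fractional_occupancy[1, ]), oracle$occupancy)
    expect_equal(sum(sm4$fractional_occupancy), 1)
    perm <- c(3L, 1L, 2L)
    smp <- state_metrics(list(perm[lab]), spec, k = 3)
    expect_equal(unname(smp$dwell_time[1, perm]),
                 unname(sm4$dwell_time[1, ]))
  }
})

test_that("state FC matrices and matching reconstruct planted patterns", {
  set.seed(71)
  n_comp <- 5
  e <- n_comp * (n_comp - 1) / 2
  truth <- lapply(1:3, function(i) {
    a <- matrix(rnorm(n_comp * 2), n_comp)
    stats::cov2cor(tcrossprod(a) + diag(n_comp))
  })
  windows <- do.call(rbind, lapply(1:3, function(s) {
    t(replicate(50, truth[[s]][upper.tri(truth[[s]])] + rnorm(e, sd = 0.05)))
  }))
  model <- cluster_states(windows, 3, seed = 1, n_init = 16)
  mats <- state_fc_matrices(model, windows, n_comp)
  ms <- match_states(mats, truth)
  expect_true(all(ms$correlation > 0.95))
  expect_equal(sort(ms$matching), 1:3)
})
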