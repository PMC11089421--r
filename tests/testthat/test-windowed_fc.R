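test_that("the tapered window has the printed duration and exact symmetry", {
  spec <- window_spec()
  expect_equal(spec$length_seconds, 45.3)
  expect_equal(spec$sigma_seconds, 5.436)
  w <- make_taper(spec)
  expect_length(w, 50L)
  expect_equal(sum(w), 1)
  expect_equal(w, rev(w))
  expect_true(all(diff(w[1:25]) >= 0))   # unimodal rise to the centre

  # vanishing sigma: the taper degenerates to the uniform window
  w0 <- make_taper(window_spec(gaussian_sigma_tr = 1e-9))
  expect_equal(w0, rep(1 / 50, 50), tolerance = 1e-12)
  expect_error(window_spec(gaussian_sigma_tr = 0), "sigma")
})

test_that("graphical lasso at lambda zero equals the weighted empirical correlation", {
  tc <- stationary_timecourses(n = 5, tt = 295, seed = 3)
  spec <- window_spec()
  wfc0 <- sliding_window_fc(tc, spec, lambda_l1 = 0)
  # recompute first window by hand
  w <- make_taper(spec)
  seg <- t(tc)[1:50, ]
  mu <- colSums(seg * w)
  xc <- sweep(seg, 2, mu)
  cv <- crossprod(xc * sqrt(w)) / (1 - sum(w^2))
  z_hand <- atanh(stats::cov2cor(cv)[upper.tri(cv)])
  expect_equal(wfc0$windows[1, ], z_hand, tolerance = 1e-6)
  expect_equal(nrow(wfc0$windows), 246L)
})

test_that("regularization shrinks correlations monotonically toward zero", {
  set.seed(4)
  a <- matrix(rnorm(3 * 2), 3)
  cv <- tcrossprod(a) + diag(3)
  x <- t(matrix(rnorm(400 * 3), 400) %*% chol(cv))
  s <- cov(t(x))
  lambdas <- c(0.01, 0.05, 0.1, 0.3, 0.6, 1.5)
  mean_abs_r <- sapply(lambdas, function(l) {
    r <- stats::cov2cor(graphical_lasso(s, l)$w)
    mean(abs(r[upper.tri(r)]))
  })
  expect_true(all(diff(mean_abs_r) <= 1e-8))
  expect_lt(mean_abs_r[length(lambdas)], 1e-6)
  # precision sparsity at large lambda
  th <- graphical_lasso(s, 1.5)$theta
  expect_equal(max(abs(th[upper.tri(th)])), 0)
})

test_that("windowed FC of stationary data stays near the static estimate", {
  tc <- stationary_timecourses(n = 5, tt = 295, seed = 9)
  wfc <- sliding_window_fc(tc, window_spec(), lambda_l1 = 0.05)
  sfc <- static_fc(tc)
  z_static <- sfc$z_values[upper.tri(sfc$z_values)]
  diff_ <- abs(sweep(wfc$windows, 2, z_static))
  expect_lt(mean(diff_), 0.15)
})

test_that("cross-validated lambda tracks the sparsity of the truth", {
  spec <- window_spec()
  grid <- 10^seq(-2, 0, length.out = 10)
  # diagonal truth favours heavy regularization; dense strong correlations
  # favour light regularization (replicated over seeds: the likelihood
  # surface is nearly flat near its optimum)
  l_sparse <- vapply(1:5, function(i) {
    set.seed(i)
    as.numeric(select_lambda(matrix(rnorm(6 * 295), 6), spec, grid))
  }, numeric(1))
  l_dense <- vapply(1:5, function(i) {
    set.seed(100 + i)
    a <- matrix(rnorm(6 * 5, sd = 2), 6)
    cvd <- tcrossprod(a) + diag(6)
    tc <- t(matrix(rnorm(295 * 6), 295) %*% chol(cvd))
    as.numeric(select_lambda(tc, spec, grid))
  }, numeric(1))
  expect_gte(median(l_sparse), 0.05)
  expect_lte(max(l_dense), 0.08)
  expect_gt(median(l_sparse), 2 * median(l_dense))
  # single-element grid is returned unchanged
  set.seed(1)
  expect_equal(as.numeric(select_lambda(matrix(rnorm(6 * 295), 6), spec,
                                        0.3)), 0.3)
})

test_that("edge bookkeeping follows component permutations", {
  tc <- stationary_timecourses(n = 4, tt = 120, seed = 5)
  rownames(tc) <- paste0("c", 1:4)
  spec <- window_spec(length_tr = 30)
  w1 <- sliding_window_fc(tc, spec, 0.05, labels = rownames(tc))
  perm <- c(3, 1, 4, 2)
  w2 <- sliding_window_fc(tc[perm, ], spec, 0.05,
                          labels = rownames(tc)[perm])
  # map each permuted edge label back and compare feature columns
  canon <- function(lbl) {
    parts <- strsplit(lbl, "--", fixed = TRUE)
    vapply(parts, function(p) paste(sort(p), collapse = "--"), character(1))
  }
  m <- match(canon(w1$edge_labels), canon(w2$edge_labels))
  expect_false(anyNA(m))
  # equal up to graphical-lasso coordinate-order tolerance
  expect_equal(abs(w1$windows), abs(w2$windows[, m]), tolerance = 1e-4)
})
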