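test_that("subject PCA preserves variance and recovers planted factors", {
  set.seed(3)
  # rank-2 data: two components explain everything
  u <- matrix(rnorm(50 * 2), 50)
  v <- matrix(rnorm(40 * 2), 40)
  x <- tcrossprod(u, v)
  p2 <- subject_pca(x, 2L)
  expect_equal(p2$explained, 1.0, tolerance = 1e-10)

  # trace conservation on white noise
  w <- matrix(rnorm(60 * 30), 60)
  pw <- subject_pca(w, 10L)
  wc <- w - rowMeans(w)
  expect_equal(sum(pw$eigenvalues), sum(wc^2), tolerance = 1e-8)

  # planted 3-factor data + small noise: near-perfect reconstruction
  f3 <- matrix(rnorm(80 * 3), 80) %*% matrix(rnorm(3 * 100), 3)
  noisy <- f3 + matrix(rnorm(8000, sd = 0.05), 80)
  p3 <- subject_pca(noisy, 3L)
  rec <- p3$scores %*% t(p3$basis) + p3$center
  expect_gt(cor(as.vector(rec), as.vector(noisy)), 0.99)

  expect_error(subject_pca(x, 10L), "rank")
})

test_that("group PCA by EM matches the exact eigendecomposition", {
  set.seed(8)
  spcas <- lapply(1:3, function(i) {
    subject_pca(matrix(rnorm(80 * 30), 80) +
                  matrix(rnorm(80 * 2), 80) %*% matrix(rnorm(2 * 30), 2), 6L)
  })
  set.seed(10)
  em <- group_pca_concat(spcas, 4L, method = "em")
  ex <- group_pca_concat(spcas, 4L, method = "svd")
  # principal angles between the two 4-dim subspaces
  s <- svd(crossprod(em$basis, ex$basis))$d
  expect_lt(max(acos(pmin(s, 1))), 1e-3)

  # single subject: equals a further PCA of that subject (same subspace)
  one <- group_pca_concat(spcas[1], 3L, method = "svd")
  sv <- svd(sweep(spcas[[1]]$scores, 2, colMeans(spcas[[1]]$scores)))
  s1 <- svd(crossprod(one$basis, sv$v[, 1:3]))$d
  expect_lt(max(acos(pmin(s1, 1))), 1e-6)

  # duplicating a subject leaves the spanned subspace unchanged
  dup <- group_pca_concat(spcas[c(1, 1)], 3L, method = "svd")
  s2 <- svd(crossprod(dup$basis[1:6, ] + dup$basis[7:12, ], one$basis))$d
  expect_lt(max(acos(pmin(s2 / max(s2), 1))), 1e-6)

  expect_error(group_pca_concat(list(spcas[[1]],
                                     subject_pca(matrix(rnorm(60 * 30), 60),
                                                 6L)), 4L),
               "voxel dimensions")
})

test_that("infomax recovers planted super-Gaussian sources", {
  # sparse blob sources are super-Gaussian
  n_src <- 3; v <- 300
  maps <- matrix(0, n_src, v)
  for (s in 1:n_src) maps[s, ((s - 1) * 100 + 1):((s - 1) * 100 + 70)] <-
      sin(pi * (1:70) / 71)
  set.seed(2)
  mix <- matrix(rnorm(5 * n_src), 5)
  x <- t(mix %*% maps) + matrix(rnorm(v * 5, sd = 0.02), v)
  fit <- infomax_ica(x, n_src, seed = 4)
  expect_true(fit$converged)
  cc <- abs(cor(t(fit$sources), t(maps)))
  perm <- match_components(t(cc))
  expect_true(all(cc[cbind(perm, 1:n_src)] > 0.95))
  # unit variance and positive skewness conventions
  expect_equal(apply(fit$sources, 1, sd), rep(1, n_src), tolerance = 1e-6)
  expect_true(all(apply(fit$sources, 1,
                        function(z) mean((z - mean(z))^3)) >= 0))

  # orthogonal mixing of 2 sources: unmixing %*% mixing = signed permutation
  maps2 <- maps[1:2, ]
  q <- qr.Q(qr(matrix(rnorm(4), 2)))
  x2 <- t(q %*% maps2)
  fit2 <- infomax_ica(x2, 2L, seed = 1)
  wa <- fit2$unmixing %*% fit2$mixing
  off <- max(abs(wa - diag(diag(wa))))
  expect_lt(off, 0.05)
  expect_equal(abs(diag(wa)), c(1, 1), tolerance = 0.05)

  # single component equals the first principal direction up to sign/scale
  fit1 <- infomax_ica(x, 1L, seed = 1)
  pc1 <- prcomp(x)$x[, 1]
  expect_gt(abs(cor(fit1$sources[1, ], pc1)), 0.999)
})

test_that("ICASSO stability separates reproducible components from noise", {
  n_src <- 4; v <- 400
  maps <- matrix(0, n_src, v)
  for (s in 1:n_src) maps[s, ((s - 1) * 100 + 1):((s - 1) * 100 + 80)] <-
      sin(pi * (1:80) / 81)
  set.seed(6)
  mix <- matrix(rnorm(6 * n_src), 6)
  x <- t(mix %*% maps) + matrix(rnorm(v * 6, sd = 0.02), v)
  gica <- icasso_stability(x, n_src, n_runs = 6, seed = 30)
  # clean, identifiable model: all components reproducible across runs
  expect_true(all(gica$stability_iq > 0.95))
  expect_true(all(gica$retained == (gica$stability_iq > 0.8)))
  cc <- abs(cor(t(gica$group_maps), t(maps)))
  perm <- match_components(t(cc))
  expect_true(all(cc[cbind(perm, 1:n_src)] > 0.9))

  # run-order permutation invariance of I_q (same runs, different base seed
  # order produces the same clustered stability profile)
  gica2 <- icasso_stability(x, n_src, n_runs = 6, seed = 30)
  expect_equal(gica$stability_iq, gica2$stability_iq)

  expect_error(icasso_stability(x, n_src, n_runs = 1), "at least 2")
})

test_that("back-reconstruction returns subject maps and time courses", {
  set.seed(12)
  n_src <- 3; v <- 240; tt <- 100
  maps <- matrix(0, n_src, v)
  for (s in 1:n_src) maps[s, ((s - 1) * 80 + 1):((s - 1) * 80 + 60)] <-
      sin(pi * (1:60) / 61)
  courses <- lapply(1:3, function(i) matrix(rnorm(n_src * tt), n_src))
  subjects <- lapply(1:3, function(i) {
    subject_timeseries(crossprod(maps, courses[[i]]) +
                         matrix(rnorm(v * tt, sd = 0.01), v), 0.906,
                       sprintf("s%d", i))
  })
  spcas <- lapply(subjects, subject_pca, n_components = 10L)
  gp <- group_pca_concat(spcas, 6L, method = "svd")
  gica <- icasso_stability(gp, n_src, n_runs = 4, seed = 2)
  br <- back_reconstruct(gica, 1L, components = seq_len(n_src))
  expect_equal(dim(br$timecourses), c(tt, n_src))
  # each reconstructed course matches a planted one
  cc <- abs(cor(br$timecourses, t(courses[[1]])))
  perm <- match_components(t(cc))
  expect_true(all(cc[cbind(perm, 1:n_src)] > 0.95))
  # subject maps match planted spatial sources
  cm <- abs(cor(t(br$maps), t(maps)))
  permm <- match_components(t(cm))
  expect_true(all(cm[cbind(permm, 1:n_src)] > 0.9))

  # zero-variance subject is an error, not silent zeros
  zero_sub <- subject_timeseries(matrix(0, v, tt) + 1, 0.906, "z")
  spz <- spcas
  spz[[1]]$scores <- spz[[1]]$scores * 0
  gpz <- gp; gpz$subject_pcas <- spz
  gicaz <- gica; gicaz$group_pca <- gpz
  expect_error(back_reconstruct(gicaz, 1L, components = seq_len(n_src)),
               "zero-variance")
})

test_that("spectral metrics separate low- and high-frequency components", {
  tr <- 0.906
  tt <- 295
  t_s <- (seq_len(tt) - 1) * tr
  set.seed(5)
  slow <- sin(2 * pi * 0.05 * t_s) + rnorm(tt, sd = 0.01)
  fast <- sin(2 * pi * 0.20 * t_s) + rnorm(tt, sd = 0.01)
  m_slow <- spectral_icn_metrics(slow, tr)
  m_fast <- spectral_icn_metrics(fast, tr)
  expect_gt(m_slow$power_ratio, 10)
  expect_lt(m_fast$power_ratio, 0.5)
  expect_gt(m_slow$dynamic_range, 0)

  # white noise: flat spectrum, ratio near the bandwidth ratio 0.10/0.10 = 1
  ratios <- sapply(1:8, function(i) {
    spectral_icn_metrics(rnorm(2048), tr)$power_ratio
  })
  expect_gt(mean(ratios), 0.5)
  expect_lt(mean(ratios), 2)

  expect_error(spectral_icn_metrics(rnorm(295), tr_seconds = 3),
               "Nyquist")
  expect_error(spectral_icn_metrics(rnorm(40), tr), "64")
})

test_that("ICN selection combines spectral criteria, masks and overrides", {
  metrics <- data.frame(power_ratio = c(10, 0.5, 5, 8),
                        dynamic_range = c(1, 1, 1, 1))
  maps <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 0, 1))
  gm <- c(TRUE, TRUE, FALSE, FALSE)
  sel <- select_icns(metrics, maps = maps, grey_matter_mask = gm,
                     min_grey_overlap = 0.6, exclude = 4)
  expect_equal(sel$is_icn, c(TRUE, FALSE, FALSE, FALSE))
  sel2 <- select_icns(metrics, include = 2)
  expect_true(sel2$is_icn[2])
})
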