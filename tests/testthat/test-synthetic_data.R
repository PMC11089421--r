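test_that("state sequences follow the requested Markov chain", {
  # absorbing chain: identity transitions never leave the start state
  seq1 <- generate_state_sequence(diag(3), 50, seed = 7)
  expect_length(unique(seq1), 1L)

  # single state
  seq2 <- generate_state_sequence(matrix(1, 1, 1), 20, seed = 1)
  expect_true(all(seq2 == 1L))

  # geometric run-length oracle: mean run length 1/(1 - stay)
  tm <- matrix(0.05 / 3, 4, 4); diag(tm) <- 0.95
  lab <- generate_state_sequence(tm, 10000, seed = 42)
  expect_true(all(lab %in% 1:4))
  mean_run <- mean(rle(lab)$lengths)
  expect_lt(abs(mean_run - 20) / 20, 0.1)

  # non-stochastic rows rejected with the row named
  bad <- diag(3); bad[2, 2] <- 0.7
  expect_error(generate_state_sequence(bad, 10), "row 2")
})

test_that("cohort generation is deterministic and shape-correct", {
  cfg <- synthetic_config(n_subjects_per_group = 2L, n_voxels = 60L,
                          n_sources = 4L, n_timepoints = 80L, seed = 5L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects[[1]]$data, b$subjects[[1]]$data)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$ground_truth$state_sequences,
                   b$ground_truth$state_sequences)

  d <- generate_cohort(synthetic_config(n_subjects_per_group = 1L, seed = 1L))
  expect_equal(dim(d$subjects[[1]]$data), c(500L, 295L))
  expect_equal(dim(d$subjects[[1]]$motion), c(295L, 6L))
})

test_that("true occupancies equal run-length-weighted label frequencies", {
  cfg <- synthetic_config(n_subjects_per_group = 2L, n_voxels = 40L,
                          n_sources = 4L, n_timepoints = 120L, seed = 3L)
  coh <- generate_cohort(cfg)
  gt <- coh$ground_truth
  for (id in names(gt$state_sequences)) {
    lab <- gt$state_sequences[[id]]
    expect_equal(gt$true_occupancy[id, ],
                 tabulate(lab, 4) / length(lab),
                 ignore_attr = TRUE)
    expect_equal(sum(gt$true_occupancy[id, ]), 1)
  }
})

test_that("noiseless single-state sources reproduce the requested covariance", {
  cfg <- synthetic_config(n_subjects_per_group = 1L, n_sources = 5L,
                          n_voxels = 20L, n_states = 1L, noise_sd = 0,
                          state_covariances = list(diag(5)), seed = 9L)
  coh <- generate_cohort(cfg)
  sc <- cov(t(coh$subjects[[1]]$sources))
  expect_lt(max(abs(sc[upper.tri(sc)])), 0.1)
  expect_lt(max(abs(diag(sc) - 1)), 0.3)
})

test_that("group effect zero leaves both groups with one generative model", {
  cfg <- synthetic_config(n_subjects_per_group = 2L, n_voxels = 40L,
                          n_sources = 4L, n_timepoints = 60L,
                          group_effect = 0, seed = 2L)
  coh <- generate_cohort(cfg)
  expect_identical(coh$ground_truth$state_covariances,
                   coh$ground_truth$state_covariances_case)
})

test_that("non-positive-definite requested covariances are rejected", {
  bad <- diag(3); bad[1, 1] <- -1
  expect_error(
    synthetic_config(n_sources = 3L, n_states = 1L,
                     state_covariances = list(bad)),
    "positive definite")
})

test_that("windowed correlations within a state match that state's correlations", {
  # planted-state recoverability: long dwell, low noise
  cv <- list(diag(4), {
    m <- diag(4); m[1, 2] <- m[2, 1] <- 0.7; m[3, 4] <- m[4, 3] <- -0.5; m
  })
  cfg <- synthetic_config(n_subjects_per_group = 1L, n_sources = 4L,
                          n_voxels = 16L, n_timepoints = 800L, n_states = 2L,
                          stay_probability = 0.995, noise_sd = 0.01,
                          state_covariances = cv, seed = 21L)
  coh <- generate_cohort(cfg)
  lab <- coh$ground_truth$state_sequences[[1]]
  src <- coh$subjects[[1]]$sources
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  long <- which(runs$lengths >= 150)
  expect_gt(length(long), 0)
  for (i in long) {
    seg <- src[, starts[i]:ends[i]]
    r <- cor(t(seg))
    truth <- stats::cov2cor(cv[[runs$values[i]]])
    expect_lt(mean(abs(r - truth)[upper.tri(r)]), 0.1)
  }
})

test_that("cohorts round-trip through the plain-text writer", {
  cfg <- synthetic_config(n_subjects_per_group = 1L, n_sources = 3L,
                          n_voxels = 12L, n_timepoints = 60L, seed = 4L)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort_dir(dir, tr_seconds = cfg$tr_seconds)
  expect_equal(back$subjects[[1]]$data, coh$subjects[[1]]$data,
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(back$cohort$group, coh$cohort$group)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
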