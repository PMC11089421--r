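#' Configuration for a synthetic resting-state cohort
#'
#' Defines the generative model for a two-group cohort of BOLD-like
#' recordings: `n_sources` spatially independent sources mix into
#' `n_voxels` observed channels; source activity is drawn per timepoint
#' from the covariance of the currently active connectivity state, and the
#' active state follows a first-order Markov chain with the given
#' self-transition (stay) probability, so dwell times are geometric.
#' Head-motion traces (3 rotations in radians, 3 translations in mm) are a
#' smooth random walk with occasional spikes so that quality-control
#' exclusions can be exercised.
#'
#' @param n_subjects_per_group subjects per group (cases / controls).
#' @param n_sources number of spatial sources (emulated intrinsic networks).
#' @param n_voxels observed channels per subject.
#' @param n_timepoints volumes per subject.
#' @param tr_seconds repetition time in seconds.
#' @param n_states number of planted connectivity states.
#' @param stay_probability Markov self-transition probability in (0, 1).
#' @param noise_sd standard deviation of additive Gaussian observation noise.
#' @param motion_spike_rate per-frame probability of a motion spike in [0, 1].
#' @param group_effect additive shift applied to the off-diagonal covariance
#'   of every state for the case group (0 = identical groups).
#' @param state_covariances optional list of `n_states` explicit
#'   source-by-source covariance matrices (symmetric positive definite);
#'   `NULL` (default) draws random low-rank-plus-diagonal states.
#' @param seed integer seed; identical config + seed gives identical cohorts.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects_per_group = 10L,
                             n_sources = 10L,
                             n_voxels = 500L,
                             n_timepoints = 295L,
                             tr_seconds = 0.906,
                             n_states = 4L,
                             stay_probability = 0.95,
                             noise_sd = 0.5,
                             motion_spike_rate = 0.01,
                             group_effect = 0,
                             state_covariances = NULL,
                             seed = 1L) {
  stopifnot(n_subjects_per_group >= 1L, n_sources >= 1L, n_voxels >= n_sources,
            n_timepoints >= 1L, tr_seconds > 0, n_states >= 1L,
            stay_probability > 0, stay_probability < 1,
            noise_sd >= 0, motion_spike_rate >= 0, motion_spike_rate <= 1)
  if (!is.null(state_covariances)) {
    if (length(state_covariances) != n_states) {
      stop("state_covariances must contain one matrix per state")
    }
    for (cv in state_covariances) {
      cv <- as.matrix(cv)
      if (nrow(cv) != n_sources || ncol(cv) != n_sources ||
          max(abs(cv - t(cv))) > 1e-8) {
        stop("each state covariance must be a symmetric n_sources matrix")
      }
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) {
        stop("requested state covariance is not positive definite")
      }
    }
  }
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_sources = as.integer(n_sources),
                 n_voxels = as.integer(n_voxels),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 n_states = as.integer(n_states),
                 stay_probability = stay_probability,
                 noise_sd = noise_sd,
                 motion_spike_rate = motion_spike_rate,
                 group_effect = group_effect,
                 state_covariances = state_covariances,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Sample a hidden Markov state sequence
#'
#' @param transition_matrix square row-stochastic matrix; entry (i, j) is the
#'   probability of moving from state i to state j.
#' @param n_timepoints sequence length.
#' @param seed integer seed (optional; if `NULL` the current RNG stream is
#'   used).
#' @param init optional initial state (default: uniform draw).
#' @return integer vector of labels in `1..nrow(transition_matrix)`.
#' @export
generate_state_sequence <- function(transition_matrix, n_timepoints,
                                    seed = NULL, init = NULL) {
  tm <- as.matrix(transition_matrix)
  if (nrow(tm) != ncol(tm)) stop("transition matrix must be square")
  if (any(tm < 0)) stop("transition probabilities must be non-negative")
  rs <- rowSums(tm)
  bad <- which(abs(rs - 1) > 1e-8)
  if (length(bad)) {
    stop(sprintf("transition matrix row %d does not sum to 1 (sum = %.6f)",
                 bad[1L], rs[bad[1L]]))
  }
  if (n_timepoints < 1L) stop("n_timepoints must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(tm)
  labels <- integer(n_timepoints)
  labels[1L] <- if (is.null(init)) sample.int(k, 1L) else as.integer(init)
  if (n_timepoints > 1L) {
    for (t in 2L:n_timepoints) {
      labels[t] <- sample.int(k, 1L, prob = tm[labels[t - 1L], ])
    }
  }
  labels
}

# uniform-stay transition matrix used by the default generator
.stay_transition_matrix <- function(n_states, stay_probability) {
  if (n_states == 1L) return(matrix(1, 1L, 1L))
  off <- (1 - stay_probability) / (n_states - 1L)
  tm <- matrix(off, n_states, n_states)
  diag(tm) <- stay_probability
  tm
}

# random SPD state covariances: low-rank factors plus diagonal loading
.make_state_covariances <- function(n_states, n_sources, rank = 2L,
                                    factor_scale = 1.3) {
  lapply(seq_len(n_states), function(s) {
    a <- matrix(rnorm(n_sources * rank, sd = factor_scale), n_sources, rank)
    cov <- tcrossprod(a) + diag(n_sources)
    cov
  })
}

# sparse blob-like source maps: each source loads on its own voxel block
# with a smooth half-cosine profile (super-Gaussian marginals, as needed
# for infomax recovery)
.make_source_maps <- function(n_sources, n_voxels) {
  maps <- matrix(0, n_sources, n_voxels)
  block <- floor(n_voxels / n_sources)
  for (s in seq_len(n_sources)) {
    start <- (s - 1L) * block + 1L
    width <- max(4L, floor(block * 0.8))
    idx <- start:min(start + width - 1L, n_voxels)
    profile <- sin(pi * seq_along(idx) / (length(idx) + 1))
    maps[s, idx] <- profile
  }
  maps
}

.make_motion_trace <- function(n_timepoints, spike_rate) {
  # smooth random walk (mm / radians) plus occasional large spikes
  walk <- function(sd_step) cumsum(rnorm(n_timepoints, sd = sd_step))
  trans <- vapply(1:3, function(i) walk(0.02), numeric(n_timepoints))
  rot <- vapply(1:3, function(i) walk(4e-4), numeric(n_timepoints))
  spikes <- which(runif(n_timepoints) < spike_rate)
  for (t in spikes) {
    trans[t, ] <- trans[t, ] + rnorm(3, sd = 1.5)
    rot[t, ] <- rot[t, ] + rnorm(3, sd = 0.01)
  }
  cbind(rot, trans)  # 6 columns: rotations first, then translations
}

#' Generate a synthetic two-group cohort with planted connectivity states
#'
#' Each subject's observed matrix is `t(source_maps) %*% sources + noise`
#' where the source vector at time t is drawn from the covariance of the
#' state active at t.  Ground truth (maps, state covariances, sequences,
#' occupancies, motion) is returned alongside the data.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_cohort` with elements
#'   `subjects` (list of subject records: `data` voxels x time, `sources`
#'   sources x time, `motion` T x 6, `subject_id`, `group`, `tr_seconds`),
#'   `ground_truth` (source maps, state covariances/correlations, per-subject
#'   state sequences and occupancies) and `cohort` (data frame: subject_id,
#'   group, age, sex, deprivation_decile).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  k <- config$n_states
  tm <- .stay_transition_matrix(k, config$stay_probability)
  covs_control <- if (is.null(config$state_covariances)) {
    .make_state_covariances(k, config$n_sources)
  } else {
    lapply(config$state_covariances, as.matrix)
  }
  covs_case <- lapply(covs_control, function(cv) {
    shift <- matrix(config$group_effect, nrow(cv), ncol(cv))
    diag(shift) <- 0
    cv + shift
  })
  for (cv in c(covs_control, covs_case)) {
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("requested state covariance is not positive definite")
  }
  maps <- .make_source_maps(config$n_sources, config$n_voxels)

  n_total <- 2L * config$n_subjects_per_group
  groups <- rep(c("case", "control"), each = config$n_subjects_per_group)
  ids <- sprintf("sub-%02d", seq_len(n_total))
  chol_control <- lapply(covs_control, chol)
  chol_case <- lapply(covs_case, chol)

  subjects <- vector("list", n_total)
  sequences <- vector("list", n_total)
  occupancy <- matrix(0, n_total, k, dimnames = list(ids, paste0("state", 1:k)))
  motion <- vector("list", n_total)

  for (i in seq_len(n_total)) {
    labels <- generate_state_sequence(tm, config$n_timepoints)
    sequences[[i]] <- labels
    occupancy[i, ] <- tabulate(labels, nbins = k) / config$n_timepoints
    ch <- if (groups[i] == "case") chol_case else chol_control
    src <- matrix(0, config$n_sources, config$n_timepoints)
    for (s in seq_len(k)) {
      tt <- which(labels == s)
      if (length(tt)) {
        z <- matrix(rnorm(length(tt) * config$n_sources), length(tt))
        src[, tt] <- t(z %*% ch[[s]])
      }
    }
    noise <- matrix(rnorm(config$n_voxels * config$n_timepoints,
                          sd = config$noise_sd),
                    config$n_voxels, config$n_timepoints)
    data <- crossprod(maps, src) + noise
    motion[[i]] <- .make_motion_trace(config$n_timepoints,
                                      config$motion_spike_rate)
    subjects[[i]] <- list(subject_id = ids[i], group = groups[i],
                          data = data, sources = src,
                          motion = motion[[i]],
                          tr_seconds = config$tr_seconds)
  }

  cohort <- data.frame(
    subject_id = ids,
    group = groups,
    age = round(runif(n_total, 6.5, 8.0), 2),
    sex = sample(c(0L, 1L), n_total, replace = TRUE),
    deprivation_decile = sample.int(10L, n_total, replace = TRUE),
    stringsAsFactors = FALSE
  )

  ground_truth <- list(
    source_maps = maps,
    transition_matrix = tm,
    state_covariances = covs_control,
    state_covariances_case = covs_case,
    state_correlations = lapply(covs_control, stats::cov2cor),
    state_sequences = setNames(sequences, ids),
    true_occupancy = occupancy
  )

  structure(list(subjects = subjects, ground_truth = ground_truth,
                 cohort = cohort, config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk in plain-text formats
#'
#' Writes per-subject voxel-by-time TSVs, 6-column whitespace-delimited
#' motion files (rotations in radians then translations in mm), the cohort
#' table, and a ground-truth bundle (JSON summary plus TSV matrices).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in cohort$subjects) {
    write.table(sub$data, file.path(dir, paste0(sub$subject_id, "_bold.tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE)
    write.table(format(sub$motion, digits = 8),
                file.path(dir, paste0(sub$subject_id, "_motion.par")),
                sep = "  ", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  write.table(cohort$cohort, file.path(dir, "cohort.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  gt <- cohort$ground_truth
  write.table(gt$source_maps, file.path(dir, "truth_source_maps.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  for (s in seq_along(gt$state_covariances)) {
    write.table(gt$state_covariances[[s]],
                file.path(dir, sprintf("truth_state_cov_%d.tsv", s)),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(config = unclass(cohort$config),
         state_sequences = gt$state_sequences,
         true_occupancy = as.data.frame(gt$true_occupancy)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
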