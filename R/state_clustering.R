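#' Autoencoder specification
#'
#' Fully connected autoencoder: `encoder_units` hidden layers ending in the
#' bottleneck, mirrored by a symmetric decoder.  ReLU activations on hidden
#' layers; linear activations on the bottleneck and the output.  Trained
#' with Adam on mean squared reconstruction error.
#'
#' @param encoder_units units per encoding layer, last = bottleneck
#'   (default `c(512, 256, 32)`).
#' @param epochs training epochs (default 200).
#' @param batch_size minibatch size (default 50).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed RNG seed for weight init and batch shuffling.
#' @return object of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(encoder_units = c(512L, 256L, 32L),
                             epochs = 200L, batch_size = 50L,
                             learning_rate = 1e-3, seed = 1L) {
  stopifnot(length(encoder_units) >= 1L, all(encoder_units >= 1L),
            epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(encoder_units = as.integer(encoder_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "autoencoder_spec")
}

# He-style initial weights for one layer
.init_layer <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

#' Train an autoencoder on pooled connectivity windows
#'
#' Features are standardized per edge (z-score across all windows) before
#' training; the returned encoder includes the standardization so that
#' [encode_windows()] can be applied to raw feature matrices.
#'
#' @param x windows x features matrix (pooled across subjects).
#' @param spec an [autoencoder_spec()]; the bottleneck must be narrower
#'   than the feature dimension.
#' @param standardize standardize features before training (default TRUE).
#' @return list of class `autoencoder`: `weights`, `biases`,
#'   `encoder_layers` (count), `final_mse`, `center`, `scale`, `spec`,
#'   `encoded` (training data in bottleneck space).
#' @export
train_autoencoder <- function(x, spec = autoencoder_spec(),
                              standardize = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  e <- ncol(x)
  stopifnot(inherits(spec, "autoencoder_spec"))
  if (n < spec$batch_size) stop("fewer windows than one batch")
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, e)
    scl <- rep(1, e)
  }
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")

  sizes <- c(e, spec$encoder_units, rev(spec$encoder_units)[-1L], e)
  n_layers <- length(sizes) - 1L
  n_enc <- length(spec$encoder_units)

  set.seed(spec$seed)
  w0 <- lapply(seq_len(n_layers), function(l) .init_layer(sizes[l], sizes[l + 1L]))
  b0 <- lapply(seq_len(n_layers), function(l) numeric(sizes[l + 1L]))
  batch_order <- t(vapply(seq_len(spec$epochs),
                          function(ep) sample.int(n) - 1L,
                          integer(n)))
  fit <- .mlp_ae_train_cpp(xs, w0, b0, batch_order, spec$batch_size,
                           c(n_enc, n_layers), lr = spec$learning_rate)
  ae <- structure(list(weights = fit$weights, biases = fit$biases,
                       encoder_layers = n_enc, final_mse = fit$final_mse,
                       center = ctr, scale = scl, spec = spec),
                  class = "autoencoder")
  ae$encoded <- encode_windows(ae, x)
  ae
}

#' Encode feature vectors to the autoencoder bottleneck
#'
#' @param ae a trained [train_autoencoder()] result.
#' @param x windows x features matrix on the original feature scale.
#' @return windows x bottleneck matrix.
#' @export
encode_windows <- function(ae, x) {
  stopifnot(inherits(ae, "autoencoder"))
  a <- sweep(sweep(as.matrix(x), 2L, ae$center), 2L, ae$scale, "/")
  for (l in seq_len(ae$encoder_layers)) {
    a <- a %*% ae$weights[[l]]
    a <- sweep(a, 2L, ae$biases[[l]], "+")
    if (l < ae$encoder_layers) a[a < 0] <- 0   # bottleneck itself is linear
  }
  a
}

#' Reconstruct features through the full autoencoder
#'
#' @param ae a trained autoencoder.
#' @param x windows x features matrix on the original feature scale.
#' @return reconstruction on the original feature scale.
#' @export
reconstruct_windows <- function(ae, x) {
  stopifnot(inherits(ae, "autoencoder"))
  a <- sweep(sweep(as.matrix(x), 2L, ae$center), 2L, ae$scale, "/")
  n_layers <- length(ae$weights)
  for (l in seq_len(n_layers)) {
    a <- a %*% ae$weights[[l]]
    a <- sweep(a, 2L, ae$biases[[l]], "+")
    if (l != ae$encoder_layers && l != n_layers) a[a < 0] <- 0
  }
  sweep(sweep(a, 2L, ae$scale, "*"), 2L, ae$center, "+")
}

#' Select exemplar windows at local maxima of feature variance
#'
#' For each subject the variance across edge features is computed per
#' window; windows at strict local maxima of that series are exemplars.
#' A constant variance series triggers an evenly-spaced fallback.
#'
#' @param wfc_list list of [sliding_window_fc()] results (one per subject).
#' @return list: `indices` (per subject, exemplar window positions),
#'   `global_rows` (rows into the pooled window matrix), `fallback`
#'   (logical per subject).
#' @export
select_exemplars <- function(wfc_list) {
  if (inherits(wfc_list, "windowed_fc")) wfc_list <- list(wfc_list)
  offsets <- c(0L, cumsum(vapply(wfc_list, function(w) nrow(w$windows),
                                 integer(1))))
  idx <- vector("list", length(wfc_list))
  fallback <- logical(length(wfc_list))
  for (i in seq_along(wfc_list)) {
    z <- wfc_list[[i]]$windows
    nw <- nrow(z)
    if (nw < 3L) stop("need at least 3 windows per subject")
    v <- apply(z, 1L, var)
    interior <- 2L:(nw - 1L)
    is_max <- v[interior] > v[interior - 1L] & v[interior] > v[interior + 1L]
    found <- interior[is_max]
    if (!length(found)) {
      fallback[i] <- TRUE
      found <- unique(round(seq(1L, nw, length.out = min(10L, nw))))
    }
    idx[[i]] <- found
  }
  global_rows <- unlist(Map(function(ix, off) ix + off, idx,
                            offsets[seq_along(idx)]))
  list(indices = idx, global_rows = global_rows, fallback = fallback)
}

# k-means++ seeding on rows of x
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in 2L:k) {
    probs <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

.kmeans_sse <- function(x, centers) {
  d2 <- vapply(seq_len(nrow(centers)), function(j) {
    rowSums(sweep(x, 2L, centers[j, ])^2)
  }, numeric(nrow(x)))
  sum(apply(d2, 1L, min))
}

#' Two-stage exemplar-initialized k-means clustering of encoded windows
#'
#' Stage 1: 128 repetitions of k-means (Lloyd, max 1000 iterations), each
#' seeded by k-means++, on the exemplar windows; the centroid set with the
#' lowest sum of squared errors wins.  Stage 2: those centroids initialize
#' a final k-means over all windows (max 10000 iterations).
#'
#' @param encoded windows x bottleneck matrix (all windows, pooled).
#' @param k number of states (>= 2, and >= 1 only for diagnostics).
#' @param exemplar_rows row indices of exemplar windows (from
#'   [select_exemplars()]); default all rows.
#' @param seed RNG seed.
#' @param n_init stage-1 repetitions (default 128).
#' @return list of class `state_model`: `k`, `centroids` (k x bottleneck),
#'   `assignments` (per window), `sse`, `exemplar_sse`.
#' @export
cluster_states <- function(encoded, k, exemplar_rows = NULL, seed = 1L,
                           n_init = 128L) {
  x <- as.matrix(encoded)
  if (is.null(exemplar_rows)) exemplar_rows <- seq_len(nrow(x))
  ex <- x[exemplar_rows, , drop = FALSE]
  if (k > nrow(ex)) stop("k exceeds the number of exemplar windows")
  set.seed(seed)
  if (k == 1L) {
    ctr <- matrix(colMeans(x), 1L)
    return(structure(list(k = 1L, centroids = ctr,
                          assignments = rep(1L, nrow(x)),
                          sse = .kmeans_sse(x, ctr), exemplar_sse = NA_real_),
                     class = "state_model"))
  }
  best <- NULL
  best_sse <- Inf
  for (r in seq_len(n_init)) {
    init <- .kmeanspp_init(ex, k)
    km <- suppressWarnings(
      kmeans(ex, centers = init, iter.max = 1000L, algorithm = "Lloyd"))
    if (km$tot.withinss < best_sse) {
      best_sse <- km$tot.withinss
      best <- km$centers
    }
  }
  km_full <- suppressWarnings(
    kmeans(x, centers = best, iter.max = 10000L, algorithm = "Lloyd"))
  structure(list(k = as.integer(k), centroids = km_full$centers,
                 assignments = as.integer(km_full$cluster),
                 sse = km_full$tot.withinss, exemplar_sse = best_sse),
            class = "state_model")
}

#' Elbow selection of the number of states
#'
#' For each candidate k the ratio of the mean within-cluster distance (each
#' window to its centroid) to the mean between-centroid distance is
#' computed from [cluster_states()].  The elbow is located as the candidate
#' whose ratio lies furthest below the straight line joining the curve's
#' endpoints (the rule used by reference dynamic-FC toolboxes); a depth
#' below `min_depth` (relative to the curve's total drop) flags the
#' selection as low-confidence.  The second-difference curvature of the
#' curve is also reported.
#'
#' @param encoded windows x bottleneck matrix.
#' @param k_range candidate state counts (default 2:9; at least 3 values).
#' @param exemplar_rows exemplar row indices (see [cluster_states()]).
#' @param seed RNG seed.
#' @param n_init stage-1 repetitions per k.
#' @param min_depth relative chord-depth threshold for the confidence flag.
#' @return list of class `elbow_fit`: `k`, `ratio` (named by k), `depth`
#'   (chord depth per candidate), `curvature` (second differences),
#'   `confident`, `models` (per-k state models).
#' @export
elbow_select_k <- function(encoded, k_range = 2:9, exemplar_rows = NULL,
                           seed = 1L, n_init = 128L, min_depth = 0.3) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L) stop("need at least 3 candidate values of k")
  x <- as.matrix(encoded)
  models <- vector("list", length(k_range))
  ratio <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    sm <- cluster_states(x, k, exemplar_rows = exemplar_rows,
                         seed = seed + i, n_init = n_init)
    models[[i]] <- sm
    within <- mean(sqrt(rowSums((x - sm$centroids[sm$assignments, ,
                                                  drop = FALSE])^2)))
    dc <- as.matrix(stats::dist(sm$centroids))
    between <- mean(dc[upper.tri(dc)])
    ratio[i] <- within / between
  }
  names(ratio) <- k_range
  n <- length(k_range)
  # depth below the chord joining the first and last candidates
  chord <- ratio[1L] + (ratio[n] - ratio[1L]) *
    (k_range - k_range[1L]) / (k_range[n] - k_range[1L])
  depth <- chord - ratio
  sel <- which.max(depth)
  total_drop <- max(ratio[1L] - ratio[n], .Machine$double.eps)
  structure(list(k = k_range[sel], ratio = ratio, depth = depth,
                 curvature = diff(ratio, differences = 2L),
                 confident = max(depth) / total_drop >= min_depth,
                 models = setNames(models, k_range)),
            class = "elbow_fit")
}

#' State temporal metrics: dwell time and fractional occupancy
#'
#' Dwell time is the mean contiguous run length in a state times the window
#' step duration (seconds); fractional occupancy is the fraction of windows
#' assigned to the state.  States a subject never visits have occupancy 0
#' and undefined (NA) dwell time.  Subject-level state FC matrices are the
#' element-wise median of the subject's windows assigned to each state.
#'
#' @param assignments list (one per subject) of per-window state labels.
#' @param spec a [window_spec()] (supplies the step duration).
#' @param k number of states (default: max observed label).
#' @param windows optional list of per-subject window feature matrices
#'   (W x E Fisher-z edges) for subject state FC.
#' @return list of class `state_metrics`: `dwell_time` (subjects x states,
#'   seconds, NA where unvisited), `fractional_occupancy`, `visited`,
#'   `subject_state_fc` (if `windows` given: list [[subject]][[state]] of
#'   median edge vectors).
#' @export
state_metrics <- function(assignments, spec, k = NULL, windows = NULL) {
  if (!is.list(assignments)) assignments <- list(assignments)
  if (is.null(k)) k <- max(unlist(assignments))
  step_s <- spec$step_tr * spec$tr_seconds
  n_sub <- length(assignments)
  dwell <- matrix(NA_real_, n_sub, k,
                  dimnames = list(names(assignments), paste0("state", 1:k)))
  occ <- matrix(0, n_sub, k,
                dimnames = list(names(assignments), paste0("state", 1:k)))
  for (i in seq_len(n_sub)) {
    lab <- as.integer(assignments[[i]])
    runs <- rle(lab)
    for (s in seq_len(k)) {
      occ[i, s] <- sum(lab == s) / length(lab)
      rl <- runs$lengths[runs$values == s]
      if (length(rl)) dwell[i, s] <- mean(rl) * step_s
    }
  }
  out <- list(dwell_time = dwell, fractional_occupancy = occ,
              visited = !is.na(dwell), step_seconds = step_s)
  if (!is.null(windows)) {
    out$subject_state_fc <- lapply(seq_len(n_sub), function(i) {
      lapply(seq_len(k), function(s) {
        rows <- which(assignments[[i]] == s)
        if (!length(rows)) return(NULL)
        apply(windows[[i]][rows, , drop = FALSE], 2L, median)
      })
    })
  }
  structure(out, class = "state_metrics")
}

#' State centroid FC matrices in edge space
#'
#' Cluster centroids live in the autoencoder bottleneck; for reporting and
#' ground-truth comparison each state's FC matrix is summarized as the
#' element-wise median of all windows assigned to that state, refolded to a
#' symmetric matrix.
#'
#' @param model a [cluster_states()] result.
#' @param windows pooled windows x edges Fisher-z matrix (original space).
#' @param n_components number of components n with E = n(n-1)/2.
#' @return list of k symmetric n x n matrices (Fisher-z, diagonal NA).
#' @export
state_fc_matrices <- function(model, windows, n_components) {
  stopifnot(inherits(model, "state_model"))
  lapply(seq_len(model$k), function(s) {
    rows <- which(model$assignments == s)
    med <- apply(windows[rows, , drop = FALSE], 2L, median)
    .edge_matrix(med, n_components)
  })
}

#' Match recovered states to planted states
#'
#' Hungarian-style assignment on the correlation between recovered state
#' edge vectors and planted state correlation matrices.
#'
#' @param recovered list of recovered state FC matrices (or edge vectors).
#' @param planted list of planted state correlation matrices.
#' @return list: `matching` (planted -> recovered index), `correlation`
#'   (per planted state, with its matched recovered state).
#' @export
match_states <- function(recovered, planted) {
  as_edge <- function(m) if (is.matrix(m)) .edge_vector(m) else as.numeric(m)
  rec <- lapply(recovered, as_edge)
  pla <- lapply(planted, as_edge)
  sim <- outer(seq_along(pla), seq_along(rec),
               Vectorize(function(i, j) abs(cor(pla[[i]], rec[[j]]))))
  m <- match_components(sim)
  corr <- vapply(seq_along(pla),
                 function(i) cor(pla[[i]], rec[[m[i]]]), numeric(1))
  list(matching = m, correlation = corr)
}
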