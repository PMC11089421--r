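#' Construct a subject time-series object
#'
#' @param data observations (voxels/regions) x timepoints numeric matrix.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id identifier.
#' @return object of class `subject_timeseries`.
#' @export
subject_timeseries <- function(data, tr_seconds, subject_id = "subject") {
  data <- as.matrix(data)
  if (anyNA(data)) stop("subject data contains missing values")
  stopifnot(tr_seconds > 0)
  structure(list(data = data, tr_seconds = tr_seconds,
                 subject_id = subject_id),
            class = "subject_timeseries")
}

#' Subject-level temporal PCA
#'
#' Reduces a voxels x T matrix to its leading `n_components` directions of
#' temporal variability.  Each voxel's time series is mean-centred; the
#' reduction keeps the top right-singular directions so that
#' `scores %*% t(basis)` reconstructs the centred data.
#'
#' @param ts a [subject_timeseries()] or numeric matrix.
#' @param n_components number of retained components.
#' @return list of class `subject_pca`: `scores` (voxels x k), `basis`
#'   (T x k), `eigenvalues` (all squared singular values, decreasing),
#'   `explained` (fraction of variance retained), `center` (per-voxel means),
#'   `tr_seconds`, `subject_id`.
#' @export
subject_pca <- function(ts, n_components) {
  if (inherits(ts, "subject_timeseries")) {
    x <- ts$data; tr <- ts$tr_seconds; id <- ts$subject_id
  } else {
    x <- as.matrix(ts); tr <- NA_real_; id <- "subject"
  }
  if (n_components > ncol(x)) {
    stop(sprintf("n_components (%d) exceeds timepoints (%d)",
                 n_components, ncol(x)))
  }
  ctr <- rowMeans(x)
  xc <- x - ctr
  sv <- svd(xc)
  rank <- sum(sv$d > sv$d[1L] * 1e-10)
  if (n_components > rank) {
    stop(sprintf("n_components (%d) exceeds achievable rank %d",
                 n_components, rank))
  }
  keep <- seq_len(n_components)
  structure(list(
    scores = sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components),
    basis = sv$v[, keep, drop = FALSE],
    eigenvalues = sv$d^2,
    explained = sum(sv$d[keep]^2) / sum(sv$d^2),
    center = ctr, tr_seconds = tr, subject_id = id),
    class = "subject_pca")
}

# EM algorithm for the principal subspace (iterated least squares);
# refined to ordered orthonormal components at the end
.em_pca <- function(x, q, maxit = 500L, tol = 1e-6) {
  p <- ncol(x)
  w <- matrix(rnorm(p * q), p, q)
  prev <- NULL
  for (it in seq_len(maxit)) {
    # E: latent coordinates; M: new basis
    z <- solve(crossprod(w), t(w) %*% t(x))        # q x n
    w <- t(x) %*% t(z) %*% solve(tcrossprod(z))    # p x q
    wo <- qr.Q(qr(w))
    if (!is.null(prev)) {
      # largest principal angle between successive subspaces
      s <- svd(crossprod(prev, wo))$d
      if (sqrt(max(0, 1 - min(s)^2)) < tol) { prev <- wo; break }
    }
    prev <- wo
  }
  # rotate to ordered principal axes within the subspace
  proj <- x %*% prev
  sv <- svd(proj)
  basis <- prev %*% sv$v
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(q)) {
    piv <- which.max(abs(basis[, j]))
    if (basis[piv, j] < 0) basis[, j] <- -basis[, j]
  }
  basis
}

#' Group PCA over temporally concatenated subject reductions
#'
#' Subject score matrices (voxels x k_i) are concatenated column-wise
#' (the concatenated-time dimension) and reduced to `n_group_components`
#' with the expectation-maximization subspace algorithm (exact
#' eigendecomposition available via `method = "svd"`).
#'
#' @param subject_pcas list of [subject_pca()] results.
#' @param n_group_components retained group components.
#' @param method `"em"` (default) or `"svd"` (exact, reference).
#' @param maxit,tol EM iteration cap and subspace-change tolerance.
#' @return list of class `group_pca`: `scores` (voxels x q), `basis`
#'   (K_tot x q), `center`, `blocks` (per-subject column ranges),
#'   `subject_pcas`.
#' @export
group_pca_concat <- function(subject_pcas, n_group_components,
                             method = c("em", "svd"),
                             maxit = 500L, tol = 1e-6) {
  method <- match.arg(method)
  nv <- vapply(subject_pcas, function(p) nrow(p$scores), integer(1))
  if (length(unique(nv)) != 1L) {
    stop("subjects have inconsistent voxel dimensions: ",
         paste(unique(nv), collapse = ", "))
  }
  g <- do.call(cbind, lapply(subject_pcas, `[[`, "scores"))
  ctr <- colMeans(g)
  gc_ <- sweep(g, 2L, ctr)
  if (n_group_components > ncol(gc_)) {
    stop("n_group_components exceeds concatenated dimension")
  }
  basis <- if (method == "svd") {
    sv <- svd(gc_, nu = 0, nv = n_group_components)
    b <- sv$v
    for (j in seq_len(n_group_components)) {
      piv <- which.max(abs(b[, j]))
      if (b[piv, j] < 0) b[, j] <- -b[, j]
    }
    b
  } else {
    .em_pca(gc_, n_group_components, maxit = maxit, tol = tol)
  }
  ks <- vapply(subject_pcas, function(p) ncol(p$scores), integer(1))
  ends <- cumsum(ks)
  blocks <- Map(function(s, e) s:e, c(1L, head(ends, -1L) + 1L), ends)
  structure(list(scores = gc_ %*% basis, basis = basis, center = ctr,
                 blocks = blocks, subject_pcas = subject_pcas),
            class = "group_pca")
}

#' Infomax independent component analysis
#'
#' Maximum-likelihood ICA with a logistic source prior, fitted by
#' natural-gradient ascent on whitened data.  Suited to the super-Gaussian
#' (sparse, blob-like) spatial sources of resting-state decompositions.
#' Recovered sources are scaled to unit variance and sign-flipped so each
#' map's skewness is positive.
#'
#' @param x mixtures: observations x channels matrix (e.g. group PCA scores,
#'   voxels x q); sources are estimated over the observation dimension.
#' @param n_components number of components (<= channels).
#' @param seed RNG seed for the unmixing initialization.
#' @param max_iter,tol,learning_rate optimizer controls.
#' @return list of class `infomax_ica`: `sources` (n_components x
#'   observations), `mixing` (channels x n_components), `unmixing`,
#'   `converged`, `iterations`.
#' @export
infomax_ica <- function(x, n_components, seed = 1L, max_iter = 500L,
                        tol = 1e-6, learning_rate = 0.1) {
  m <- t(as.matrix(x))                      # channels x observations
  q <- nrow(m)
  n <- ncol(m)
  if (n_components > q) stop("n_components exceeds channel dimension")
  m <- m - rowMeans(m)
  cv <- tcrossprod(m) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_components)
  wh <- diag(1 / sqrt(eg$values[keep]), n_components) %*%
    t(eg$vectors[, keep, drop = FALSE])
  dewh <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), n_components)
  xw <- wh %*% m                            # whitened, n_components x n

  set.seed(seed)
  w <- diag(n_components) + matrix(rnorm(n_components^2, sd = 0.05),
                                   n_components)
  converged <- FALSE
  lr <- learning_rate
  it <- 0L
  eye <- diag(n_components)
  while (it < max_iter) {
    it <- it + 1L
    u <- w %*% xw
    y <- 1 / (1 + exp(-u))
    grad <- (eye + ((1 - 2 * y) %*% t(u)) / n) %*% w
    step_norm <- sqrt(sum(grad^2)) / sqrt(sum(w^2))
    w_new <- w + lr * grad
    if (!all(is.finite(w_new))) { lr <- lr / 2; next }
    w <- w_new
    if (step_norm * lr < tol) { converged <- TRUE; break }
    if (it %% 100L == 0L) lr <- lr * 0.7    # gentle annealing
  }
  if (!converged) {
    warning(sprintf("infomax did not converge in %d iterations", max_iter))
  }

  s <- w %*% xw
  scale <- apply(s, 1L, sd)
  s <- s / scale
  skew <- apply(s, 1L, function(v) mean((v - mean(v))^3))
  flip <- ifelse(skew < 0, -1, 1)
  s <- s * flip
  unmix <- (flip / scale) * (w %*% wh)      # n_components x channels
  mixing <- dewh %*% solve(w) %*% diag(scale * flip, n_components)
  structure(list(sources = s, mixing = mixing, unmixing = unmix,
                 converged = converged, iterations = it),
            class = "infomax_ica")
}

#' ICASSO stability analysis of repeated ICA runs
#'
#' ICA is repeated `n_runs` times with randomized initialization and (by
#' default) bootstrap resampling of the observations, the canonical ICASSO
#' scheme: data-constrained source components reappear in every run while
#' components fitting noise wander.  Each run's unmixing is applied to the
#' full data so maps are comparable; all estimated components are clustered
#' by absolute spatial correlation and each cluster's stability index I_q
#' is the mean within-cluster similarity minus the mean similarity to
#' components outside the cluster.  The aggregate map of a cluster is its
#' centrotype (the member most similar to the rest of its cluster).
#' Components with I_q <= `iq_threshold` are flagged for exclusion.
#'
#' @param group_reduced group PCA result ([group_pca_concat()]) or a
#'   voxels x q score matrix.
#' @param n_components components per run.
#' @param n_runs number of ICA repetitions (>= 2).
#' @param seed base seed; run r uses seed + r.
#' @param iq_threshold stability threshold (default 0.8).
#' @param bootstrap resample observations with replacement per run
#'   (default TRUE).
#' @param ... passed to [infomax_ica()].
#' @return list of class `group_ica`: `group_maps` (components x voxels,
#'   centrotypes), `mixing` (q x components), `stability_iq`, `retained`
#'   (I_q > threshold), `n_runs_used`, plus the `group_pca` input when
#'   supplied.
#' @export
icasso_stability <- function(group_reduced, n_components, n_runs = 10L,
                             seed = 1L, iq_threshold = 0.8,
                             bootstrap = TRUE, ...) {
  if (n_runs < 2L) stop("ICASSO needs at least 2 runs")
  scores <- if (inherits(group_reduced, "group_pca")) {
    group_reduced$scores
  } else {
    as.matrix(group_reduced)
  }
  m_full <- t(scores)
  m_full <- m_full - rowMeans(m_full)
  runs <- list()
  for (r in seq_len(n_runs)) {
    x_run <- if (bootstrap) {
      set.seed(seed + 7919L * r)
      scores[sample.int(nrow(scores), replace = TRUE), , drop = FALSE]
    } else {
      scores
    }
    fit <- tryCatch(
      withCallingHandlers(
        infomax_ica(x_run, n_components, seed = seed + r, ...),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    # project the run's unmixing onto the full data for comparable maps
    s_full <- fit$unmixing %*% m_full
    sds <- apply(s_full, 1L, sd)
    if (any(sds == 0)) next
    s_full <- s_full / sds
    skew <- apply(s_full, 1L, function(v) mean((v - mean(v))^3))
    fit$sources <- s_full * ifelse(skew < 0, -1, 1)
    runs[[length(runs) + 1L]] <- fit
  }
  if (length(runs) < 2L) stop("fewer than 2 ICASSO runs converged")

  all_maps <- do.call(rbind, lapply(runs, `[[`, "sources"))
  sim <- abs(cor(t(all_maps)))
  run_id <- rep(seq_along(runs), each = n_components)
  cl <- stats::cutree(stats::hclust(stats::as.dist(1 - sim),
                                    method = "average"),
                      k = n_components)

  iq <- numeric(n_components)
  centrotype <- integer(n_components)
  for (k in seq_len(n_components)) {
    members <- which(cl == k)
    others <- which(cl != k)
    intra <- if (length(members) > 1L) {
      sm <- sim[members, members, drop = FALSE]
      mean(sm[upper.tri(sm)])
    } else 1
    extra <- if (length(others)) mean(sim[members, others, drop = FALSE]) else 0
    iq[k] <- intra - extra
    score <- rowSums(sim[members, members, drop = FALSE])
    centrotype[k] <- members[which.max(score)]
  }
  ord <- order(iq, decreasing = TRUE)
  iq <- iq[ord]
  centrotype <- centrotype[ord]
  group_maps <- all_maps[centrotype, , drop = FALSE]

  # mixing of aggregate maps in the group-reduced space (least squares)
  a_t <- solve(tcrossprod(group_maps), group_maps %*% scores)
  res <- list(group_maps = group_maps, mixing = t(a_t),
              stability_iq = iq, retained = iq > iq_threshold,
              iq_threshold = iq_threshold,
              n_components = n_components, n_runs_used = length(runs))
  if (inherits(group_reduced, "group_pca")) res$group_pca <- group_reduced
  structure(res, class = "group_ica")
}

#' Back-reconstruct subject-specific maps and time courses
#'
#' Subject time courses are obtained by projecting the group ICA mixing
#' back through the group and subject PCA bases (the projection analogue of
#' dual regression); subject spatial maps are then the least-squares
#' regression of the subject's centred data on those time courses.
#'
#' @param gica a [icasso_stability()] result carrying its `group_pca`.
#' @param subject_index index of the subject within the group PCA.
#' @param components which components to reconstruct (default: retained).
#' @return list: `timecourses` (T x n_c), `maps` (n_c x voxels),
#'   `component_index`.
#' @export
back_reconstruct <- function(gica, subject_index, components = NULL) {
  stopifnot(inherits(gica, "group_ica"))
  gp <- gica$group_pca
  if (is.null(gp)) stop("group ICA result lacks the group PCA (subject bases)")
  if (is.null(components)) {
    components <- which(gica$retained)
    if (!length(components)) components <- seq_len(gica$n_components)
  }
  sp <- gp$subject_pcas[[subject_index]]
  if (is.null(sp$basis)) stop("missing subject PCA basis")
  block <- gp$blocks[[subject_index]]
  b_i <- gp$basis[block, , drop = FALSE]          # k x q
  a <- gica$mixing[, components, drop = FALSE]    # q x n_c
  tc <- sp$basis %*% (b_i %*% a)                  # T x n_c
  xc <- sp$scores %*% t(sp$basis)                 # centred subject data (V x T)
  if (max(abs(xc)) == 0) stop("zero-variance subject data; cannot reconstruct")
  maps <- t(solve(crossprod(tc), t(tc) %*% t(xc)))  # V x n_c
  list(timecourses = tc, maps = t(maps), component_index = components)
}

#' Spectral metrics for intrinsic-connectivity-network selection
#'
#' Welch power spectrum (Hann taper, 50% overlap) of a component time
#' course; `power_ratio` is total power below 0.10 Hz over total power in
#' 0.15-0.25 Hz (a small floor keeps the ratio finite when the denominator
#' band is empty of power) and `dynamic_range` is the difference between
#' the maximum and minimum of the estimated spectrum.
#'
#' @param timecourse numeric vector (length >= 64).
#' @param tr_seconds repetition time in seconds; Nyquist must reach 0.25 Hz.
#' @param segment_length Welch segment length (default 64).
#' @return list of class `spectral_metrics`: `power_ratio`, `dynamic_range`,
#'   `freq`, `power`.
#' @export
spectral_icn_metrics <- function(timecourse, tr_seconds,
                                 segment_length = 64L) {
  if (length(timecourse) < 64L) stop("time course shorter than 64 samples")
  fs <- 1 / tr_seconds
  if (fs / 2 < 0.25) {
    stop(sprintf("Nyquist frequency %.3f Hz below the 0.25 Hz band edge",
                 fs / 2))
  }
  psd <- welch_psd(timecourse, fs, segment_length = segment_length)
  low <- sum(psd$power[psd$freq < 0.10])
  high <- sum(psd$power[psd$freq >= 0.15 & psd$freq <= 0.25])
  floor_ <- 1e-12 * sum(psd$power) + .Machine$double.xmin
  structure(list(power_ratio = low / max(high, floor_),
                 dynamic_range = max(psd$power) - min(psd$power),
                 freq = psd$freq, power = psd$power),
            class = "spectral_metrics")
}

#' Select intrinsic connectivity networks from component metrics
#'
#' Combines the spectral criteria (low-frequency dominance, dynamic range)
#' with an optional mask-overlap proxy for the anatomical criterion and
#' manual include/exclude overrides.
#'
#' @param metrics list of [spectral_icn_metrics()] results (one per
#'   component) or a data frame with columns `power_ratio`, `dynamic_range`.
#' @param min_power_ratio minimum low/high power ratio (default 2).
#' @param min_dynamic_range minimum spectral dynamic range (default 0).
#' @param maps optional components x voxels matrix for mask overlap.
#' @param grey_matter_mask,artefact_mask optional logical voxel masks.
#' @param min_grey_overlap,max_artefact_overlap overlap-fraction bounds on
#'   the absolute map mass inside each mask.
#' @param include,exclude component indices forced in or out.
#' @return data frame: component, power_ratio, dynamic_range, is_icn.
#' @export
select_icns <- function(metrics, min_power_ratio = 2,
                        min_dynamic_range = 0, maps = NULL,
                        grey_matter_mask = NULL, artefact_mask = NULL,
                        min_grey_overlap = 0.5, max_artefact_overlap = 0.5,
                        include = NULL, exclude = NULL) {
  if (is.data.frame(metrics)) {
    pr <- metrics$power_ratio
    dr <- metrics$dynamic_range
  } else {
    pr <- vapply(metrics, `[[`, numeric(1), "power_ratio")
    dr <- vapply(metrics, `[[`, numeric(1), "dynamic_range")
  }
  ok <- pr >= min_power_ratio & dr >= min_dynamic_range
  if (!is.null(maps)) {
    mass <- rowSums(abs(maps))
    if (!is.null(grey_matter_mask)) {
      gm <- rowSums(abs(maps[, grey_matter_mask, drop = FALSE])) / mass
      ok <- ok & gm >= min_grey_overlap
    }
    if (!is.null(artefact_mask)) {
      af <- rowSums(abs(maps[, artefact_mask, drop = FALSE])) / mass
      ok <- ok & af <= max_artefact_overlap
    }
  }
  if (!is.null(include)) ok[include] <- TRUE
  if (!is.null(exclude)) ok[exclude] <- FALSE
  data.frame(component = seq_along(pr), power_ratio = pr,
             dynamic_range = dr, is_icn = ok)
}
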