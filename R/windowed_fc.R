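#' Sliding-window specification
#'
#' Defaults describe a 50-TR (45.3 s at TR = 0.906 s) tapered window built
#' by convolving a rectangle with a Gaussian of sigma 6 TR (5.436 s),
#' slid in steps of 1 TR.
#'
#' @param length_tr window length in TR (default 50).
#' @param gaussian_sigma_tr Gaussian taper sigma in TR (default 6).
#' @param step_tr slide step in TR (default 1).
#' @param tr_seconds repetition time in seconds (default 0.906).
#' @return object of class `window_spec` (also carries `length_seconds`,
#'   `sigma_seconds`, `step_seconds`).
#' @export
window_spec <- function(length_tr = 50L, gaussian_sigma_tr = 6,
                        step_tr = 1L, tr_seconds = 0.906) {
  stopifnot(length_tr >= 2L, step_tr >= 1L, tr_seconds > 0)
  if (gaussian_sigma_tr <= 0) stop("gaussian taper sigma must be positive")
  structure(list(length_tr = as.integer(length_tr),
                 gaussian_sigma_tr = gaussian_sigma_tr,
                 step_tr = as.integer(step_tr),
                 tr_seconds = tr_seconds,
                 length_seconds = length_tr * tr_seconds,
                 sigma_seconds = gaussian_sigma_tr * tr_seconds,
                 step_seconds = step_tr * tr_seconds),
            class = "window_spec")
}

#' Tapered window weights
#'
#' A rectangular window of `length_tr` samples is convolved with a
#' unit-area Gaussian (sigma in TR), the result truncated to the
#' rectangle's support and renormalized to sum to one.  The weights are
#' symmetric and unimodal.
#'
#' @param spec a [window_spec()].
#' @return numeric weight vector of length `length_tr`, summing to 1.
#' @export
make_taper <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  L <- spec$length_tr
  sigma <- spec$gaussian_sigma_tr
  half <- ceiling(4 * sigma)
  g <- dnorm(seq(-half, half), sd = sigma)
  g <- g / sum(g)
  # discrete convolution of the length-L rectangle with the Gaussian,
  # evaluated on the rectangle's support only
  u <- seq(-half, half)
  w <- vapply(seq_len(L), function(i) {
    sum(g[(i - u) >= 1L & (i - u) <= L])
  }, numeric(1))
  w / sum(w)
}

# weighted covariance of a window (weights sum to 1)
.weighted_cov <- function(x, w) {
  mu <- colSums(x * w)
  xc <- sweep(x, 2L, mu)
  denom <- 1 - sum(w^2)
  crossprod(xc * sqrt(w)) / denom
}

#' Graphical lasso covariance/precision estimate
#'
#' L1-penalized Gaussian precision estimation by block coordinate descent
#' (off-diagonals penalized).  At `lambda = 0` the empirical covariance is
#' returned directly (it must then be non-singular).
#'
#' @param s sample covariance matrix.
#' @param lambda L1 penalty (>= 0).
#' @param tol,maxit convergence controls.
#' @return list: `w` (regularized covariance), `theta` (precision).
#' @export
graphical_lasso <- function(s, lambda, tol = 1e-5, maxit = 200L) {
  s <- as.matrix(s)
  if (lambda < 0) stop("lambda must be >= 0")
  if (lambda == 0) {
    rc <- rcond(s)
    if (!is.finite(rc) || rc < 1e-12) {
      stop("singular covariance at lambda = 0; use lambda > 0")
    }
    return(list(w = s, theta = solve(s)))
  }
  .glasso_cpp(s, lambda, tol, maxit)
}

#' Tapered sliding-window functional connectivity
#'
#' For each window position the taper-weighted covariance of the component
#' time courses is regularized by the graphical lasso, converted to a
#' correlation matrix and Fisher z-transformed; each window contributes one
#' vector of `n(n-1)/2` edge features.
#'
#' @param timecourses components x timepoints matrix.
#' @param spec a [window_spec()].
#' @param lambda_l1 graphical-lasso penalty (per subject; see
#'   [select_lambda()]).
#' @param labels optional component labels.
#' @return list of class `windowed_fc`: `windows` (W x E Fisher-z edge
#'   matrix), `window_centers` (timepoint indices), `lambda_l1`, `spec`,
#'   `edge_labels`, `n_components`.
#' @export
sliding_window_fc <- function(timecourses, spec, lambda_l1, labels = NULL) {
  x <- t(as.matrix(timecourses))              # T x n
  tt <- nrow(x)
  n <- ncol(x)
  stopifnot(inherits(spec, "window_spec"))
  if (tt < spec$length_tr) stop("fewer timepoints than the window length")
  if (lambda_l1 < 0) stop("lambda_l1 must be >= 0")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  w <- make_taper(spec)
  starts <- seq(1L, tt - spec$length_tr + 1L, by = spec$step_tr)
  e <- n * (n - 1L) / 2L
  z <- matrix(NA_real_, length(starts), e)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + spec$length_tr - 1L), , drop = FALSE]
    cv <- .weighted_cov(seg, w)
    fit <- graphical_lasso(cv, lambda_l1)
    r <- stats::cov2cor(fit$w)
    z[i, ] <- fisher_z(.edge_vector(r))
  }
  structure(list(windows = z,
                 window_centers = starts + (spec$length_tr - 1L) / 2,
                 lambda_l1 = lambda_l1, spec = spec,
                 edge_labels = .edge_labels(labels),
                 n_components = n),
            class = "windowed_fc")
}

#' Cross-validated selection of the graphical-lasso penalty
#'
#' Windows are split into `n_folds` contiguous folds.  For each candidate
#' lambda and fold, the precision estimated (by graphical lasso) from the
#' mean weighted window covariance of the training folds is scored by the
#' average Gaussian log-likelihood of the held-out windows' covariances;
#' the lambda maximizing the mean held-out log-likelihood is returned
#' (ties broken toward the smaller lambda).
#'
#' @param timecourses components x timepoints matrix.
#' @param spec a [window_spec()].
#' @param lambda_grid candidate penalties (default 10 points log-spaced in
#'   [0.01, 1]).
#' @param n_folds number of contiguous folds (default 5).
#' @param buffer_tr optionally drop training windows within this distance
#'   of the test block (overlapping windows share samples and leak a little
#'   information toward small penalties; the default 0 keeps all training
#'   windows, because larger buffers starve the training folds and inflate
#'   the between-subject spread of selected penalties on non-stationary
#'   data).
#' @return selected lambda (attribute `cv_loglik` carries the score curve).
#' @export
select_lambda <- function(timecourses, spec,
                          lambda_grid = 10^seq(-2, 0, length.out = 10),
                          n_folds = 5L, buffer_tr = 0L) {
  if (!length(lambda_grid)) stop("empty lambda grid")
  if (n_folds < 2L) stop("need at least 2 folds")
  lambda_grid <- sort(lambda_grid)
  x <- t(as.matrix(timecourses))
  tt <- nrow(x)
  stopifnot(inherits(spec, "window_spec"))
  w <- make_taper(spec)
  starts <- seq(1L, tt - spec$length_tr + 1L, by = spec$step_tr)
  covs <- lapply(starts, function(s0) {
    .weighted_cov(x[s0:(s0 + spec$length_tr - 1L), , drop = FALSE], w)
  })
  fold <- cut(seq_along(covs), breaks = n_folds, labels = FALSE)
  ll <- matrix(NA_real_, length(lambda_grid), n_folds)
  for (f in seq_len(n_folds)) {
    test_block <- which(fold == f)
    # drop training windows overlapping the test block: shared samples
    # leak information toward small penalties
    near <- seq_along(covs) >= min(test_block) - buffer_tr &
      seq_along(covs) <= max(test_block) + buffer_tr
    train_idx <- which(fold != f & !near)
    if (!length(train_idx)) train_idx <- which(fold != f)
    train <- Reduce(`+`, covs[train_idx]) / length(train_idx)
    test <- covs[test_block]
    for (li in seq_along(lambda_grid)) {
      fit <- tryCatch(graphical_lasso(train, lambda_grid[li]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      theta <- fit$theta
      ld <- determinant(theta, logarithm = TRUE)
      if (ld$sign <= 0) next
      ll[li, f] <- mean(vapply(test, function(s) {
        as.numeric(ld$modulus) - sum(theta * s)
      }, numeric(1)))
    }
  }
  score <- rowMeans(ll)
  if (all(!is.finite(score))) stop("all held-out log-likelihoods undefined")
  best <- which(score == max(score, na.rm = TRUE))[1L]
  structure(lambda_grid[best], cv_loglik = score, lambda_grid = lambda_grid)
}
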