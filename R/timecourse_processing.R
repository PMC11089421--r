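#' Remove polynomial trends from a time course
#'
#' Least-squares projection onto an orthogonal polynomial basis of the
#' given order (default cubic: removes constant, linear, quadratic and
#' cubic trends); the residual is returned.
#'
#' @param tc numeric vector.
#' @param order polynomial order (>= 0; default 3).
#' @return numeric vector, same length, orthogonal to the polynomial basis.
#' @export
detrend_poly <- function(tc, order = 3L) {
  if (order < 0L) stop("polynomial order must be >= 0")
  n <- length(tc)
  if (n <= order + 1L) stop("series too short for the requested order")
  if (order == 0L) return(tc - mean(tc))
  basis <- stats::poly(seq_len(n), degree = order)
  residuals(lm(tc ~ basis))
}

#' Replace outlier timepoints by cubic-spline interpolation
#'
#' Outliers are timepoints whose deviation from the running median of their
#' surrounding values (window `median_window`, centre excluded so the point
#' cannot mask itself) exceeds `mad_factor` times the median absolute
#' deviation of those residuals.  Each flagged point is replaced by a
#' third-order (cubic) spline fitted to the nearest `n_neighbours` clean
#' points on each side (boundary spikes use one-sided extrapolation).
#'
#' @param tc numeric vector (length >= 10).
#' @param mad_factor robust threshold multiplier (default 3).
#' @param median_window neighbourhood window (odd, default 7).
#' @param n_neighbours clean neighbours per side for the spline (default 4).
#' @return list of class `despiked_timecourse`: `values`, `spike_indices`.
#' @export
despike <- function(tc, mad_factor = 3, median_window = 7L,
                    n_neighbours = 4L) {
  n <- length(tc)
  if (n < 10L) stop("despike needs at least 10 timepoints")
  half <- median_window %/% 2L
  # running median of the surrounding values, centre excluded
  padded <- c(rep(tc[1L], half), tc, rep(tc[n], half))
  emb <- sapply(c(seq_len(half), half + 1L + seq_len(half)), function(j) {
    padded[(j - 1L) + seq_len(n)]
  })
  rm_ <- apply(emb, 1L, median)
  resid <- tc - rm_
  scale <- mad(resid)
  spikes <- if (scale == 0) integer(0) else which(abs(resid) > mad_factor * scale)
  if (length(spikes) > n / 2) {
    stop("more than half of the timepoints flagged as spikes; data unusable")
  }
  out <- tc
  clean <- setdiff(seq_len(n), spikes)
  for (s in spikes) {
    left <- utils::tail(clean[clean < s], n_neighbours)
    right <- utils::head(clean[clean > s], n_neighbours)
    nb <- c(left, right)
    if (length(nb) < 4L) nb <- clean[order(abs(clean - s))][seq_len(min(8L, length(clean)))]
    sp <- splinefun(nb, tc[nb], method = "natural")
    out[s] <- sp(s)
  }
  structure(list(values = out, spike_indices = spikes),
            class = "despiked_timecourse")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Fifth-order (by default) Butterworth low-pass applied forward and
#' backward (zero phase, DC gain exactly 1, effective magnitude response
#' squared).  The series is reflect-padded by three filter lengths at each
#' end before filtering to suppress edge transients.
#'
#' @param tc numeric vector.
#' @param tr_seconds sampling interval in seconds.
#' @param cutoff_hz low-pass cut-off frequency (default 0.15 Hz); must be
#'   below Nyquist.
#' @param order filter order (default 5).
#' @return filtered numeric vector, same length.
#' @export
lowpass_butterworth <- function(tc, tr_seconds, cutoff_hz = 0.15,
                                order = 5L) {
  fs <- 1 / tr_seconds
  if (cutoff_hz >= fs / 2) {
    stop(sprintf("cutoff %.3f Hz is at or above Nyquist %.3f Hz",
                 cutoff_hz, fs / 2))
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  n <- length(tc)
  pad <- min(n - 1L, 3L * (order + 1L) * 3L)
  padded <- c(2 * tc[1L] - tc[(pad + 1L):2L],
              tc,
              2 * tc[n] - tc[(n - 1L):(n - pad)])
  fwd <- signal::filter(bf, padded)
  bwd <- rev(signal::filter(bf, rev(fwd)))
  as.numeric(bwd[(pad + 1L):(pad + n)])
}

#' Post-process a component time course
#'
#' Fixed order: polynomial detrend, despike, zero-phase low-pass — the
#' order in which the pipeline always applies these steps.
#'
#' @param tc numeric vector.
#' @param tr_seconds sampling interval in seconds.
#' @param detrend_order polynomial order (default 3).
#' @param cutoff_hz low-pass cut-off (default 0.15 Hz).
#' @param filter_order Butterworth order (default 5).
#' @return list of class `processed_timecourse`: `values`, `spike_indices`,
#'   `tr_seconds`.
#' @export
process_timecourse <- function(tc, tr_seconds, detrend_order = 3L,
                               cutoff_hz = 0.15, filter_order = 5L) {
  dt <- detrend_poly(tc, order = detrend_order)
  ds <- despike(dt)
  lp <- lowpass_butterworth(ds$values, tr_seconds, cutoff_hz = cutoff_hz,
                            order = filter_order)
  structure(list(values = lp, spike_indices = ds$spike_indices,
                 tr_seconds = tr_seconds),
            class = "processed_timecourse")
}
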