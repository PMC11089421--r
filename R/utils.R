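#' Match two sets of labelled objects by maximum total similarity
#'
#' Solves the assignment problem on a similarity matrix: rows (e.g. planted
#' states or sources) are matched one-to-one to columns (recovered states)
#' so that the total similarity is maximal.  For up to 7 rows all
#' permutations are enumerated; beyond that a greedy assignment is used.
#'
#' @param similarity numeric matrix, rows x columns, higher = more similar.
#' @return integer vector `m` with `m[i]` the column matched to row `i`.
#' @export
match_components <- function(similarity) {
  similarity <- as.matrix(similarity)
  n <- nrow(similarity)
  m <- ncol(similarity)
  if (n > m) stop("more rows than columns to match")
  if (n <= 7L) {
    perms <- .permutations(seq_len(m), n)
    scores <- vapply(perms, function(p) {
      sum(similarity[cbind(seq_len(n), p)])
    }, numeric(1))
    return(perms[[which.max(scores)]])
  }
  # greedy fallback
  assign <- integer(n)
  free <- rep(TRUE, m)
  ord <- order(apply(similarity, 1L, max), decreasing = TRUE)
  for (i in ord) {
    j <- which.max(ifelse(free, similarity[i, ], -Inf))
    assign[i] <- j
    free[j] <- FALSE
  }
  assign
}

# all injective maps of length k from values v (list of integer vectors)
.permutations <- function(v, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i], k - 1L)) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with a Hann taper: the series is split
#' into overlapping segments, each segment is detrended (mean removed),
#' tapered and Fourier transformed, and the squared magnitudes are averaged.
#'
#' @param x numeric vector.
#' @param fs sampling frequency in Hz.
#' @param segment_length samples per segment (default 64).
#' @param overlap fraction of segment overlap (default 0.5).
#' @return list with `freq` (Hz) and `power` (one-sided PSD).
#' @export
welch_psd <- function(x, fs, segment_length = 64L, overlap = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < segment_length) stop("series shorter than one Welch segment")
  step <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  starts <- seq(1L, n - segment_length + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(segment_length) / (segment_length + 1)))
  u <- sum(w^2)
  nf <- segment_length %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment_length - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(fft(seg))^2 / (u * fs)
    acc <- acc + p[seq_len(nf)]
  }
  power <- acc / length(starts)
  # fold two-sided power into the one-sided estimate
  if (segment_length %% 2L == 0L) {
    power[2:(nf - 1L)] <- 2 * power[2:(nf - 1L)]
  } else {
    power[2:nf] <- 2 * power[2:nf]
  }
  freq <- (seq_len(nf) - 1L) * fs / segment_length
  list(freq = freq, power = power)
}

#' Fisher z-transform of correlations
#'
#' Correlations are clipped to +/-(1 - 1e-12) before `atanh` so degenerate
#' inputs cannot propagate infinities.
#'
#' @param r numeric vector or matrix of correlations.
#' @return `atanh` of the clipped values.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

# upper-triangle edge vector (row-major over i < j) and its inverse
.edge_vector <- function(m) m[upper.tri(m)]

.edge_matrix <- function(v, n, diag_value = NA_real_) {
  m <- matrix(diag_value, n, n)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

.edge_labels <- function(labels) {
  n <- length(labels)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  paste(labels[idx[, "row"]], labels[idx[, "col"]], sep = "--")
}

# deterministic per-stage seed expansion from a master seed
.stage_seed <- function(master_seed, stage_index) {
  as.integer((as.numeric(master_seed) * 97L + 1009L * stage_index) %% 2147483647)
}
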