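#' Read a 6-column motion-parameter file
#'
#' Whitespace-delimited text, one row per volume.  The common realignment
#' convention is rotations (radians) in columns 1-3 and translations (mm)
#' in columns 4-6; set `rotations_first = FALSE` for the reverse layout.
#'
#' @param path file path.
#' @param tr_seconds repetition time in seconds.
#' @param rotations_first logical column-order switch.
#' @return a `motion_trace` (see [motion_trace()]).
#' @export
read_motion_file <- function(path, tr_seconds, rotations_first = TRUE) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L) {
    stop(sprintf("motion file '%s' has %d columns; expected 6", path, ncol(m)))
  }
  if (rotations_first) {
    motion_trace(rotations = m[, 1:3], translations = m[, 4:6],
                 tr_seconds = tr_seconds)
  } else {
    motion_trace(rotations = m[, 4:6], translations = m[, 1:3],
                 tr_seconds = tr_seconds)
  }
}

#' Construct a motion trace
#'
#' @param translations T x 3 matrix of translations in mm.
#' @param rotations T x 3 matrix of rotations in radians.
#' @param tr_seconds repetition time in seconds.
#' @return object of class `motion_trace`.
#' @export
motion_trace <- function(translations, rotations, tr_seconds) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  if (ncol(translations) != 3L || ncol(rotations) != 3L) {
    stop("translations and rotations must each have 3 columns")
  }
  if (nrow(translations) != nrow(rotations)) {
    stop("translation and rotation parameter lengths differ")
  }
  if (nrow(translations) < 2L) stop("motion trace needs at least 2 frames")
  stopifnot(tr_seconds > 0)
  structure(list(translations = translations, rotations = rotations,
                 tr_seconds = tr_seconds),
            class = "motion_trace")
}

#' Framewise displacement and per-subject motion summary
#'
#' Framewise displacement at frame t is the sum of absolute frame-to-frame
#' differences of the three translations plus `head_radius_mm` times the
#' sum of absolute differences of the three rotations, converting angular
#' motion into arc displacement at the cortical surface.  The maximum
#' absolute displacement is the largest Euclidean translation distance from
#' the reference volume (by default the middle volume, matching the usual
#' motion-correction reference).
#'
#' @param trace a [motion_trace()].
#' @param head_radius_mm assumed brain-centre-to-cortex radius (default 50).
#' @param reference_volume index of the reference volume (default middle).
#' @return list of class `motion_qc`: `fd_series` (length T-1, mm),
#'   `mean_fd`, `max_abs_displacement`, `head_radius_mm`.
#' @export
framewise_displacement <- function(trace, head_radius_mm = 50,
                                   reference_volume = NULL) {
  stopifnot(inherits(trace, "motion_trace"), head_radius_mm > 0)
  dt <- abs(diff(trace$translations))
  dr <- abs(diff(trace$rotations))
  fd <- rowSums(dt) + head_radius_mm * rowSums(dr)
  n <- nrow(trace$translations)
  if (is.null(reference_volume)) reference_volume <- (n + 1L) %/% 2L
  ref <- trace$translations[reference_volume, ]
  disp <- sqrt(rowSums(sweep(trace$translations, 2L, ref)^2))
  structure(list(fd_series = as.numeric(fd),
                 mean_fd = mean(fd),
                 max_abs_displacement = max(disp),
                 head_radius_mm = head_radius_mm),
            class = "motion_qc")
}

#' Apply cohort-level motion exclusion rules
#'
#' A subject is excluded when mean framewise displacement exceeds
#' `fd_threshold` (strictly) or when the maximum absolute displacement from
#' the reference volume exceeds `max_disp_threshold` (strictly).
#'
#' @param qc_list named list of `motion_qc` objects (names = subject ids).
#' @param fd_threshold mean-FD threshold in mm (default 0.5).
#' @param max_disp_threshold maximum-displacement threshold in mm (default 4).
#' @return data frame with columns subject_id, mean_fd, max_abs_displacement,
#'   excluded, reason.
#' @export
apply_exclusions <- function(qc_list, fd_threshold = 0.5,
                             max_disp_threshold = 4.0) {
  stopifnot(fd_threshold > 0, max_disp_threshold > 0)
  if (length(qc_list) == 0L) stop("empty cohort: no QC records supplied")
  ids <- names(qc_list)
  if (is.null(ids)) ids <- sprintf("sub-%02d", seq_along(qc_list))
  rows <- lapply(seq_along(qc_list), function(i) {
    qc <- qc_list[[i]]
    fd_bad <- qc$mean_fd > fd_threshold
    disp_bad <- qc$max_abs_displacement > max_disp_threshold
    reason <- if (fd_bad && disp_bad) {
      "mean_fd;max_displacement"
    } else if (fd_bad) {
      "mean_fd"
    } else if (disp_bad) {
      "max_displacement"
    } else {
      ""
    }
    data.frame(subject_id = ids[i], mean_fd = qc$mean_fd,
               max_abs_displacement = qc$max_abs_displacement,
               excluded = fd_bad || disp_bad, reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
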