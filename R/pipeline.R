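#' Discard initial volumes of a BOLD acquisition
#'
#' Leading volumes are removed so analysis starts at steady-state
#' magnetization (e.g. 300 acquired volumes with the default `n = 5` leave
#' 295 analysed volumes).
#'
#' @param ts a [subject_timeseries()] or observations x time matrix.
#' @param n number of initial volumes to discard (default 5; must be < T).
#' @return same type as the input, with T - n timepoints.
#' @export
discard_initial_volumes <- function(ts, n = 5L) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  get_t <- function(x) ncol(x)
  if (inherits(ts, "subject_timeseries")) {
    if (n >= get_t(ts$data)) stop("cannot discard all volumes")
    if (n == 0L) return(ts)
    ts$data <- ts$data[, -(seq_len(n)), drop = FALSE]
    return(ts)
  }
  x <- as.matrix(ts)
  if (n >= ncol(x)) stop("cannot discard all volumes")
  if (n == 0L) return(x)
  x[, -(seq_len(n)), drop = FALSE]
}

#' Pipeline run configuration
#'
#' Bundles the per-stage specifications and a master seed.  Stage seeds are
#' expanded deterministically from the master seed (stage i uses
#' `(97 * seed + 1009 * i) mod (2^31 - 1)`), isolating the stochastic
#' stages from each other.
#'
#' @param synthetic a [synthetic_config()] (cohort source for simulated
#'   runs) or `NULL` when reading data from disk.
#' @param data_dir directory of per-subject TSVs/motion files (used when
#'   `synthetic` is `NULL`).
#' @param discard_volumes initial volumes to discard (default 5; applied to
#'   raw acquisitions longer than the analysis length).
#' @param fd_threshold,max_disp_threshold motion-exclusion thresholds.
#' @param n_subject_pcs,n_group_pcs,n_ica_components,n_ica_runs group ICA
#'   scale (desk-scale defaults 30/12/10/10).
#' @param window a [window_spec()].
#' @param autoencoder an [autoencoder_spec()].
#' @param k_range candidate state counts for the elbow rule.
#' @param lambda_grid candidate graphical-lasso penalties.
#' @param seed master seed.
#' @param outdir output directory (`NULL` = nothing written).
#' @return object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       data_dir = NULL,
                       discard_volumes = 5L,
                       fd_threshold = 0.5, max_disp_threshold = 4.0,
                       n_subject_pcs = 30L, n_group_pcs = 12L,
                       n_ica_components = 10L, n_ica_runs = 10L,
                       window = window_spec(),
                       autoencoder = autoencoder_spec(
                         encoder_units = c(128L, 64L, 16L), epochs = 60L),
                       k_range = 2:8,
                       lambda_grid = 10^seq(-2, 0, length.out = 10),
                       seed = 1L, outdir = NULL) {
  structure(list(synthetic = synthetic, data_dir = data_dir,
                 discard_volumes = as.integer(discard_volumes),
                 fd_threshold = fd_threshold,
                 max_disp_threshold = max_disp_threshold,
                 n_subject_pcs = as.integer(n_subject_pcs),
                 n_group_pcs = as.integer(n_group_pcs),
                 n_ica_components = as.integer(n_ica_components),
                 n_ica_runs = as.integer(n_ica_runs),
                 window = window, autoencoder = autoencoder,
                 k_range = k_range, lambda_grid = lambda_grid,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Dynamic-FC analysis of a set of component time courses
#'
#' The dynamic branch of the pipeline: per-subject cross-validated
#' graphical-lasso penalty, tapered sliding-window Fisher-z connectivity,
#' pooled autoencoder encoding, exemplar selection, elbow selection of k
#' with two-stage exemplar-initialized k-means, and state temporal metrics.
#'
#' @param timecourse_list list (one per subject) of components x timepoints
#'   matrices.
#' @param window a [window_spec()].
#' @param autoencoder an [autoencoder_spec()] (its seed is overridden by
#'   `seed`).
#' @param k_range candidate state counts.
#' @param lambda_grid penalty grid for [select_lambda()].
#' @param k fixed state count; when given, the elbow search is skipped.
#' @param seed seed driving lambda CV order-independent stages, autoencoder
#'   init and k-means.
#' @return list of class `dfc_result`: `windowed` (per-subject
#'   [sliding_window_fc()]), `lambdas`, `autoencoder`, `exemplars`,
#'   `elbow` (NULL if `k` fixed), `k`, `model` ([cluster_states()] at the
#'   selected k), `assignments` (per subject), `metrics`
#'   ([state_metrics()]), `state_fc` (per-state median edge matrices).
#' @export
run_dfc <- function(timecourse_list, window = window_spec(),
                    autoencoder = autoencoder_spec(), k_range = 2:8,
                    lambda_grid = 10^seq(-2, 0, length.out = 10),
                    k = NULL, seed = 1L) {
  n_sub <- length(timecourse_list)
  stopifnot(n_sub >= 1L)
  lambdas <- numeric(n_sub)
  wfc <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    tc <- timecourse_list[[i]]
    lambdas[i] <- as.numeric(select_lambda(tc, window,
                                           lambda_grid = lambda_grid))
    wfc[[i]] <- sliding_window_fc(tc, window, lambdas[i])
  }
  names(wfc) <- names(timecourse_list)
  pooled <- do.call(rbind, lapply(wfc, `[[`, "windows"))

  ae_spec <- autoencoder
  ae_spec$seed <- .stage_seed(seed, 2L)
  ae <- train_autoencoder(pooled, ae_spec)

  ex <- select_exemplars(wfc)
  if (is.null(k)) {
    elbow <- elbow_select_k(ae$encoded, k_range = k_range,
                            exemplar_rows = ex$global_rows,
                            seed = .stage_seed(seed, 3L))
    k_sel <- elbow$k
    model <- elbow$models[[as.character(k_sel)]]
  } else {
    elbow <- NULL
    k_sel <- as.integer(k)
    model <- cluster_states(ae$encoded, k_sel,
                            exemplar_rows = ex$global_rows,
                            seed = .stage_seed(seed, 3L))
  }

  counts <- vapply(wfc, function(w) nrow(w$windows), integer(1))
  split_idx <- rep(seq_len(n_sub), counts)
  assignments <- split(model$assignments, split_idx)
  names(assignments) <- names(wfc)
  metrics <- state_metrics(assignments, window, k = k_sel,
                           windows = lapply(wfc, `[[`, "windows"))
  n_comp <- wfc[[1L]]$n_components
  structure(list(windowed = wfc, lambdas = lambdas, autoencoder = ae,
                 exemplars = ex, elbow = elbow, k = k_sel, model = model,
                 assignments = assignments, metrics = metrics,
                 state_fc = state_fc_matrices(model, pooled, n_comp),
                 window = window),
            class = "dfc_result")
}

#' Run the full analysis pipeline
#'
#' Stage order: cohort input (synthetic generation or TSV ingestion, with
#' initial-volume discard) -> motion QC and exclusions -> group spatial ICA
#' with ICASSO and back-reconstruction -> component time-course
#' post-processing -> static FC -> dynamic FC (sliding windows, deep
#' clustering) -> state metrics -> group statistics.  A JSON manifest of
#' seeds, parameters and stage summaries is written when `outdir` is set.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with per-stage outputs
#'   (`cohort`, `qc`, `gica`, `timecourses`, `sfc`, `dfc`, `stats`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- input -----------------------------------------------------------
  cohort <- stage("input", {
    if (!is.null(config$synthetic)) {
      cfg <- config$synthetic
      cfg$seed <- .stage_seed(config$seed, 1L)
      generate_cohort(cfg)
    } else {
      read_cohort_dir(config$data_dir, discard = config$discard_volumes)
    }
  })
  tr <- cohort$subjects[[1L]]$tr_seconds

  # --- quality control -------------------------------------------------
  qc <- stage("quality_control", {
    qcl <- lapply(cohort$subjects, function(s) {
      framewise_displacement(
        motion_trace(translations = s$motion[, 4:6],
                     rotations = s$motion[, 1:3], tr_seconds = tr))
    })
    names(qcl) <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
    apply_exclusions(qcl, config$fd_threshold, config$max_disp_threshold)
  })
  keep <- which(!qc$excluded)
  if (!length(keep)) stop("pipeline stage 'quality_control' failed: all subjects excluded")
  subjects <- cohort$subjects[keep]
  cohort_tab <- cohort$cohort[keep, , drop = FALSE]

  # --- group ICA -------------------------------------------------------
  gica_out <- stage("group_ica", {
    spcas <- lapply(subjects, function(s) {
      subject_pca(subject_timeseries(s$data, tr, s$subject_id),
                  config$n_subject_pcs)
    })
    gp <- group_pca_concat(spcas, config$n_group_pcs)
    gica <- icasso_stability(gp, config$n_ica_components,
                             n_runs = config$n_ica_runs,
                             seed = .stage_seed(config$seed, 4L))
    list(gica = gica,
         back = lapply(seq_along(subjects),
                       function(i) back_reconstruct(gica, i)))
  })

  # --- time-course post-processing + ICN selection ---------------------
  tcs <- stage("timecourse_processing", {
    out <- lapply(gica_out$back, function(b) {
      apply(b$timecourses, 2L, function(v) {
        process_timecourse(v, tr)$values
      })
    })
    names(out) <- vapply(subjects, `[[`, character(1), "subject_id")
    out
  })
  icn <- stage("icn_selection", {
    pooled_tc <- do.call(rbind, tcs)
    metrics <- lapply(seq_len(ncol(pooled_tc)), function(j) {
      spectral_icn_metrics(pooled_tc[, j], tr)
    })
    select_icns(metrics)
  })
  icn_idx <- which(icn$is_icn)
  if (length(icn_idx) < 2L) icn_idx <- seq_len(ncol(tcs[[1L]]))

  # --- static FC -------------------------------------------------------
  sfc <- stage("static_fc", {
    lapply(tcs, function(m) static_fc(t(m[, icn_idx, drop = FALSE])))
  })

  # --- dynamic FC ------------------------------------------------------
  dfc <- stage("dynamic_fc", {
    run_dfc(lapply(tcs, function(m) t(m[, icn_idx, drop = FALSE])),
            window = config$window, autoencoder = config$autoencoder,
            k_range = config$k_range, lambda_grid = config$lambda_grid,
            seed = config$seed)
  })

  # --- statistics ------------------------------------------------------
  stats_out <- stage("group_stats", {
    edges <- t(vapply(sfc, function(f) .edge_vector(f$z_values),
                      numeric(sum(upper.tri(sfc[[1L]]$z_values)))))
    list(sfc_tests = residual_ttest(edges, cohort_tab),
         state_tests = state_ancova_table(dfc$metrics, cohort_tab))
  })

  manifest <- list(
    seed = config$seed,
    stage_seeds = vapply(1:4, function(i) .stage_seed(config$seed, i),
                         numeric(1)),
    n_subjects_input = length(cohort$subjects),
    n_subjects_kept = length(keep),
    n_excluded = sum(qc$excluded),
    n_icns = length(icn_idx),
    stability_iq = gica_out$gica$stability_iq,
    lambdas = dfc$lambdas,
    windows_per_subject = vapply(dfc$windowed,
                                 function(w) nrow(w$windows), integer(1)),
    selected_k = dfc$k,
    autoencoder_final_mse = dfc$autoencoder$final_mse,
    window = unclass(config$window),
    tr_seconds = tr)

  result <- structure(list(cohort = cohort, qc = qc, gica = gica_out$gica,
                           timecourses = tcs, icn = icn, sfc = sfc,
                           dfc = dfc, stats = stats_out,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  result
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory with `*_bold.tsv`, `*_motion.par` and `cohort.tsv`.
#' @param discard initial volumes to discard from each subject.
#' @param tr_seconds repetition time (default 0.906).
#' @return a list shaped like [generate_cohort()]'s output (no ground truth).
#' @export
read_cohort_dir <- function(dir, discard = 0L, tr_seconds = 0.906) {
  tab <- read.table(file.path(dir, "cohort.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$subject_id[i]
    data <- as.matrix(read.table(file.path(dir, paste0(id, "_bold.tsv")),
                                 sep = "\t"))
    if (discard > 0L) data <- discard_initial_volumes(data, discard)
    motion <- as.matrix(read.table(file.path(dir, paste0(id, "_motion.par"))))
    list(subject_id = id, group = tab$group[i], data = data,
         motion = motion, tr_seconds = tr_seconds)
  })
  list(subjects = subjects, cohort = tab, ground_truth = NULL)
}

#' Write pipeline outputs and manifest to a directory
#'
#' @param result a `pipeline_result`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.table(result$qc, file.path(outdir, "qc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$icn, file.path(outdir, "component_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ids <- vapply(result$cohort$subjects, `[[`, character(1), "subject_id")
  for (i in seq_along(result$sfc)) {
    write_fc_matrix(result$sfc[[i]],
                    file.path(outdir, sprintf("sfc_%s.tsv", ids[i])))
  }
  for (s in seq_along(result$dfc$state_fc)) {
    write.table(result$dfc$state_fc[[s]],
                file.path(outdir, sprintf("state_fc_%d.tsv", s)),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  occ <- result$dfc$metrics$fractional_occupancy
  dt <- result$dfc$metrics$dwell_time
  if (is.null(rownames(occ))) {
    rownames(occ) <- sprintf("sub-%02d", seq_len(nrow(occ)))
  }
  met <- data.frame(subject_id = rep(rownames(occ), ncol(occ)),
                    state = rep(seq_len(ncol(occ)), each = nrow(occ)),
                    dwell_s = as.vector(dt),
                    occupancy = as.vector(occ))
  write.table(met, file.path(outdir, "state_metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$stats$sfc_tests, file.path(outdir, "sfc_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$stats$state_tests,
              file.path(outdir, "state_ancova.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
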