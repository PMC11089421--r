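#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values via `stats::p.adjust`, with input validation.
#'
#' @param p vector of p-values in [0, 1].
#' @return monotone q-values, same length.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Edge-wise covariate-residualized two-sample t-tests with FDR
#'
#' For every edge, age and sex are regressed out of the edge value (one
#' pooled regression over both groups, intercept included); a two-tailed
#' two-sample t-test (pooled variance) then compares the residuals between
#' cases and controls.  BH-FDR is applied across all edges.
#'
#' @param edge_values subjects x edges numeric matrix.
#' @param cohort data frame with columns `subject_id`, `group`
#'   (case/control), `age`, `sex` (0/1), rows aligned with `edge_values`.
#' @param fdr_level significance level on q (default 0.05).
#' @return data frame of class `edge_test_result`: edge, t_statistic,
#'   p_uncorrected, q_fdr, significant_fdr.
#' @export
residual_ttest <- function(edge_values, cohort, fdr_level = 0.05) {
  x <- as.matrix(edge_values)
  stopifnot(nrow(x) == nrow(cohort))
  grp <- factor(cohort$group)
  if (nlevels(grp) != 2L) stop("cohort must contain exactly two groups")
  if (min(table(grp)) < 3L) stop("need at least 3 subjects per group")
  design <- cbind(1, age = cohort$age, sex = cohort$sex)
  if (qr(design)$rank < ncol(design)) stop("rank-deficient covariate design")
  # residualize all edges in one pass
  hat <- design %*% solve(crossprod(design), t(design))
  res <- x - hat %*% x
  g1 <- grp == levels(grp)[1L]
  n1 <- sum(g1)
  n2 <- sum(!g1)
  m1 <- colMeans(res[g1, , drop = FALSE])
  m2 <- colMeans(res[!g1, , drop = FALSE])
  v1 <- apply(res[g1, , drop = FALSE], 2L, var)
  v2 <- apply(res[!g1, , drop = FALSE], 2L, var)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  pval <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  q <- bh_fdr(pval)
  edge_names <- colnames(x)
  if (is.null(edge_names)) edge_names <- as.character(seq_len(ncol(x)))
  out <- data.frame(edge = edge_names, t_statistic = tstat,
                    p_uncorrected = pval, q_fdr = q,
                    significant_fdr = q < fdr_level,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "df") <- df
  class(out) <- c("edge_test_result", class(out))
  out
}

#' ANCOVA group effect on a temporal metric
#'
#' Ordinary least squares of `metric ~ group + age + sex`; returns the
#' group coefficient's t-statistic and two-tailed p-value.  Subjects with
#' an undefined metric (e.g. dwell time in a never-visited state) are
#' dropped.
#'
#' @param metric numeric vector (one value per subject; NA = undefined).
#' @param cohort data frame with `group`, `age`, `sex`, aligned rows.
#' @return list: `t`, `p`, `estimate`, `n_used`, `n_dropped`.
#' @export
ancova_group_effect <- function(metric, cohort) {
  stopifnot(length(metric) == nrow(cohort))
  keep <- !is.na(metric)
  n_dropped <- sum(!keep)
  d <- data.frame(metric = metric[keep],
                  group = factor(cohort$group[keep]),
                  age = cohort$age[keep], sex = cohort$sex[keep])
  if (min(table(d$group)) < 3L) {
    stop("need at least 3 subjects per group with a defined metric")
  }
  fit <- lm(metric ~ group + age + sex, data = d)
  co <- summary(fit)$coefficients
  grow <- grep("^group", rownames(co))
  list(t = unname(co[grow, "t value"]),
       p = unname(co[grow, "Pr(>|t|)"]),
       estimate = unname(co[grow, "Estimate"]),
       n_used = nrow(d), n_dropped = n_dropped)
}

#' State-wise ANCOVA table for dwell time and fractional occupancy
#'
#' @param metrics a [state_metrics()] result.
#' @param cohort cohort table aligned with the metric rows.
#' @return data frame: state, metric, t, p, n_used, n_dropped.
#' @export
state_ancova_table <- function(metrics, cohort) {
  stopifnot(inherits(metrics, "state_metrics"))
  rows <- list()
  for (what in c("dwell_time", "fractional_occupancy")) {
    m <- metrics[[what]]
    for (s in seq_len(ncol(m))) {
      a <- tryCatch(ancova_group_effect(m[, s], cohort),
                    error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(a)) {
        # state visited by too few subjects in one group: reported, untested
        data.frame(state = s, metric = what, t = NA_real_, p = NA_real_,
                   n_used = sum(!is.na(m[, s])),
                   n_dropped = sum(is.na(m[, s])))
      } else {
        data.frame(state = s, metric = what, t = a$t, p = a$p,
                   n_used = a$n_used, n_dropped = a$n_dropped)
      }
    }
  }
  do.call(rbind, rows)
}
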