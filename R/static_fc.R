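#' Static functional connectivity matrix
#'
#' Pairwise Pearson correlation between component time courses, Fisher
#' z-transformed.  The diagonal is undefined and returned as `NA`.
#'
#' @param timecourses components x timepoints numeric matrix (rows are
#'   component time courses).
#' @param labels optional component labels (default row names or indices).
#' @return list of class `fc_matrix`: `z_values` (n x n symmetric, `NA`
#'   diagonal), `labels`.
#' @export
static_fc <- function(timecourses, labels = NULL) {
  x <- as.matrix(timecourses)
  if (ncol(x) < 3L) stop("need at least 3 timepoints")
  sds <- apply(x, 1L, sd)
  if (any(sds == 0)) {
    stop("constant time course for component(s): ",
         paste(which(sds == 0), collapse = ", "))
  }
  if (is.null(labels)) {
    labels <- rownames(x)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  }
  r <- cor(t(x))
  z <- fisher_z(r)
  diag(z) <- NA_real_
  dimnames(z) <- list(labels, labels)
  structure(list(z_values = z, labels = labels), class = "fc_matrix")
}

#' Long-format edge table of an FC matrix
#'
#' @param fc an `fc_matrix`.
#' @return data frame: component_i, component_j, z (upper triangle, i < j).
#' @export
fc_edge_table <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  n <- length(fc$labels)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  data.frame(component_i = fc$labels[idx[, "row"]],
             component_j = fc$labels[idx[, "col"]],
             z = fc$z_values[idx],
             stringsAsFactors = FALSE)
}

#' Write an FC matrix as TSV (square matrix plus long edge table)
#'
#' @param fc an `fc_matrix`.
#' @param path output path for the square matrix; the edge table is written
#'   next to it with suffix `_edges.tsv`.
#' @return `path`, invisibly.
#' @export
write_fc_matrix <- function(fc, path) {
  write.table(fc$z_values, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  write.table(fc_edge_table(fc), sub("\\.tsv$", "_edges.tsv", path),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
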