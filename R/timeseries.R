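#' ROI time-series container
#'
#' A T x N matrix of mean BOLD signal per region of interest, with the
#' sampling interval, a per-row run label (runs are never mixed by temporal
#' filters) and node identifiers.
#'
#' @param values T x N numeric matrix (rows = time points, columns = nodes).
#' @param tr Sampling interval in seconds.
#' @param run_labels Length-T vector identifying the run of each row.
#' @param node_ids Length-N character vector of node identifiers.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, tr,
                           run_labels = rep(1L, nrow(values)),
                           node_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("time-series values must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stopf("time-series values contain missing or non-finite entries")
  if (tr <= 0) stopf("tr must be positive")
  if (length(run_labels) != nrow(values))
    stopf("run_labels length (%d) != number of rows (%d)",
          length(run_labels), nrow(values))
  if (is.null(node_ids)) {
    node_ids <- colnames(values)
    if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(ncol(values)))
  }
  if (length(node_ids) != ncol(values))
    stopf("node_ids length (%d) != number of columns (%d)",
          length(node_ids), ncol(values))
  colnames(values) <- node_ids
  structure(list(values = values, tr = tr,
                 run_labels = as.vector(run_labels),
                 node_ids = as.character(node_ids)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d time points x %d nodes, tr = %gs, %d run(s)\n",
              nrow(x$values), ncol(x$values), x$tr,
              length(unique(x$run_labels))))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$values)

# Apply a per-run transform f(matrix, run_rows) and restack in order.
map_runs <- function(ts, f) {
  out <- ts$values
  for (r in unique(ts$run_labels)) {
    rows <- which(ts$run_labels == r)
    out[rows, ] <- f(ts$values[rows, , drop = FALSE])
  }
  roi_timeseries(out, ts$tr, ts$run_labels, ts$node_ids)
}
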