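#' Write a matrix as TSV with node/module ids
#'
#' @param m Matrix (connectivity, difference or density).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("n%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  utils::write.table(unclass(m), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read a matrix written by [write_matrix()], with validation
#'
#' @param path TSV file with a header row and id column.
#' @param kind `"connectivity"` (symmetric weights), `"difference"`
#'   (validated to {-1, 0, 1}) or `"density"` (validated to \[0, 1\]).
#' @return Numeric matrix; difference matrices carry the
#'   `difference_matrix` class.
#' @export
read_matrix <- function(path, kind = c("connectivity", "difference",
                                       "density")) {
  kind <- match.arg(kind)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character")
  m <- matrix(NA_real_, nrow(raw), ncol(raw),
              dimnames = list(rownames(raw), colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad) > 0)
      stopf("malformed numeric cell at row %d, column %d of %s",
            bad[1], j, path)
    m[, j] <- v
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("missing cell at row %d, column %d of %s", idx[1], idx[2], path)
  }
  if (kind == "difference") {
    bad <- which(!(m %in% c(-1, 0, 1)))
    if (length(bad) > 0) {
      idx <- arrayInd(bad[1], dim(m))
      stopf("difference matrix value %g at row %d, column %d not in {-1, 0, 1}",
            m[bad[1]], idx[1], idx[2])
    }
    storage.mode(m) <- "integer"
    class(m) <- c("difference_matrix", "matrix")
  }
  if (kind == "density") {
    bad <- which(!is.nan(m) & (m < 0 | m > 1))
    if (length(bad) > 0) {
      idx <- arrayInd(bad[1], dim(m))
      stopf("density value %g at row %d, column %d outside [0, 1]",
            m[bad[1]], idx[1], idx[2])
    }
  }
  m
}

#' Write a partition as TSV (node_id, module_id, module_name)
#'
#' @param partition [icn_partition()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  lab <- partition$labels
  d <- data.frame(node_id = partition$node_ids,
                  module_id = ifelse(is.na(lab), "UNASSIGNED", lab),
                  module_name = ifelse(is.na(lab), "UNASSIGNED",
                                       partition$module_names[lab]))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a partition TSV
#'
#' @param path File written by [write_partition()].
#' @return [icn_partition()].
#' @export
read_partition <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  lab <- suppressWarnings(as.integer(d$module_id))
  icn_partition(lab, node_ids = d$node_id)
}

#' Mean ROI time series from a 4D image and an integer-labelled atlas
#'
#' For every atlas label >= 1, averages the image voxels with that label at
#' each volume; columns are ordered by ascending label. Labels with no
#' voxels yield an `NA` column with a warning.
#'
#' @param image Path to a 4D NIfTI volume.
#' @param atlas Path to a 3D integer-labelled NIfTI atlas on the same grid.
#' @param tr Repetition time in seconds (read from the image header when
#'   `NULL`).
#' @param labels Optional integer labels to extract; defaults to all labels
#'   present in the atlas. Requested labels absent from the atlas yield an
#'   `NA` column with a warning.
#' @return A [roi_timeseries()].
#' @export
extract_roi_timeseries <- function(image, atlas, tr = NULL, labels = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("extract_roi_timeseries requires the RNifti package")
  img <- RNifti::readNifti(image)
  atl <- RNifti::readNifti(atlas)
  di <- dim(img); da <- dim(atl)
  if (length(di) != 4) stopf("image must be 4D, got %d dims", length(di))
  if (!identical(di[1:3], da[1:3]))
    stopf("image grid (%s) and atlas grid (%s) differ",
          paste(di[1:3], collapse = "x"), paste(da[1:3], collapse = "x"))
  if (is.null(tr)) {
    pd <- attr(img, "pixdim")
    tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  if (is.null(labels)) labels <- sort(unique(as.integer(atl[atl >= 1])))
  labels <- sort(unique(as.integer(labels)))
  n_t <- di[4]
  vol <- matrix(as.numeric(img), prod(di[1:3]), n_t)
  lab_vec <- as.integer(atl)
  out <- matrix(NA_real_, n_t, length(labels),
                dimnames = list(NULL, sprintf("roi%03d", labels)))
  for (k in seq_along(labels)) {
    vox <- which(lab_vec == labels[k])
    if (length(vox) == 0) {
      warnf("atlas label %d has no voxels; NA column", labels[k])
      next
    }
    out[, k] <- colMeans(vol[vox, , drop = FALSE])
  }
  if (anyNA(out)) {  # keep NA columns for absent labels, bypass validation
    ts <- roi_timeseries(matrix(0, n_t, ncol(out), dimnames = dimnames(out)), tr)
    ts$values <- out
    return(ts)
  }
  roi_timeseries(out, tr)
}

#' Write ROI time series as TSV
#'
#' One row per time point with a leading `run` column, one column per node.
#'
#' @param ts A [roi_timeseries()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  d <- data.frame(run = ts$run_labels, ts$values, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ROI time series written by [write_timeseries()]
#'
#' @param path TSV file with a `run` column.
#' @param tr Sampling interval in seconds.
#' @return A [roi_timeseries()].
#' @export
read_timeseries <- function(path, tr) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE)
  if (!"run" %in% names(d)) stopf("%s lacks a 'run' column", path)
  roi_timeseries(as.matrix(d[setdiff(names(d), "run")]), tr,
                 run_labels = d$run)
}

#' Read a per-node score table (node_id, score)
#'
#' The input format for meta-analytic association scores: a TSV with
#' columns `node_id` and `score`, returned in the order of `node_ids`
#' when given.
#'
#' @param path TSV file.
#' @param node_ids Optional node ordering to match against.
#' @return Named numeric vector of scores.
#' @export
read_node_scores <- function(path, node_ids = NULL) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "numeric"))
  if (!all(c("node_id", "score") %in% names(d)))
    stopf("%s needs columns node_id and score", path)
  scores <- stats::setNames(d$score, d$node_id)
  if (!is.null(node_ids)) {
    if (!all(node_ids %in% names(scores)))
      stopf("scores missing for node(s): %s",
            paste(setdiff(node_ids, names(scores)), collapse = ", "))
    scores <- scores[node_ids]
  }
  scores
}
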