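#' Co-assignment (consensus) matrix from a list of partitions
#'
#' Entry (i, j) is the fraction of runs in which nodes i and j received the
#' same module label; unassigned (`NA`) nodes never co-assign. The diagonal
#' is 1 by convention.
#'
#' @param partitions List of integer membership vectors (NA = unassigned).
#' @return N x N matrix in \[0, 1\] with attribute `n_runs`.
#' @export
coassignment_matrix <- function(partitions) {
  n <- length(partitions[[1]])
  acc <- matrix(0, n, n)
  for (lab in partitions) {
    if (length(lab) != n) stopf("partitions differ in length")
    ok <- !is.na(lab)
    same <- outer(lab, lab, "==")
    same[!ok, ] <- FALSE
    same[, !ok] <- FALSE
    acc <- acc + same
  }
  acc <- acc / length(partitions)
  diag(acc) <- 1
  structure(acc, n_runs = length(partitions))
}

#' Intrinsic-connectivity-network partition
#'
#' @param labels Integer module label per node, `NA` for unassigned.
#' @param node_ids Character node identifiers.
#' @param module_names Optional names per module id.
#' @return Object of class `icn_partition`.
#' @export
icn_partition <- function(labels, node_ids = NULL, module_names = NULL) {
  labels <- as.integer(labels)
  mods <- sort(unique(labels[!is.na(labels)]))
  if (length(mods) > 0 && !identical(mods, seq_along(mods)))
    labels <- match(labels, mods)
  k <- length(mods)
  if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_along(labels))
  if (is.null(module_names)) module_names <- sprintf("ICN%02d", seq_len(k))
  structure(list(labels = labels, node_ids = as.character(node_ids),
                 module_names = module_names, n_modules = k),
            class = "icn_partition")
}

#' @export
print.icn_partition <- function(x, ...) {
  cat(sprintf("<icn_partition> %d nodes, %d modules, %d unassigned\n",
              length(x$labels), x$n_modules, sum(is.na(x$labels))))
  invisible(x)
}

# Canonical string form of a partition (labels renumbered by first
# appearance) so identical partitions compare equal regardless of labels.
canonical_partition <- function(lab) {
  ok <- !is.na(lab)
  lab[ok] <- match(lab[ok], unique(lab[ok]))
  paste(ifelse(is.na(lab), "U", lab), collapse = ".")
}

# Greedy best-overlap relabeling of `lab` onto reference `ref`.
relabel_to <- function(lab, ref) {
  out <- rep(NA_integer_, length(lab))
  ok <- !is.na(lab) & !is.na(ref)
  if (!any(ok)) return(out)
  tab <- table(lab[ok], ref[ok])
  used_r <- used_c <- character(0)
  next_free <- max(ref, na.rm = TRUE)
  map <- stats::setNames(integer(0), character(0))
  while (nrow(tab) > length(used_r) && ncol(tab) > length(used_c)) {
    t2 <- tab
    t2[rownames(tab) %in% used_r, ] <- -1
    t2[, colnames(tab) %in% used_c] <- -1
    idx <- which(t2 == max(t2), arr.ind = TRUE)[1, ]
    map[rownames(tab)[idx[1]]] <- as.integer(colnames(tab)[idx[2]])
    used_r <- c(used_r, rownames(tab)[idx[1]])
    used_c <- c(used_c, colnames(tab)[idx[2]])
  }
  for (r in setdiff(rownames(tab), used_r)) {
    next_free <- next_free + 1L
    map[r] <- next_free
  }
  out[!is.na(lab)] <- unname(map[as.character(lab[!is.na(lab)])])
  out
}

#' Group consensus clustering of subject connectomes
#'
#' Per subject: proportional-threshold the Fisher-z partial-correlation
#' matrix at `subject_cost`, run the map-equation detector `subject_runs`
#' times, and build the co-assignment matrix. Average co-assignment matrices
#' across subjects, threshold the average at `group_threshold`, run the
#' detector `group_runs` times on it, and return the modal partition. A node
#' is unassigned when it is isolated after group thresholding or when its
#' module agrees with the modal partition in fewer than half of the group
#' runs.
#'
#' @param matrices List of per-subject `connectivity_matrix` objects
#'   sharing node ids.
#' @param subject_cost Proportional threshold for subject matrices.
#' @param subject_runs Detector runs per subject.
#' @param group_threshold Proportional threshold for the averaged consensus
#'   matrix.
#' @param group_runs Detector runs on the group matrix.
#' @param seed Integer seed.
#' @return An [icn_partition()] with attributes `consensus` (group
#'   consensus matrix) and `stability` (per-node modal agreement rate).
#' @export
consensus_cluster <- function(matrices, subject_cost = 0.035,
                              subject_runs = 50, group_threshold = 0.07,
                              group_runs = 100, seed = 1L) {
  if (length(matrices) < 2) stopf("need at least 2 subjects")
  ids <- attr(matrices[[1]], "node_ids")
  if (is.null(ids)) ids <- colnames(matrices[[1]])
  for (m in matrices) {
    mi <- attr(m, "node_ids")
    if (is.null(mi)) mi <- colnames(m)
    if (!identical(mi, ids)) stopf("node ids differ across subjects")
  }
  cons <- vector("list", length(matrices))
  for (s in seq_along(matrices)) {
    thr <- proportional_threshold(matrices[[s]], subject_cost)
    runs <- detect_communities(thr, subject_runs, child_seed(seed, s))
    cons[[s]] <- coassignment_matrix(runs)
  }
  avg <- Reduce("+", cons) / length(cons)
  diag(avg) <- 0
  gthr <- proportional_threshold(avg, group_threshold)
  gruns <- detect_communities(gthr, group_runs, child_seed(seed, 999999))
  keys <- vapply(gruns, canonical_partition, character(1))
  modal <- gruns[[which(keys == names(which.max(table(keys))))[1]]]
  aligned <- vapply(gruns, relabel_to, integer(length(modal)), ref = modal)
  agree <- rowMeans(aligned == modal, na.rm = FALSE)
  agree[is.na(agree)] <- rowMeans(aligned == modal, na.rm = TRUE)[is.na(agree)]
  labels <- modal
  labels[is.na(agree) | agree < 0.5] <- NA_integer_
  labels[rowSums(gthr) == 0] <- NA_integer_
  part <- icn_partition(labels, node_ids = ids)
  attr(part, "consensus") <- avg
  attr(part, "stability") <- agree
  part
}
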