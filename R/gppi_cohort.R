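#' Per-subject gPPI beta stack over all seeds
#'
#' Runs the full seed-wise gPPI estimation for one subject: per session the
#' target series and nuisance table are high-pass filtered, a pooled AR(1)
#' coefficient is estimated from the residuals of the condition + nuisance
#' GLM, seeds are adjusted for the effects of interest, and every seed's
#' gPPI design is fitted (after quasi-differencing data and design) against
#' all other nodes.
#'
#' @param scan A `task_scan` (see [generate_task_timeseries()]): list with
#'   `ts`, `nuisance`, `design`.
#' @param hrf [hrf_params()].
#' @param lambda Deconvolution ridge penalty.
#' @param highpass_s High-pass cutoff in seconds (applied to data and seed
#'   time courses alike).
#' @param deconvolve_seed Passed to [build_gppi_design()].
#' @return Array seed x target x condition x session of interaction betas
#'   (`NA` on the seed = target diagonal).
#' @export
gppi_subject_betas <- function(scan, hrf = hrf_params(), lambda = 0.01,
                               highpass_s = 200, deconvolve_seed = TRUE) {
  ts <- scan$ts
  designs <- scan$designs %||% list(scan$design)
  sessions <- unique(ts$run_labels)
  n <- ncol(ts$values)
  conds <- unique(designs[[1]]$condition)
  out <- array(NA_real_, c(n, n, length(conds), length(sessions)),
               dimnames = list(ts$node_ids, ts$node_ids, conds, NULL))
  for (si in seq_along(sessions)) {
    design <- designs[[min(si, length(designs))]]
    n_vol <- attr(design, "n_volumes")
    rows <- ts$run_labels == sessions[si]
    y <- roi_timeseries(ts$values[rows, , drop = FALSE], ts$tr)
    nuis <- if (is.null(scan$nuisance)) NULL else
      highpass_matrix(scan$nuisance[rows, , drop = FALSE], ts$tr, highpass_s)
    yf <- highpass_dct(y, highpass_s)
    x0 <- build_design(design, nuisance = nuis, hrf = hrf, n_sessions = 1)
    resid <- yf$values - x0 %*% qr.coef(qr(x0), yf$values)
    rho <- stats::median(lag1_rho(resid, rep(1L, nrow(resid))))
    adj <- adjust_for_effects(yf, x0, attr(x0, "condition_cols"))
    one_run <- rep(1L, n_vol)
    wy <- quasi_difference(yf$values, one_run, rho)
    for (s in seq_len(n)) {
      xs <- build_gppi_design(adj$values[, s], design, nuisance = nuis,
                              hrf = hrf, lambda = lambda,
                              deconvolve_seed = deconvolve_seed)
      wx <- quasi_difference(xs, one_run, rho)
      attr(wx, "ppi_cols") <- attr(xs, "ppi_cols")
      colnames(wx) <- colnames(xs)
      betas <- fit_gppi_all_targets(s, wy, wx)
      for (ci in seq_along(conds))
        out[s, , ci, si] <- betas[paste0("ppi.", conds[ci]), ]
    }
  }
  attr(out, "rho_pooled") <- rho
  out
}

#' Group difference matrix from a cohort of task scans
#'
#' Convenience driver: estimates every subject's gPPI beta stack and reduces
#' them to the signed directed difference matrix. Nodes left unassigned by
#' the partition (if one is given) are dropped before group statistics, so
#' the matrix covers classified nodes only.
#'
#' @param task_scans List of `task_scan` objects (one per subject).
#' @param partition Optional [icn_partition()]; unassigned nodes are
#'   dropped.
#' @param contrast,alpha Passed to [difference_matrix()].
#' @param ... Passed to [gppi_subject_betas()].
#' @return A `difference_matrix` with attribute `kept_nodes` (indices into
#'   the original node set).
#' @export
gppi_difference <- function(task_scans, partition = NULL,
                            contrast = c(emotion = 1, shape = -1),
                            alpha = 0.05, ...) {
  stacks <- lapply(task_scans, gppi_subject_betas, ...)
  keep <- seq_len(dim(stacks[[1]])[1])
  if (!is.null(partition)) {
    keep <- which(!is.na(partition$labels))
    stacks <- lapply(stacks, function(a) a[keep, keep, , , drop = FALSE])
  }
  d <- difference_matrix(stacks, contrast = contrast, alpha = alpha)
  attr(d, "kept_nodes") <- keep
  d
}
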