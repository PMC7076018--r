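#' First-level GLM design matrix
#'
#' Builds condition boxcars at the TR, convolves them with the canonical
#' HRF, and appends unconvolved motion regressors, their first temporal
#' derivatives (first differences, zero-padded at each session start) and
#' one constant per session.
#'
#' @param design A `task_design` (one session layout, reused for every
#'   session) or a list of per-session designs (e.g. counterbalanced
#'   block orders).
#' @param nuisance T x M matrix of motion-like regressors (all sessions
#'   stacked), or `NULL`.
#' @param hrf [hrf_params()].
#' @param n_sessions Number of sessions; rows of `nuisance` must equal
#'   `n_sessions * n_volumes`.
#' @param cue_handling Passed to [condition_boxcar()]: `"merge"` (default)
#'   models the cue as part of its block.
#' @return Design matrix with attributes `roles` (column roles) and
#'   `condition_cols` (indices of convolved condition columns, named
#'   `<condition>.s<session>`).
#' @export
build_design <- function(design, nuisance = NULL, hrf = hrf_params(),
                         n_sessions = 1,
                         cue_handling = c("merge", "ignore", "separate")) {
  cue_handling <- match.arg(cue_handling)
  designs <- if (is.list(design) && !inherits(design, "task_design")) {
    if (length(design) != n_sessions)
      stopf("need %d per-session designs, got %d", n_sessions, length(design))
    design
  } else rep(list(design), n_sessions)
  tr <- attr(designs[[1]], "tr")
  n_vol <- attr(designs[[1]], "n_volumes")
  convs <- lapply(designs, function(d) {
    for (cond in unique(d$condition)) {
      dd <- d[d$condition == cond, , drop = FALSE]
      dd <- dd[order(dd$onset), , drop = FALSE]
      if (nrow(dd) > 1 &&
          any(dd$onset[-1] < (dd$onset + dd$duration)[-nrow(dd)]))
        stopf("overlapping '%s' blocks in task design", cond)
    }
    box <- condition_boxcar(d, n_volumes = n_vol, cue_handling = cue_handling)
    convolve_hrf(box, hrf, tr)
  })
  n_cond <- ncol(convs[[1]])
  t_total <- n_sessions * n_vol
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != t_total)
      stopf("nuisance rows (%d) != %d sessions x %d volumes",
            nrow(nuisance), n_sessions, n_vol)
  }
  cond_cols <- matrix(0, t_total, n_cond * n_sessions)
  cn <- character(ncol(cond_cols))
  for (s in seq_len(n_sessions)) {
    conv <- convs[[s]]
    # keep a fixed condition column order regardless of block order
    if (n_cond > 0) conv <- conv[, order(colnames(conv)), drop = FALSE]
    rows <- (s - 1) * n_vol + seq_len(n_vol)
    cols <- (s - 1) * n_cond + seq_len(n_cond)
    cond_cols[rows, cols] <- conv
    cn[cols] <- sprintf("%s.s%d", colnames(conv), s)
  }
  colnames(cond_cols) <- cn
  consts <- matrix(0, t_total, n_sessions,
                   dimnames = list(NULL, sprintf("const.s%d", seq_len(n_sessions))))
  for (s in seq_len(n_sessions))
    consts[(s - 1) * n_vol + seq_len(n_vol), s] <- 1
  x <- cond_cols
  roles <- rep("condition", ncol(cond_cols))
  if (!is.null(nuisance) && ncol(nuisance) > 0) {
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- sprintf("mot%d", seq_len(ncol(nuisance)))
    dmot <- apply(nuisance, 2, function(col) c(0, diff(col)))
    for (s in seq_len(n_sessions))   # derivative must not bridge sessions
      dmot[(s - 1) * n_vol + 1, ] <- 0
    colnames(dmot) <- paste0("d.", colnames(nuisance))
    x <- cbind(x, nuisance, dmot)
    roles <- c(roles, rep("motion", ncol(nuisance)),
               rep("motion_derivative", ncol(dmot)))
  }
  x <- cbind(x, consts)
  roles <- c(roles, rep("constant", n_sessions))
  q <- qr(x)
  if (q$rank < ncol(x)) {
    bad <- colnames(x)[q$pivot[(q$rank + 1):ncol(x)]]
    stopf("design matrix is rank deficient; dependent columns: %s",
          paste(bad, collapse = ", "))
  }
  structure(x, roles = roles,
            condition_cols = which(roles == "condition"))
}

#' First-level contrast fit
#'
#' OLS fit of a (prewhitened) design to every node, with a t test for the
#' given contrast of regression coefficients.
#'
#' @param ts A [roi_timeseries()] (after prewhitening).
#' @param x Design matrix (after the same prewhitening transform).
#' @param contrast Numeric contrast weights, length `ncol(x)`.
#' @return `contrast_result` data frame with per-node `beta` (contrast
#'   estimate), `t`, `p`, `df`; the full coefficient matrix is kept in
#'   attribute `coefficients`.
#' @export
fit_first_level <- function(ts, x, contrast) {
  y <- if (inherits(ts, "roi_timeseries")) ts$values else as.matrix(ts)
  x <- as.matrix(x)
  if (length(contrast) != ncol(x))
    stopf("contrast length (%d) != design columns (%d)",
          length(contrast), ncol(x))
  q <- qr(x)
  if (q$rank < ncol(x)) stopf("design matrix is rank deficient")
  beta <- qr.coef(q, y)
  resid <- y - x %*% beta
  df <- nrow(x) - q$rank
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(chol(crossprod(x)))
  cvar <- drop(t(contrast) %*% xtx_inv %*% contrast)
  est <- drop(crossprod(contrast, beta))
  if (cvar <= 0 || all(contrast == 0)) {
    tstat <- rep(0, length(est)); pval <- rep(1, length(est))
  } else {
    tstat <- est / sqrt(cvar * sigma2)
    pval <- 2 * stats::pt(-abs(tstat), df)
  }
  out <- data.frame(node = colnames(y) %||% seq_along(est),
                    beta = est, t = tstat, p = pval, df = df)
  attr(out, "coefficients") <- beta
  class(out) <- c("contrast_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group-level ICN activation summary
#'
#' For each module of the partition, averages node-level contrast estimates
#' within the module per subject, then tests the across-subject mean with a
#' two-sided one-sample t test, Bonferroni-corrected over the number of
#' modules.
#'
#' @param betas Subjects x nodes matrix of contrast estimates (or a list of
#'   `contrast_result` objects).
#' @param partition An [icn_partition()]; unassigned nodes are ignored.
#' @return Data frame with per-module `mean`, `se`, `t`, `df`, `p`,
#'   `p_bonferroni`.
#' @export
group_icn_activation <- function(betas, partition) {
  if (is.list(betas) && !is.matrix(betas))
    betas <- do.call(rbind, lapply(betas, function(b) b$beta))
  betas <- as.matrix(betas)
  if (nrow(betas) < 3) stopf("need at least 3 subjects")
  lab <- partition$labels
  k <- partition$n_modules
  rows <- lapply(seq_len(k), function(m) {
    idx <- which(!is.na(lab) & lab == m)
    if (length(idx) == 0) {
      warnf("module %d has no nodes; skipped", m)
      return(NULL)
    }
    x <- rowMeans(betas[, idx, drop = FALSE])
    se <- stats::sd(x) / sqrt(length(x))
    if (se == 0) {  # degenerate: constant subject means
      tt <- ifelse(mean(x) == 0, 0, sign(mean(x)) * Inf)
      pp <- ifelse(mean(x) == 0, 1, 0)
    } else {
      tt <- mean(x) / se
      pp <- 2 * stats::pt(-abs(tt), length(x) - 1)
    }
    data.frame(module = m, n_nodes = length(idx), mean = mean(x),
               se = se, t = tt, df = length(x) - 1,
               p = pp, p_bonferroni = min(1, pp * k))
  })
  do.call(rbind, rows)
}
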