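# Cache of deconvolution operators keyed by (T, tr, lambda, hrf params):
# building B (C'C + lambda I)^-1 C' costs O(T^3) and is reused constantly.
.gppi_cache <- new.env(parent = emptyenv())

deconv_operator <- function(n_time, tr, hrf, lambda) {
  key <- paste(n_time, tr, lambda, hrf$peak_s, hrf$undershoot_s, hrf$ratio,
               hrf$length_s, sep = "_")
  hit <- .gppi_cache[[key]]
  if (!is.null(hit)) return(hit)
  b <- cbind(rep(1 / sqrt(n_time), n_time), dct_basis(n_time, n_time - 1))
  h <- conv_matrix(hrf_kernel(hrf, tr), n_time)
  cc <- h %*% b
  lam <- lambda * mean(diag(crossprod(cc)))
  op <- b %*% solve(crossprod(cc) + diag(lam, n_time), t(cc))
  .gppi_cache[[key]] <- list(op = op, h = h)
  .gppi_cache[[key]]
}

#' Deconvolve BOLD to a neural-level series
#'
#' Ridge-regularized least-squares estimate of the latent series n such that
#' `HRF * n ~ bold`, with n represented on an orthonormal discrete-cosine
#' basis. The relative ridge penalty `lambda` scales the mean diagonal of
#' the normal equations, so `lambda = 0` is the unregularized solve and
#' `lambda -> Inf` shrinks the output to zero.
#'
#' @param bold Numeric vector or T x N matrix (single run).
#' @param hrf [hrf_params()].
#' @param tr Sampling interval in seconds.
#' @param lambda Relative ridge penalty (default 0.01).
#' @return Neural series of the same shape, with attribute `r_squared`
#'   (reconvolution R^2 per column).
#' @export
deconvolve <- function(bold, hrf = hrf_params(), tr, lambda = 0.01) {
  x <- if (is.matrix(bold)) bold else matrix(bold, ncol = 1)
  if (any(!is.finite(x))) stopf("non-finite values in BOLD input")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) warnf("zero-variance BOLD input: deconvolved to zero")
  dec <- deconv_operator(nrow(x), tr, hrf, lambda)
  neural <- dec$op %*% x
  neural[, v == 0] <- 0
  recon <- dec$h %*% neural
  ss_res <- colSums((x - recon)^2)
  ss_tot <- colSums(sweep(x, 2, colMeans(x))^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 0)
  out <- if (is.matrix(bold)) neural else drop(neural)
  attr(out, "r_squared") <- r2
  out
}

#' Generalized PPI design matrix for one seed
#'
#' Columns, in order: one PPI interaction column per condition
#' (`HRF * (deconvolved seed x condition boxcar)`), the seed BOLD time
#' course, the HRF-convolved condition regressors, the unconvolved nuisance
#' regressors with their first temporal derivatives, and a constant. The
#' generalized form requires the full condition set (>= 2 conditions).
#'
#' @param seed_ts Numeric vector: the prepared (filtered, adjusted) seed
#'   time course for a single session.
#' @param design A `task_design`.
#' @param nuisance T x M nuisance matrix for the session (or `NULL`).
#' @param hrf [hrf_params()].
#' @param lambda Deconvolution ridge penalty.
#' @param deconvolve_seed If `FALSE`, PPI terms are formed directly from the
#'   BOLD seed times the boxcar (no deconvolution round trip).
#' @return Design matrix with attribute `roles`; PPI columns are named
#'   `ppi.<condition>`.
#' @export
build_gppi_design <- function(seed_ts, design, nuisance = NULL,
                              hrf = hrf_params(), lambda = 0.01,
                              deconvolve_seed = TRUE) {
  tr <- attr(design, "tr")
  n_vol <- attr(design, "n_volumes")
  seed_ts <- as.numeric(seed_ts)
  if (length(seed_ts) != n_vol)
    stopf("seed series length (%d) != session volumes (%d)",
          length(seed_ts), n_vol)
  box <- condition_boxcar(design, n_volumes = n_vol, cue_handling = "merge")
  if (ncol(box) < 2)
    stopf("gPPI requires the full condition set (>= 2 conditions), got %d",
          ncol(box))
  neural <- if (deconvolve_seed) {
    as.numeric(deconvolve(seed_ts, hrf, tr, lambda))
  } else seed_ts
  ppi <- convolve_hrf(neural * box, hrf, tr)
  colnames(ppi) <- paste0("ppi.", colnames(box))
  conv <- convolve_hrf(box, hrf, tr)
  colnames(conv) <- paste0("task.", colnames(box))
  x <- cbind(ppi, seed = seed_ts, conv)
  roles <- c(rep("ppi", ncol(ppi)), "seed", rep("condition", ncol(conv)))
  if (!is.null(nuisance) && ncol(as.matrix(nuisance)) > 0) {
    nuisance <- as.matrix(nuisance)
    dmot <- apply(nuisance, 2, function(col) c(0, diff(col)))
    x <- cbind(x, nuisance, dmot)
    roles <- c(roles, rep("motion", ncol(nuisance)),
               rep("motion_derivative", ncol(dmot)))
  }
  x <- cbind(x, const = 1)
  roles <- c(roles, "constant")
  structure(x, roles = roles, ppi_cols = which(roles == "ppi"))
}

#' Fit a seed's gPPI model against all target nodes
#'
#' One OLS fit per target node (all solved in a single decomposition); the
#' interaction-term coefficients are returned per condition. The seed column
#' itself is skipped (`NA`).
#'
#' @param seed Seed node index.
#' @param targets T x N matrix of prepared target time series (same
#'   whitening transform as `x`).
#' @param x gPPI design from [build_gppi_design()] (whitened).
#' @return Conditions x N matrix of interaction betas (`NA` at the seed).
#' @export
fit_gppi_all_targets <- function(seed, targets, x) {
  targets <- as.matrix(targets)
  q <- qr(x)
  if (q$rank < ncol(x))
    stopf("gPPI design for seed %d is rank deficient", seed)
  beta <- qr.coef(q, targets)
  ppi_rows <- attr(x, "ppi_cols")
  out <- beta[ppi_rows, , drop = FALSE]
  rownames(out) <- colnames(x)[ppi_rows]
  out[, seed] <- NA_real_
  out
}

#' Edge-wise Bonferroni bookkeeping
#'
#' @param n_nodes Number of nodes.
#' @param alpha Family-wise level.
#' @return List with `n_tests` (= N(N-1) ordered pairs) and `threshold`
#'   (= alpha / n_tests).
#' @export
edgewise_threshold <- function(n_nodes, alpha = 0.05) {
  n_tests <- n_nodes * (n_nodes - 1)
  list(n_tests = n_tests, threshold = alpha / n_tests)
}

#' Group-level signed difference matrix from PPI beta stacks
#'
#' Per ordered node pair, forms the per-subject condition contrast of the
#' interaction betas (averaged over sessions with the given weights), tests
#' it against zero with a two-sided one-sample t test across subjects, and
#' thresholds at `alpha / (N (N-1))`. Significant increases are flagged +1,
#' decreases -1, the rest 0.
#'
#' @param stacks List (one element per subject) of arrays with dimensions
#'   seed x target x condition x session.
#' @param contrast Named condition weights (default
#'   `c(emotion = 1, shape = -1)`).
#' @param session_weights Weights over sessions (default equal).
#' @param alpha Family-wise level.
#' @return `difference_matrix`: N x N matrix in {-1, 0, 1} with attributes
#'   `alpha`, `n_tests`, `threshold`, `t`, `p`.
#' @export
difference_matrix <- function(stacks, contrast = c(emotion = 1, shape = -1),
                              session_weights = NULL, alpha = 0.05) {
  if (length(stacks) < 3) stopf("need at least 3 subjects")
  dm <- dim(stacks[[1]])
  n <- dm[1]
  if (dm[2] != n) stopf("beta stacks must be square in seed x target")
  conds <- dimnames(stacks[[1]])[[3]]
  if (is.null(conds)) conds <- names(contrast)
  if (!all(names(contrast) %in% conds))
    stopf("contrast conditions %s not all present in stacks",
          paste(names(contrast), collapse = ", "))
  n_sess <- dm[4]
  if (is.null(session_weights)) session_weights <- rep(1 / n_sess, n_sess)
  cons <- lapply(stacks, function(a) {
    if (!identical(dim(a), dm)) stopf("beta stacks differ in shape")
    con <- matrix(0, n, n)
    for (ci in seq_along(contrast)) {
      cidx <- match(names(contrast)[ci], conds)
      for (s in seq_len(n_sess))
        con <- con + contrast[ci] * session_weights[s] * a[, , cidx, s]
    }
    con
  })
  off <- !diag(TRUE, n)
  complete <- vapply(cons, function(con) all(is.finite(con[off])), logical(1))
  if (any(!complete)) {
    message(sprintf("difference_matrix: excluding %d subject(s) with missing nodes: %s",
                    sum(!complete), paste(which(!complete), collapse = ", ")))
    cons <- cons[complete]
  }
  if (length(cons) < 3) stopf("fewer than 3 subjects with complete coverage")
  subj <- simplify2array(cons)
  n_subj <- length(cons)
  mean_c <- apply(subj, c(1, 2), mean)
  sd_c <- apply(subj, c(1, 2), stats::sd)
  tmat <- mean_c / (sd_c / sqrt(n_subj))
  df <- n_subj - 1
  pmat <- 2 * stats::pt(-abs(tmat), df)
  bk <- edgewise_threshold(n, alpha)
  out <- matrix(0L, n, n)
  sig <- !is.na(pmat) & pmat < bk$threshold
  out[sig] <- as.integer(sign(mean_c[sig]))
  diag(out) <- 0L
  dimnames(out) <- dimnames(stacks[[1]])[1:2]
  structure(out, alpha = alpha, n_tests = bk$n_tests,
            threshold = bk$threshold, t = tmat, p = pmat,
            class = c("difference_matrix", "matrix"))
}
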