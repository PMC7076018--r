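#' Orthonormal DCT-II basis
#'
#' Discrete cosine basis used for drift modelling, band-pass projection and
#' the deconvolution representation. Component `r` has frequency
#' `r / (2 * T * tr)` Hz. All columns are orthonormal and orthogonal to the
#' constant vector.
#'
#' @param n_time Number of time points.
#' @param k Number of components (1..k).
#' @return `n_time` x `k` matrix.
#' @export
dct_basis <- function(n_time, k) {
  stopifnot(n_time >= 2, k >= 1, k <= n_time - 1)
  t <- 0:(n_time - 1)
  b <- vapply(seq_len(k),
              function(r) cos(pi * (2 * t + 1) * r / (2 * n_time)),
              numeric(n_time))
  sweep(b, 2, sqrt(colSums(b^2)), "/")
}

#' Band-pass filter ROI time series
#'
#' Projects each run onto the discrete-cosine components whose frequencies
#' fall inside `[low_hz, high_hz]` after removing the column mean, so power
#' outside the passband is attenuated and the output has zero mean. Runs are
#' filtered independently.
#'
#' @param ts A [roi_timeseries()].
#' @param low_hz,high_hz Passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr)` (the Nyquist frequency).
#' @return Filtered [roi_timeseries()].
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1) {
  nyq <- 1 / (2 * ts$tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stopf("passband [%g, %g] Hz outside (0, Nyquist = %g) Hz",
          low_hz, high_hz, nyq)
  map_runs(ts, function(x) {
    n <- nrow(x)
    freq <- seq_len(n - 1) / (2 * n * ts$tr)
    keep <- which(freq >= low_hz & freq <= high_hz)
    xc <- sweep(x, 2, colMeans(x))
    if (length(keep) == 0) return(xc * 0)
    b <- dct_basis(n, max(keep))[, keep, drop = FALSE]
    b %*% crossprod(b, xc)
  })
}

#' High-pass filter by discrete-cosine residualization
#'
#' Removes, per run, a drift basis consisting of the mean, a linear trend
#' and the `k = floor(2 T tr / cutoff_s)` slowest discrete-cosine
#' components — the standard drift model for task fMRI (the explicit linear
#' term makes detrending exact rather than approximate).
#'
#' @param ts A [roi_timeseries()].
#' @param cutoff_s Cutoff period in seconds; must exceed `2 tr`.
#' @return Filtered [roi_timeseries()].
#' @export
highpass_dct <- function(ts, cutoff_s = 200) {
  if (cutoff_s <= 2 * ts$tr)
    stopf("cutoff_s = %g s must exceed 2 * tr = %g s", cutoff_s, 2 * ts$tr)
  warned <- FALSE
  out <- map_runs(ts, function(x) {
    n <- nrow(x)
    k <- floor(2 * n * ts$tr / cutoff_s)
    if (k < 1 && !warned) {
      warned <<- TRUE
      warnf("cutoff %g s defines no cosine basis function for a %d-point run; removing mean and trend only",
            cutoff_s, n)
    }
    x - drift_basis(n, k) %*% crossprod(drift_basis(n, k), x)
  })
  out
}

# Orthonormal drift basis: mean, linear trend, k slowest DCT components.
drift_basis <- function(n, k) {
  lin <- seq_len(n) - (n + 1) / 2
  base <- cbind(rep(1 / sqrt(n), n), lin / sqrt(sum(lin^2)))
  if (k >= 1) base <- cbind(base, dct_basis(n, k))
  qr.Q(qr(base))[, seq_len(ncol(base)), drop = FALSE]
}

# High-pass an arbitrary matrix with the same basis (nuisance regressors).
highpass_matrix <- function(x, tr, cutoff_s = 200) {
  n <- nrow(x)
  k <- floor(2 * n * tr / cutoff_s)
  b <- drift_basis(n, k)
  x - b %*% crossprod(b, x)
}

# Lag-1 autocorrelation of residual columns, respecting run boundaries.
lag1_rho <- function(resid, run_labels) {
  num <- 0; den <- 0
  acc <- function(r) {
    if (nrow(r) < 3) return(NULL)
    num <<- num + colSums(r[-1, , drop = FALSE] * r[-nrow(r), , drop = FALSE])
    den <<- den + colSums(r[-nrow(r), , drop = FALSE]^2)
  }
  for (rl in unique(run_labels)) acc(resid[run_labels == rl, , drop = FALSE])
  rho <- num / pmax(den, .Machine$double.eps)
  pmin(pmax(rho, -0.99), 0.99)
}

# Quasi-difference rows of x by rho per run, dropping the first row per run.
quasi_difference <- function(x, run_labels, rho) {
  pieces <- lapply(unique(run_labels), function(rl) {
    xr <- x[run_labels == rl, , drop = FALSE]
    xr[-1, , drop = FALSE] - rho * xr[-nrow(xr), , drop = FALSE]
  })
  do.call(rbind, pieces)
}

#' AR(1) prewhitening of data and design (Cochrane-Orcutt)
#'
#' Fits `design` to each node by OLS, estimates the lag-1 autocorrelation of
#' the residuals per node (or pooled across nodes), and applies the
#' quasi-differencing transform `x_t - rho x_{t-1}` to both the data and the
#' design, dropping the first row of each run.
#'
#' @param ts A [roi_timeseries()].
#' @param design T x P numeric design matrix with full column rank.
#' @param pool If `TRUE`, a single median rho is used for all nodes (and a
#'   single transformed design is returned); if `FALSE` (default) each node
#'   keeps its own rho and `design` becomes a T' x P x N array.
#' @return List with elements `ts` (whitened [roi_timeseries()]), `design`
#'   (matrix if pooled, array otherwise), `rho` (per-node coefficients) and
#'   `run_labels` of the retained rows.
#' @export
prewhiten_ar1 <- function(ts, design, pool = FALSE) {
  design <- as.matrix(design)
  if (nrow(design) != nrow(ts$values))
    stopf("design rows (%d) != time points (%d)", nrow(design), nrow(ts$values))
  q <- qr(design)
  if (q$rank < ncol(design)) {
    bad <- colnames(design)[q$pivot[(q$rank + 1):ncol(design)]]
    if (is.null(bad)) bad <- q$pivot[(q$rank + 1):ncol(design)]
    stopf("design is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  resid <- ts$values - design %*% qr.coef(q, ts$values)
  rho <- lag1_rho(resid, ts$run_labels)
  keep <- unlist(lapply(unique(ts$run_labels), function(rl) {
    idx <- which(ts$run_labels == rl); idx[-1]
  }))
  new_labels <- ts$run_labels[keep]
  if (pool) {
    r <- stats::median(rho)
    wy <- quasi_difference(ts$values, ts$run_labels, r)
    wx <- quasi_difference(design, ts$run_labels, r)
    rho[] <- r
  } else {
    wy <- vapply(seq_len(ncol(ts$values)), function(j)
      drop(quasi_difference(ts$values[, j, drop = FALSE], ts$run_labels, rho[j])),
      numeric(length(keep)))
    colnames(wy) <- ts$node_ids
    wx <- array(NA_real_, c(length(keep), ncol(design), ncol(ts$values)),
                dimnames = list(NULL, colnames(design), ts$node_ids))
    for (j in seq_len(ncol(ts$values)))
      wx[, , j] <- quasi_difference(design, ts$run_labels, rho[j])
  }
  list(ts = roi_timeseries(wy, ts$tr, new_labels, ts$node_ids),
       design = wx, rho = rho, run_labels = new_labels)
}

#' Remove nuisance effects, keeping effects of interest
#'
#' Fits the full design by OLS and returns the fitted effects-of-interest
#' plus residuals, i.e. the data with the nuisance partition of the design
#' projected out — the standard seed-adjustment step before forming PPI
#' terms.
#'
#' @param ts A [roi_timeseries()].
#' @param design T x P design matrix.
#' @param effects_of_interest Integer column indices of the design columns to
#'   keep; all other columns are removed from the data.
#' @return Adjusted [roi_timeseries()].
#' @export
adjust_for_effects <- function(ts, design, effects_of_interest) {
  design <- as.matrix(design)
  p <- ncol(design)
  if (length(effects_of_interest) == 0) {
    warnf("empty effects-of-interest set; returning pure residuals")
  } else if (!all(effects_of_interest %in% seq_len(p))) {
    stopf("effects_of_interest outside design columns 1..%d", p)
  }
  beta <- qr.coef(qr(design), ts$values)
  beta[is.na(beta)] <- 0
  nuis <- setdiff(seq_len(p), effects_of_interest)
  adj <- ts$values - design[, nuis, drop = FALSE] %*% beta[nuis, , drop = FALSE]
  roi_timeseries(adj, ts$tr, ts$run_labels, ts$node_ids)
}
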