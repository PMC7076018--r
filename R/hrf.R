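#' Canonical double-gamma hemodynamic response function
#'
#' Parameters of the canonical HRF: a positive gamma density peaking at
#' `peak_s`, minus an undershoot gamma peaking at `undershoot_s`, scaled by
#' `1/ratio`, truncated at `length_s` and discretized at the repetition time.
#'
#' @param peak_s Peak delay in seconds.
#' @param undershoot_s Undershoot delay in seconds.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param length_s Kernel length in seconds.
#' @return An object of class `hrf` (a parameter list).
#' @export
hrf_params <- function(peak_s = 6, undershoot_s = 16, ratio = 6,
                       length_s = 32) {
  stopifnot(peak_s > 0, undershoot_s > peak_s, ratio > 0, length_s > 0)
  structure(list(peak_s = peak_s, undershoot_s = undershoot_s,
                 ratio = ratio, length_s = length_s),
            class = "hrf")
}

#' Discretized HRF kernel
#'
#' Samples the double-gamma response at interval `tr` over the kernel length
#' and normalizes it to unit peak. The kernel integrates to a positive value.
#'
#' @param hrf An [hrf_params()] object.
#' @param tr Sampling interval (repetition time) in seconds.
#' @return Numeric vector of kernel weights.
#' @export
hrf_kernel <- function(hrf = hrf_params(), tr) {
  stopifnot(inherits(hrf, "hrf"), tr > 0)
  t <- seq(0, hrf$length_s, by = tr)
  # gamma densities with scale 1: shape = delay + 1 puts the mode at `delay`
  h <- stats::dgamma(t, shape = hrf$peak_s + 1, rate = 1) -
    stats::dgamma(t, shape = hrf$undershoot_s + 1, rate = 1) / hrf$ratio
  h / max(h)
}

#' Convolve a signal with the HRF
#'
#' Causal discrete convolution with the HRF kernel, truncated to the input
#' length. Accepts a vector or a column matrix (each column convolved).
#'
#' @param x Numeric vector or T x N matrix of neural-level signals.
#' @param hrf An [hrf_params()] object.
#' @param tr Sampling interval in seconds.
#' @return Object of the same shape as `x`.
#' @export
convolve_hrf <- function(x, hrf = hrf_params(), tr) {
  k <- hrf_kernel(hrf, tr)
  if (is.matrix(x) && ncol(x) == 0) return(x)
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col)
      stats::convolve(col, rev(k), type = "open")[seq_along(col)])
    dimnames(out) <- dimnames(x)
    out
  } else {
    stats::convolve(x, rev(k), type = "open")[seq_along(x)]
  }
}

# Lower-triangular Toeplitz convolution operator for batched convolution:
# conv_matrix(k, T) %*% X convolves every column of X with kernel k.
conv_matrix <- function(kernel, n) {
  m <- matrix(0, n, n)
  for (i in seq_along(kernel)) {
    if (i > n) break
    idx <- seq_len(n - i + 1)
    m[cbind(idx + i - 1, idx)] <- kernel[i]
  }
  m
}
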