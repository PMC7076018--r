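#' Evaluate an expression under a local RNG state
#'
#' Runs `expr` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards, so that seeded generators never disturb a caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a bounded child seed from a master seed and a stream index, so every
# pipeline stage gets an independent, reproducible substream (< 2^31).
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483629 + 1
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same nodes.
#' Pairs where either labeling is `NA` (unassigned nodes) are dropped.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return Numeric scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stopf("labelings differ in length")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maximum - expected)
}
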