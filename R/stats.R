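# Cohort correlation statistics.
#
# Spearman's rank correlation is implemented from first principles (average
# ranks, exact permutation p-value for small n, t approximation otherwise)
# because the exact small-cohort null matters for n ~ 15 EEG studies;
# Pearson's r uses the closed form with the t reference distribution.

# All n! permutations of 1..n as an (n! x n) integer matrix, lexicographic.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- seq_len(n)[-first]
    block <- cbind(first, matrix(rest[sub], nrow = nrow(sub)))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes rho from average ranks (equal to `1 - 6*sum(d^2)/(n*(n^2-1))`
#' when there are no ties) with a two-sided p-value: exact by enumeration of
#' all `n!` rank permutations for `n <= exact_max`, a t approximation with
#' `n - 2` degrees of freedom above that.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @param exact_max largest n for which the permutation null is enumerated
#'   (default 9).
#' @return list with `estimate`, `p_value`, `n`, `method`.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))$estimate  # 0.8
#' @export
spearman_cor <- function(x, y, exact_max = 9L) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_cs("spearman_cor needs n >= 3 complete pairs (got %d)", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_cs("spearman_cor undefined for a constant input vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    # rho for every permutation of the y ranks against the fixed x ranks
    rho_all <- (matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(estimate = rho, p_value = min(p, 1), n = n, method = method)
}

#' Pearson product-moment correlation
#'
#' Closed-form r with a two-sided p-value from the t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, nonzero variances.
#' @return list with `estimate`, `p_value`, `n`, `method`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_cs("pearson_cor needs n >= 3 complete pairs (got %d)", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_cs("pearson_cor undefined for a zero-variance input")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(estimate = r, p_value = p, n = n, method = "t distribution")
}
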