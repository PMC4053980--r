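# Spearman rank correlation as used throughout the cis-mapping engine:
# Pearson correlation of mid-ranks (ties get average ranks), computed over
# pairwise-complete samples. A vectorized row-standardized-rank form drives
# the permutation machinery; the scalar form and the exact enumeration null
# are exposed for direct use and for calibration checks.

#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of mid-ranks (average ranks at ties) over the
#' pairwise-complete entries. Genotype vectors are typically ternary, so ties
#' are the norm, not an edge case.
#'
#' @param x,y Numeric vectors of equal length; `NA` allowed.
#' @param min_n Minimum number of pairwise-complete entries (default 4).
#' @return The correlation in `[-1, 1]`, or `NA` if either ranked vector has
#'   zero variance or fewer than `min_n` complete pairs exist.
#' @export
spearman_rho <- function(x, y, min_n = 4) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_n) return(NA_real_)
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  if (var(rx) == 0 || var(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Asymptotic two-sided p-value for a Spearman correlation
#'
#' Student-t approximation: `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. `|rho| = 1` returns 0 by convention.
#'
#' @param rho Correlation value(s).
#' @param n Number of samples (`>= 4`).
#' @return Two-sided p-value(s).
#' @export
spearman_pvalue_t <- function(rho, n) {
  if (any(n < 4)) abort("spearman_pvalue_t requires n >= 4")
  if (any(abs(rho) > 1, na.rm = TRUE)) abort("|rho| must be <= 1")
  p <- rep(NA_real_, length(rho))
  exact1 <- !is.na(rho) & abs(rho) == 1
  p[exact1] <- 0
  idx <- !is.na(rho) & !exact1
  tval <- rho[idx] * sqrt((n - 2) / (1 - rho[idx]^2))
  p[idx] <- 2 * pt(-abs(tval), df = n - 2)
  p
}

#' Exact permutation null of the Spearman correlation
#'
#' Enumerates all `n!` pairings of `y` against `x` and returns the full null
#' distribution of rho. Feasible for `n <= 7`; used to validate the pooled
#' Monte-Carlo permutation null.
#'
#' @param x,y Complete numeric vectors of equal length `n <= 7`.
#' @return Numeric vector of `n!` correlations.
#' @export
spearman_null_exact <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, !anyNA(x), !anyNA(y))
  if (n > 7) abort("exact enumeration is limited to n <= 7")
  perms <- all_permutations(n)
  apply(perms, 1, function(idx) spearman_rho(x, y[idx], min_n = n))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Row-wise mid-ranks of a complete matrix, standardized so that the dot
# product of two rows is exactly their Spearman correlation. Rows with zero
# rank variance come back as all-NA (the caller drops and counts them).
standardized_rank_rows <- function(mat) {
  rk <- t(apply(mat, 1, rank))
  if (nrow(mat) == 1) rk <- matrix(rk, 1)
  ctr <- rk - rowMeans(rk)
  ss <- sqrt(rowSums(ctr^2))
  out <- ctr / ss
  out[ss == 0, ] <- NA_real_
  dimnames(out) <- dimnames(mat)
  out
}
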