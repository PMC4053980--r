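# Normalization and filtering applied before any mapping: quantile
# normalization within probe-type groups, top-fraction variance filtering,
# and principal-component regression for sensitivity analyses.

#' Quantile normalize a feature-by-sample matrix within feature groups
#'
#' Within each group the reference distribution is the average distribution of
#' the group (the mean of the within-column order statistics); each sample
#' column is replaced by the reference value at its within-column rank. Tied
#' values receive the mean of the tied reference slots, which makes the
#' operation exactly idempotent. Methylation arrays are normalized separately
#' for type I and type II probes by passing the probe type as `grouping`.
#'
#' @param mat Numeric feature-by-sample matrix, no missing values.
#' @param grouping Optional factor/vector of length `nrow(mat)` partitioning
#'   the features; `NULL` treats the matrix as one group.
#' @return A matrix of the same shape; within-column rank order is preserved.
#' @export
quantile_normalize <- function(mat, grouping = NULL) {
  if (anyNA(mat)) abort("quantile_normalize requires a complete matrix")
  if (is.null(grouping)) grouping <- rep_len(1L, nrow(mat))
  if (length(grouping) != nrow(mat)) abort("grouping must have one entry per feature")
  out <- mat
  for (g in unique(grouping)) {
    rows <- which(grouping == g)
    if (length(rows) < 2) abort("each normalization group needs >= 2 features")
    sub <- mat[rows, , drop = FALSE]
    ref <- rowMeans(apply(sub, 2, sort))
    out[rows, ] <- apply(sub, 2, function(x) {
      o <- order(x)
      v <- ref
      grp <- cumsum(c(1, diff(x[o]) != 0))
      v <- stats::ave(v, grp, FUN = mean)
      res <- numeric(length(x))
      res[o] <- v
      res
    })
  }
  out
}

#' Keep the most variable features of a matrix
#'
#' Features are ranked by their sample standard deviation (pairwise-complete)
#' and the top `ceiling(top_fraction * n)` are kept, mirroring the top-25%
#' CpG-variance and top-50% expression-variance filters applied before
#' mapping. The realized SD cutoff is a property of the data, reported rather
#' than assumed.
#'
#' @param mat Numeric feature-by-sample matrix; each feature needs >= 2
#'   non-missing values.
#' @param top_fraction Fraction of features to keep, in `(0, 1]`.
#' @return A list of class `variance_filter_result`: `kept` (feature ids),
#'   `sd` (named per-feature SD), `cutoff` (realized SD cutoff), `fraction`
#'   requested, and `matrix` (the filtered matrix).
#' @export
variance_filter <- function(mat, top_fraction) {
  if (top_fraction <= 0 || top_fraction > 1) abort("top_fraction must be in (0, 1]")
  nn <- rowSums(!is.na(mat))
  if (any(nn < 2)) abort("every feature needs >= 2 non-missing values")
  sds <- apply(mat, 1, sd, na.rm = TRUE)
  if (all(sds == 0)) {
    warn("all features are constant; variance filter keeps nothing")
    return(structure(list(kept = character(), sd = sds, cutoff = NA_real_,
                          fraction = top_fraction,
                          matrix = mat[0, , drop = FALSE]),
                     class = "variance_filter_result"))
  }
  n_keep <- ceiling(top_fraction * nrow(mat))
  ord <- order(sds, decreasing = TRUE)
  kept_idx <- sort(ord[seq_len(n_keep)])
  structure(list(kept = rownames(mat)[kept_idx],
                 sd = sds,
                 cutoff = sds[ord[n_keep]],
                 fraction = top_fraction,
                 matrix = mat[kept_idx, , drop = FALSE]),
            class = "variance_filter_result")
}

#' @export
print.variance_filter_result <- function(x, ...) {
  cat(sprintf("<variance_filter_result> kept %d/%d features (top %.0f%%), SD cutoff %.4g\n",
              length(x$kept), length(x$sd), 100 * x$fraction, x$cutoff))
  invisible(x)
}

#' @export
tidy.variance_filter_result <- function(x, ...) {
  tibble::tibble(feature_id = names(x$sd), sd = unname(x$sd),
                 kept = names(x$sd) %in% x$kept)
}

#' Regress sample-space principal components out of a matrix
#'
#' Removes the top `k` principal components of the sample space (right
#' singular vectors of the row-centered matrix) from every feature, the usual
#' sensitivity check that hidden structure is not driving QTL calls.
#' Residuals are exactly orthogonal to each removed component.
#'
#' @param mat Numeric feature-by-sample matrix, no missing values.
#' @param k Number of components; `k = 0` returns the row-centered matrix.
#' @return Residual matrix of the same shape.
#' @export
regress_out_components <- function(mat, k) {
  if (anyNA(mat)) abort("regress_out_components requires a complete matrix")
  if (k < 0) abort("k must be >= 0")
  if (k >= ncol(mat)) abort("k must be smaller than the number of samples")
  ctr <- mat - rowMeans(mat)
  if (k == 0) return(ctr)
  sv <- svd(ctr, nu = 0, nv = k)
  v <- sv$v
  ctr - (ctr %*% v) %*% t(v)
}
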