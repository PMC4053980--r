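# Allelic-expression calling: permutation calibration of the aeSNP threshold,
# per-SNP calls with signs, and aggregation of consecutive same-sign calls
# into aeRegions with per-sample scores.

count_ae_calls <- function(smoothed, thresholds, min_samples) {
  vapply(thresholds, function(t) {
    sum(rowSums(abs(smoothed) > t, na.rm = TRUE) >= min_samples)
  }, 0L)
}

permute_within_samples <- function(raw) {
  out <- raw
  for (j in seq_len(ncol(raw))) {
    obs <- which(!is.na(raw[, j]))
    if (length(obs) > 1) out[obs, j] <- raw[obs[sample.int(length(obs))], j]
  }
  out
}

#' Calibrate the aeSNP calling threshold by within-sample permutation
#'
#' A null track is built by permuting the raw allelic ratios independently
#' within each sample (preserving each sample's missingness pattern and
#' marginal distribution while destroying positional persistence), re-running
#' the HMM smoother, and counting calls. For each candidate threshold `t` the
#' empirical FDR is the mean permuted call count at (`t`, `min_samples`)
#' divided by the observed call count; the smallest `t` with FDR at or below
#' the target is returned.
#'
#' @param track An [allele_ratio_track()]; smoothed scores are computed if
#'   absent.
#' @param target_fdr Target false discovery rate (default 0.05).
#' @param min_samples Minimum number of super-threshold samples per SNP
#'   (default 2).
#' @param n_permutations Number of permutation replicates (>= 1).
#' @param seed Integer seed for the permutations.
#' @param grid Candidate thresholds (default 0.05 to 1.0 by 0.05).
#' @param spec The [hmm_spec()] used for smoothing.
#' @return An object of class `ae_threshold`: `threshold` (NA with a warning
#'   if no observed calls exist at any threshold), a per-threshold `grid`
#'   tibble with observed/null counts and FDR, and provenance fields.
#' @export
calibrate_ae_threshold <- function(track, target_fdr = 0.05, min_samples = 2,
                                   n_permutations = 10, seed = 1,
                                   grid = seq(0.05, 1, by = 0.05),
                                   spec = hmm_spec()) {
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  if (is.null(track$smoothed_ratio)) track <- smooth_allelic_ratios(track, spec)
  obs_counts <- count_ae_calls(track$smoothed_ratio, grid, min_samples)
  null_counts <- matrix(0, n_permutations, length(grid))
  set.seed(seed)
  for (r in seq_len(n_permutations)) {
    perm <- allele_ratio_track(permute_within_samples(track$raw_ratio), track$loci)
    perm <- smooth_allelic_ratios(perm, spec)
    null_counts[r, ] <- count_ae_calls(perm$smoothed_ratio, grid, min_samples)
  }
  null_mean <- colMeans(null_counts)
  fdr <- ifelse(obs_counts > 0, null_mean / obs_counts, NA_real_)
  ok <- which(!is.na(fdr) & fdr <= target_fdr)
  threshold <- if (length(ok)) grid[min(ok)] else NA_real_
  if (all(obs_counts == 0)) {
    warn("no observed aeSNP calls at any candidate threshold; returning NA")
  } else if (is.na(threshold)) {
    warn("no candidate threshold achieves the target FDR; returning NA")
  }
  structure(list(threshold = threshold,
                 grid = tibble::tibble(threshold = grid,
                                       n_observed = obs_counts,
                                       n_null_mean = null_mean,
                                       fdr = fdr),
                 target_fdr = target_fdr, min_samples = min_samples,
                 n_permutations = n_permutations, seed = seed),
            class = "ae_threshold")
}

#' @export
print.ae_threshold <- function(x, ...) {
  cat(sprintf("<ae_threshold> %.2f at target FDR %.0f%% (>= %d samples, %d permutations)\n",
              x$threshold, 100 * x$target_fdr, x$min_samples, x$n_permutations))
  invisible(x)
}

#' @export
tidy.ae_threshold <- function(x, ...) x$grid

#' @export
glance.ae_threshold <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, target_fdr = x$target_fdr,
                 min_samples = x$min_samples, n_permutations = x$n_permutations,
                 seed = x$seed)
}

#' Call aeSNPs from smoothed allelic scores
#'
#' A SNP is an aeSNP if its absolute smoothed log2 ratio exceeds the threshold
#' in at least `min_samples` samples. The call sign is the majority sign among
#' the super-threshold samples (ties broken by the sign of their mean score).
#'
#' @param track A smoothed [allele_ratio_track()].
#' @param threshold Calling threshold on `|smoothed|`.
#' @param min_samples Minimum super-threshold samples (default 2).
#' @return A tibble with one row per SNP: `snp_id`, `chrom`, `position`,
#'   `n_super`, `sign` (+1/-1, NA if uncalled), `called`.
#' @export
call_aesnps <- function(track, threshold, min_samples = 2) {
  if (is.null(track$smoothed_ratio)) abort("track has no smoothed scores; run smooth_allelic_ratios()")
  sm <- track$smoothed_ratio
  super <- !is.na(sm) & abs(sm) > threshold
  n_super <- rowSums(super)
  n_pos <- rowSums(super & sm > 0)
  mean_super <- rowSums(sm * super, na.rm = TRUE)
  sgn <- ifelse(n_pos * 2 > n_super, 1,
                ifelse(n_pos * 2 < n_super, -1, sign(mean_super)))
  called <- n_super >= min_samples
  tibble::tibble(snp_id = track$loci$snp_id, chrom = track$loci$chrom,
                 position = track$loci$position,
                 n_super = as.integer(unname(n_super)),
                 sign = unname(ifelse(called, sgn, NA_real_)),
                 called = unname(called))
}

#' Aggregate consecutive same-sign aeSNPs into aeRegions
#'
#' Maximal runs of two or more consecutive called SNPs sharing a sign become
#' regions; an uncalled SNP or a sign change breaks the run. Each region is
#' scored per sample by the mean smoothed value over its member SNPs (missing
#' if the sample observed no member).
#'
#' @param calls The tibble from [call_aesnps()].
#' @param track The smoothed [allele_ratio_track()] the calls came from.
#' @return An object of class `ae_regions`: `regions` (tibble with `region_id`,
#'   `chrom`, `start`, `end`, `sign`, `n_snps`, `snp_ids` list-column) and
#'   `scores` (region-by-sample matrix of mean smoothed values).
#' @export
build_aeregions <- function(calls, track) {
  stopifnot(identical(calls$snp_id, track$loci$snp_id))
  key <- ifelse(calls$called, calls$sign, NA_real_)
  # run ids: change whenever chrom, called status or sign changes
  brk <- c(TRUE, calls$chrom[-1] != calls$chrom[-nrow(calls)] |
                 is.na(key[-1]) != is.na(key[-length(key)]) |
                 (!is.na(key[-1]) & !is.na(key[-length(key)]) &
                  key[-1] != key[-length(key)]))
  run <- cumsum(brk)
  keep <- !is.na(key)
  runs <- split(which(keep), run[keep])
  runs <- runs[lengths(runs) >= 2]
  if (length(runs) == 0) {
    regions <- tibble::tibble(region_id = character(), chrom = character(),
                              start = numeric(), end = numeric(),
                              sign = numeric(), n_snps = integer(),
                              snp_ids = list())
    scores <- matrix(numeric(), 0, ncol(track$raw_ratio),
                     dimnames = list(NULL, colnames(track$raw_ratio)))
    return(structure(list(regions = regions, scores = scores), class = "ae_regions"))
  }
  regions <- purrr::map_dfr(seq_along(runs), function(i) {
    idx <- runs[[i]]
    tibble::tibble(region_id = sprintf("aeR%04d", i),
                   chrom = calls$chrom[idx[1]],
                   start = min(calls$position[idx]),
                   end = max(calls$position[idx]) + 1,
                   sign = calls$sign[idx[1]],
                   n_snps = length(idx),
                   snp_ids = list(calls$snp_id[idx]))
  })
  scores <- t(vapply(runs, function(idx) {
    colMeans(track$smoothed_ratio[idx, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(track$smoothed_ratio))))
  scores[is.nan(scores)] <- NA_real_
  rownames(scores) <- regions$region_id
  structure(list(regions = regions, scores = scores), class = "ae_regions")
}

#' @export
print.ae_regions <- function(x, ...) {
  cat(sprintf("<ae_regions> %d regions over %d samples\n",
              nrow(x$regions), ncol(x$scores)))
  invisible(x)
}

#' @export
tidy.ae_regions <- function(x, ...) {
  dplyr::select(x$regions, -"snp_ids")
}
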