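# The shared cis-mapping statistical engine: pair construction within a
# +/-250 kb window, Spearman statistics, a pooled permutation null with
# tail-ratio empirical-FDR threshold selection, and the LD-pruned
# distance-binned QQ construction. The same machinery serves four modes:
# mQTL (CpG ~ SNP), eQTL (gene ~ SNP), aeQTL (aeRegion ~ SNP) and
# methylation-expression (gene ~ CpG).

#' Build the cis pair universe for a mapping mode
#'
#' Point features pair with loci within `window` bp of the point (closed
#' boundary); extended features (genes, aeRegions) pair with loci inside the
#' feature or within `window` of either boundary. SNP loci are filtered at
#' `maf_min` in the three genotype modes; the methylation-expression mode
#' takes CpG probes as loci and applies no MAF filter.
#'
#' @param features Feature tibble. For `mqtl`: a [cpg_table()]. For `eqtl` and
#'   `methexpr`: a [gene_table()]. For `aeqtl`: the `regions` tibble of an
#'   [build_aeregions()] result (columns `region_id`, `chrom`, `start`, `end`).
#' @param loci Locus tibble: a [snp_table()] (or a [cpg_table()] for
#'   `methexpr`).
#' @param mode One of `"mqtl"`, `"eqtl"`, `"aeqtl"`, `"methexpr"`.
#' @param window Cis window in bp on either side (default 250000, closed).
#' @param maf_min Minimum minor allele frequency for SNP loci, exclusive
#'   (default 0.10, i.e. MAF > 10%).
#' @return A tibble of pairs: `feature_id`, `locus_id`, `distance_bp`
#'   (0 if the locus lies inside the feature).
#' @export
build_cis_pairs <- function(features, loci, mode = c("mqtl", "eqtl", "aeqtl", "methexpr"),
                            window = 250000, maf_min = 0.10) {
  mode <- match.arg(mode)
  id_col <- switch(mode, mqtl = "probe_id", eqtl = "gene_id",
                   aeqtl = "region_id", methexpr = "gene_id")
  if (!id_col %in% names(features)) {
    abort(sprintf("features for mode '%s' need a '%s' column", mode, id_col))
  }
  if (mode == "mqtl") {
    f_start <- features$position
    f_end <- features$position
  } else {
    f_start <- features$start
    f_end <- features$end - 1   # last base inside the feature
  }
  locus_id_col <- if (mode == "methexpr") "probe_id" else "snp_id"
  loci_use <- loci
  if (mode != "methexpr") {
    if (!"maf" %in% names(loci)) abort("SNP loci need a 'maf' column")
    loci_use <- loci[loci$maf > maf_min, , drop = FALSE]
  }
  out <- vector("list", length(unique(features$chrom)))
  k <- 0
  for (chr in unique(features$chrom)) {
    frows <- which(features$chrom == chr)
    lrows <- which(loci_use$chrom == chr)
    if (!length(lrows)) next
    pos <- loci_use$position[lrows]
    ord <- order(pos)
    pos_sorted <- pos[ord]
    lrows_sorted <- lrows[ord]
    chunks <- lapply(frows, function(i) {
      lo <- f_start[i] - window
      hi <- f_end[i] + window
      a <- findInterval(lo - 0.5, pos_sorted) + 1
      b <- findInterval(hi + 0.5, pos_sorted)
      if (a > b) return(NULL)
      sel <- lrows_sorted[a:b]
      p <- loci_use$position[sel]
      dist <- pmax(0, pmax(f_start[i] - p, p - f_end[i]))
      tibble::tibble(feature_id = features[[id_col]][i],
                     locus_id = loci_use[[locus_id_col]][sel],
                     distance_bp = dist)
    })
    k <- k + 1
    out[[k]] <- dplyr::bind_rows(chunks)
  }
  res <- dplyr::bind_rows(out[seq_len(k)])
  if (nrow(res) == 0) {
    res <- tibble::tibble(feature_id = character(), locus_id = character(),
                          distance_bp = numeric())
  }
  res
}

align_columns <- function(feature_matrix, locus_matrix) {
  common <- intersect(colnames(feature_matrix), colnames(locus_matrix))
  if (length(common) < 4) abort("fewer than 4 shared samples between the matrices")
  list(f = feature_matrix[, common, drop = FALSE],
       l = locus_matrix[, common, drop = FALSE])
}

# |rho| for every pair given aligned matrices. Fast path (no missing data):
# dot products of row-standardized mid-ranks. Pairwise-complete path
# otherwise. Returns NA for incomputable pairs.
pairs_abs_rho <- function(fm, lm, fi, li, min_informative) {
  if (!anyNA(fm) && !anyNA(lm)) {
    fz <- standardized_rank_rows(fm)
    lz <- standardized_rank_rows(lm)
    rho <- rowSums(fz[fi, , drop = FALSE] * lz[li, , drop = FALSE])
    if (ncol(fm) < min_informative) rho[] <- NA_real_
    return(rho)
  }
  vapply(seq_along(fi), function(k) {
    spearman_rho(fm[fi[k], ], lm[li[k], ], min_n = min_informative)
  }, 0)
}

#' Map features to loci with a pooled permutation-FDR threshold
#'
#' The engine behind all four mapping modes. Observed `|rho|` (Spearman) is
#' computed per cis pair; the null is built by permuting the sample labels of
#' the feature matrix (each replicate is one full re-analysis of every pair)
#' and pooling null `|rho|` across pairs and replicates. The empirical
#' p-value of a pair is `(1 + #null >= |rho|) / (1 + #null)`; the empirical
#' FDR at a cutoff `c` is the mean per-replicate null count at or above `c`
#' divided by the observed count, and the significance cutoff is the smallest
#' observed `|rho|` whose FDR is at or below the requested level (a tail-ratio
#' estimator with pi0 = 1, conservative).
#'
#' @param feature_matrix Feature-by-sample numeric matrix (the side that gets
#'   permuted: methylation, expression or aeRegion scores).
#' @param locus_matrix Locus-by-sample numeric matrix (genotype dosages, or
#'   beta values in methylation-expression mode).
#' @param pairs Pair tibble from [build_cis_pairs()].
#' @param fdr Target FDR level (default 0.05).
#' @param n_permutations Number of permutation replicates (default 10).
#' @param seed Integer seed.
#' @param min_informative Minimum pairwise-complete samples per pair
#'   (default 10); pairs below it are dropped and counted.
#' @param mode Tag recorded in the result.
#' @return An object of class `association_result`: `pairs` with `rho`,
#'   `p_empirical`, `distance_bp`, `significant`; the realized `rho_cutoff`
#'   and `p_cutoff` (`Inf`/0-sized significant set if no cutoff achieves the
#'   FDR, reported as a sentinel); null provenance (`n_permutations`,
#'   `null_size`, `n_dropped`, `seed`, `fdr`, `mode`) and the pooled null
#'   `null_abs_rho`.
#' @export
permutation_fdr_map <- function(feature_matrix, locus_matrix, pairs,
                                fdr = 0.05, n_permutations = 10, seed = 1,
                                min_informative = 10, mode = "mqtl") {
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  al <- align_columns(feature_matrix, locus_matrix)
  fm <- al$f; lm <- al$l
  fi <- match(pairs$feature_id, rownames(fm))
  li <- match(pairs$locus_id, rownames(lm))
  if (anyNA(fi) || anyNA(li)) abort("pairs reference features/loci missing from the matrices")
  rho_signed <- unname(pairs_abs_rho(fm, lm, fi, li, min_informative))
  obs <- abs(rho_signed)
  keep <- !is.na(obs)
  n_dropped <- sum(!keep)
  set.seed(seed)
  n <- ncol(fm)
  null_abs <- vector("list", n_permutations)
  for (r in seq_len(n_permutations)) {
    fp <- fm[, sample.int(n), drop = FALSE]
    colnames(fp) <- colnames(fm)
    nr <- abs(pairs_abs_rho(fp, lm, fi, li, min_informative))
    null_abs[[r]] <- nr[!is.na(nr)]
  }
  null_pool <- sort(unlist(null_abs))
  n_null <- length(null_pool)
  obs_kept <- obs[keep]
  # counts of null values >= x via binary search on the sorted pool
  null_ge <- n_null - findInterval(obs_kept - 1e-12, null_pool)
  p_emp <- (1 + null_ge) / (1 + n_null)
  # FDR(c) over candidate cutoffs = sorted observed |rho|
  ord <- order(obs_kept, decreasing = TRUE)
  cand <- obs_kept[ord]
  obs_ge <- seq_along(cand)
  null_ge_cand <- (n_null - findInterval(cand - 1e-12, null_pool)) / n_permutations
  fdr_at <- null_ge_cand / obs_ge
  ok <- which(fdr_at <= fdr)
  if (length(ok)) {
    cut_idx <- max(ok)          # smallest cutoff (largest tail) still within FDR
    rho_cutoff <- cand[cut_idx]
    p_cutoff <- (1 + null_ge_cand[cut_idx] * n_permutations) / (1 + n_null)
  } else {
    rho_cutoff <- Inf
    p_cutoff <- 0
  }
  out_pairs <- pairs[keep, , drop = FALSE]
  out_pairs$rho <- rho_signed[keep]
  out_pairs$abs_rho <- obs_kept
  out_pairs$p_empirical <- p_emp
  out_pairs$significant <- obs_kept >= rho_cutoff
  if (!"distance_bp" %in% names(out_pairs)) out_pairs$distance_bp <- NA_real_
  structure(list(pairs = tibble::as_tibble(out_pairs),
                 rho_cutoff = rho_cutoff, p_cutoff = p_cutoff,
                 fdr = fdr, mode = mode,
                 n_permutations = as.integer(n_permutations),
                 null_size = n_null,
                 pair_count = sum(keep),
                 n_dropped = n_dropped,
                 seed = seed,
                 null_abs_rho = null_pool),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> mode=%s: %d/%d pairs significant at FDR %.0f%% (|rho| >= %.3f)\n",
              x$mode, sum(x$pairs$significant), nrow(x$pairs),
              100 * x$fdr, x$rho_cutoff))
  invisible(x)
}

#' @export
tidy.association_result <- function(x, ...) x$pairs

#' @export
glance.association_result <- function(x, ...) {
  tibble::tibble(mode = x$mode, fdr = x$fdr, rho_cutoff = x$rho_cutoff,
                 p_cutoff = x$p_cutoff, n_pairs = x$pair_count,
                 n_significant = sum(x$pairs$significant),
                 n_dropped = x$n_dropped,
                 n_permutations = x$n_permutations, seed = x$seed)
}

#' Significant loci / features of an association result
#'
#' @param result An `association_result`.
#' @return Tibble of the significant pairs.
#' @export
significant_pairs <- function(result) {
  stopifnot(inherits(result, "association_result"))
  dplyr::filter(result$pairs, .data$significant)
}

#' LD-pruned, distance-binned p-values for QQ plots
#'
#' For each feature, iteratively select the most strongly associated
#' remaining locus, emit its p-value into the distance bin of the pair,
#' remove all loci in linkage disequilibrium with the selection (squared
#' Pearson correlation of dosages above `r2_cutoff`), and repeat until the
#' feature's loci are exhausted. Expected uniform quantiles are attached per
#' bin for QQ plotting.
#'
#' @param result An `association_result`.
#' @param genotypes A [genotype_matrix()] covering the result's loci.
#' @param r2_cutoff LD pruning threshold on R^2 (default 0.8).
#' @param distance_bins Numeric break points in bp (left-closed bins; the
#'   default separates 0-5 kb, 5-20 kb, 20-100 kb and >100 kb).
#' @return A tibble: `feature_id`, `locus_id`, `distance_bp`, `bin`,
#'   `p_empirical`, `expected` (uniform quantile within bin).
#' @export
ld_pruned_qq <- function(result, genotypes, r2_cutoff = 0.8,
                         distance_bins = c(0, 5e3, 2e4, 1e5, Inf)) {
  stopifnot(inherits(result, "association_result"))
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else genotypes
  pr <- result$pairs
  picked <- pr[0, ]
  for (f in unique(pr$feature_id)) {
    sub <- pr[pr$feature_id == f, , drop = FALSE]
    sub <- sub[order(sub$p_empirical, -abs(sub$rho)), , drop = FALSE]
    while (nrow(sub) > 0) {
      best <- sub[1, , drop = FALSE]
      picked <- dplyr::bind_rows(picked, best)
      if (nrow(sub) == 1) break
      g0 <- dos[best$locus_id, ]
      r2 <- vapply(sub$locus_id[-1], function(s) {
        suppressWarnings(cor(g0, dos[s, ], use = "pairwise.complete.obs"))^2
      }, 0)
      r2[is.na(r2)] <- 1   # constant dosage: treat as redundant
      sub <- sub[-1, , drop = FALSE][r2 <= r2_cutoff, , drop = FALSE]
    }
  }
  picked$bin <- cut(picked$distance_bp, breaks = distance_bins,
                    include.lowest = TRUE, right = FALSE)
  picked <- dplyr::group_by(picked, .data$bin)
  picked <- dplyr::mutate(picked,
                          expected = (rank(.data$p_empirical, ties.method = "first") - 0.5) /
                            dplyr::n())
  dplyr::ungroup(picked)[, c("feature_id", "locus_id", "distance_bp", "bin",
                             "p_empirical", "expected")]
}
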