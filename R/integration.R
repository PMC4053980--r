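# Integration of the three mapping arms: emQTL intersection, MAF-matched
# enrichment, cross-validated variance partitioning of expression into
# sequence and methylation components, cell-proliferation variance
# attribution, and Fisher term enrichment.

#' Intersect mapping results into emQTLs
#'
#' An emQTL is a SNP significant in the methylation map AND in at least one
#' expression map (eQTL to a gene and/or aeQTL to an aeRegion), all at the
#' same FDR level. The linked gene list combines eQTL genes with genes
#' overlapped by emQTL-linked aeRegions; aeRegions without gene overlap are
#' reported separately.
#'
#' @param mqtl,eqtl,aeqtl `association_result` objects from
#'   [permutation_fdr_map()] (the `aeqtl` arm may be `NULL`).
#' @param aeregions Optional [build_aeregions()] result (needed to map
#'   aeRegions onto genes).
#' @param genes Optional [gene_table()] for the aeRegion-gene overlap.
#' @return An object of class `emqtl_set`: `snps` (emQTL SNP ids), `genes`
#'   (linked gene ids), `orphan_aeregions` (emQTL-linked aeRegions with no
#'   gene overlap), plus the per-arm significant sets.
#' @export
find_emqtls <- function(mqtl, eqtl, aeqtl = NULL, aeregions = NULL, genes = NULL) {
  stopifnot(inherits(mqtl, "association_result"), inherits(eqtl, "association_result"))
  fdrs <- c(mqtl$fdr, eqtl$fdr, if (!is.null(aeqtl)) aeqtl$fdr)
  if (length(unique(fdrs)) != 1) abort("all mapping results must share the FDR level")
  m_sig <- significant_pairs(mqtl)
  e_sig <- significant_pairs(eqtl)
  a_sig <- if (!is.null(aeqtl)) significant_pairs(aeqtl) else e_sig[0, ]
  m_snps <- unique(m_sig$locus_id)
  expr_snps <- union(unique(e_sig$locus_id), unique(a_sig$locus_id))
  em_snps <- intersect(m_snps, expr_snps)
  em_genes <- unique(e_sig$feature_id[e_sig$locus_id %in% em_snps])
  em_regions <- unique(a_sig$feature_id[a_sig$locus_id %in% em_snps])
  orphan <- character()
  if (length(em_regions) && !is.null(aeregions) && !is.null(genes)) {
    reg <- aeregions$regions[aeregions$regions$region_id %in% em_regions, , drop = FALSE]
    for (i in seq_len(nrow(reg))) {
      hit <- genes$chrom == reg$chrom[i] &
        genes$start < reg$end[i] & genes$end > reg$start[i]
      if (any(hit)) {
        em_genes <- union(em_genes, genes$gene_id[hit])
      } else {
        orphan <- c(orphan, reg$region_id[i])
      }
    }
  } else {
    orphan <- em_regions
  }
  structure(list(snps = em_snps, genes = sort(unique(em_genes)),
                 orphan_aeregions = orphan,
                 mqtl_snps = m_snps,
                 eqtl_snps = unique(e_sig$locus_id),
                 aeqtl_snps = unique(a_sig$locus_id),
                 eqtl_genes = unique(e_sig$feature_id),
                 aeqtl_regions = unique(a_sig$feature_id)),
            class = "emqtl_set")
}

#' @export
print.emqtl_set <- function(x, ...) {
  cat(sprintf("<emqtl_set> %d emQTL SNPs; %d linked genes; %d orphan aeRegions\n",
              length(x$snps), length(x$genes), length(x$orphan_aeregions)))
  invisible(x)
}

#' @export
glance.emqtl_set <- function(x, ...) {
  tibble::tibble(n_emqtl_snps = length(x$snps), n_genes = length(x$genes),
                 n_orphan_aeregions = length(x$orphan_aeregions),
                 n_mqtl_snps = length(x$mqtl_snps),
                 n_eqtl_snps = length(x$eqtl_snps),
                 n_aeqtl_snps = length(x$aeqtl_snps))
}

#' MAF-matched enrichment of a SNP set in a reference set
#'
#' Bins all SNPs by minor allele frequency (default 5%-wide bins), draws
#' random SNP sets matching the target's bin profile, and reports the fold
#' enrichment: observed overlap of target with the reference set divided by
#' the mean random overlap.
#'
#' @param target_snps Character vector of SNP ids (e.g. the mQTL set).
#' @param reference_snps Character vector (e.g. the emQTL set).
#' @param snps A [snp_table()] carrying MAF for every SNP.
#' @param n_draws Number of random draws (>= 100).
#' @param seed Integer seed.
#' @param bin_width MAF bin width (default 0.05).
#' @return A list of class `maf_enrichment`: `fold`, `observed`,
#'   `null_mean`, `null_sd`, `n_draws`.
#' @export
maf_matched_enrichment <- function(target_snps, reference_snps, snps,
                                   n_draws = 1000, seed = 1, bin_width = 0.05) {
  if (n_draws < 100) abort("n_draws must be >= 100")
  if (!all(target_snps %in% snps$snp_id)) abort("target SNPs missing MAF")
  bins <- floor(snps$maf / bin_width)
  names(bins) <- snps$snp_id
  target_bins <- table(bins[target_snps])
  observed <- length(intersect(target_snps, reference_snps))
  ref <- snps$snp_id %in% reference_snps
  pool_by_bin <- split(seq_len(nrow(snps)), bins)
  set.seed(seed)
  null_overlap <- vapply(seq_len(n_draws), function(d) {
    picked <- unlist(lapply(names(target_bins), function(b) {
      pool <- pool_by_bin[[b]]
      k <- target_bins[[b]]
      if (length(pool) < k) {
        warn(sprintf("MAF bin %s has only %d eligible SNPs for %d draws; sampling with replacement",
                     b, length(pool), k))
        sample(pool, k, replace = TRUE)
      } else {
        sample(pool, k)
      }
    }))
    sum(ref[picked])
  }, 0)
  null_mean <- mean(null_overlap)
  structure(list(fold = observed / null_mean, observed = observed,
                 null_mean = null_mean, null_sd = sd(null_overlap),
                 n_draws = n_draws, seed = seed),
            class = "maf_enrichment")
}

#' @export
print.maf_enrichment <- function(x, ...) {
  cat(sprintf("<maf_enrichment> fold = %.2f (observed %d vs null mean %.2f over %d draws)\n",
              x$fold, x$observed, x$null_mean, x$n_draws))
  invisible(x)
}

#' @export
glance.maf_enrichment <- function(x, ...) {
  tibble::tibble(fold = x$fold, observed = x$observed, null_mean = x$null_mean,
                 null_sd = x$null_sd, n_draws = x$n_draws)
}

# Greedy forward selection of up to k features by training RSS with an AIC
# stop; returns the selected column indices (possibly none).
forward_select_aic <- function(y, X, k) {
  chosen <- integer()
  candidates <- seq_len(ncol(X))
  n <- length(y)
  best_aic <- n * log(sum((y - mean(y))^2) / n) + 2
  while (length(chosen) < k && length(candidates) > 0) {
    rss <- vapply(candidates, function(j) {
      fit <- lm.fit(cbind(1, X[, c(chosen, j), drop = FALSE]), y)
      sum(fit$residuals^2)
    }, 0)
    j_best <- candidates[which.min(rss)]
    aic <- n * log(min(rss) / n) + 2 * (length(chosen) + 2)
    if (aic >= best_aic) break
    best_aic <- aic
    chosen <- c(chosen, j_best)
    candidates <- setdiff(candidates, j_best)
  }
  chosen
}

cv_r2_forward <- function(y, X, k_features, folds, fold_id) {
  pred <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    train <- !test
    if (ncol(X) == 0) {
      pred[test] <- mean(y[train])
      next
    }
    sel <- forward_select_aic(y[train], X[train, , drop = FALSE], k_features)
    if (length(sel) == 0) {
      pred[test] <- mean(y[train])
    } else {
      fit <- lm.fit(cbind(1, X[train, sel, drop = FALSE]), y[train])
      pred[test] <- cbind(1, X[test, sel, drop = FALSE]) %*% fit$coefficients
    }
  }
  r <- suppressWarnings(cor(y, pred))
  if (is.na(r) || r < 0) 0 else r^2
}

#' Partition a gene's expression variance into sequence and methylation parts
#'
#' Three cross-validated models are fitted with greedy forward selection (up
#' to `k_features` features, AIC stop): genotypes of cis SNPs, beta values of
#' cis CpGs, and CpGs applied to the residuals of the sequence model. Each
#' R-squared is the squared Pearson correlation between observations and
#' pooled out-of-fold predictions (negative correlations clipped to zero).
#' The independent fraction `r2_meth_given_seq / r2_meth` estimates how much
#' methylation-explained expression variation is independent of sequence.
#'
#' @param expr Numeric vector of the gene's expression across samples.
#' @param snp_matrix Dosage matrix (SNPs x samples) of the gene's cis SNPs.
#' @param cpg_matrix Beta matrix (CpGs x samples) of the gene's cis CpGs.
#' @param k_features Maximum selected features per model (default 5).
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `variance_partition`: `r2_seq`, `r2_meth`,
#'   `r2_meth_given_seq`, `independent_fraction`.
#' @export
variance_partition <- function(expr, snp_matrix, cpg_matrix,
                               k_features = 5, folds = 5, seed = 1) {
  n <- length(expr)
  if (n < folds * 4) abort("need at least folds * 4 samples")
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  Xs <- if (is.null(snp_matrix) || nrow(snp_matrix) == 0) {
    matrix(0, n, 0)
  } else t(snp_matrix)
  Xm <- if (is.null(cpg_matrix) || nrow(cpg_matrix) == 0) {
    matrix(0, n, 0)
  } else t(cpg_matrix)
  r2_seq <- cv_r2_forward(expr, Xs, k_features, folds, fold_id)
  r2_meth <- cv_r2_forward(expr, Xm, k_features, folds, fold_id)
  # residualize on the in-sample sequence model, then repeat with methylation
  resid <- expr
  if (ncol(Xs) > 0) {
    sel <- forward_select_aic(expr, Xs, k_features)
    if (length(sel)) resid <- lm.fit(cbind(1, Xs[, sel, drop = FALSE]), expr)$residuals
  }
  r2_mgs <- cv_r2_forward(resid, Xm, k_features, folds, fold_id)
  structure(list(r2_seq = r2_seq, r2_meth = r2_meth, r2_meth_given_seq = r2_mgs,
                 independent_fraction = if (r2_meth > 0) min(1, r2_mgs / r2_meth) else NA_real_,
                 k_features = k_features, folds = folds, seed = seed),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("<variance_partition> seq %.1f%%, meth %.1f%%, meth|seq %.1f%% (independent fraction %.0f%%)\n",
              100 * x$r2_seq, 100 * x$r2_meth, 100 * x$r2_meth_given_seq,
              100 * x$independent_fraction))
  invisible(x)
}

#' @export
glance.variance_partition <- function(x, ...) {
  tibble::tibble(r2_seq = x$r2_seq, r2_meth = x$r2_meth,
                 r2_meth_given_seq = x$r2_meth_given_seq,
                 independent_fraction = x$independent_fraction)
}

#' Variance explained by a cell-proliferation expression signature
#'
#' The proliferation vector is the first principal component of the
#' marker-gene expression submatrix (sample scores). Every target feature is
#' regressed on the vector; the explained fraction is
#' `1 - sum(residual variance) / sum(original variance)`, accumulated across
#' the target set. Zero-variance targets are skipped (and counted).
#'
#' @param expression An [expression_matrix()] (or plain matrix) holding the
#'   marker genes.
#' @param targets Numeric feature-by-sample matrix of the probes/genes whose
#'   variance is to be attributed (columns must cover the expression samples).
#' @param marker_gene_ids Character vector of marker gene ids (>= 2).
#' @return A list of class `proliferation_variance`: `fraction`,
#'   `proliferation_vector`, `n_targets`, `n_skipped`.
#' @export
proliferation_variance <- function(expression, targets, marker_gene_ids) {
  lev <- if (inherits(expression, "expression_matrix")) expression$level else expression
  if (length(marker_gene_ids) < 2) abort("need >= 2 marker genes")
  if (!all(marker_gene_ids %in% rownames(lev))) abort("marker genes missing from the expression matrix")
  sub <- lev[marker_gene_ids, , drop = FALSE]
  pc <- prcomp(t(sub), center = TRUE, scale. = FALSE)
  vec <- pc$x[, 1]
  common <- intersect(colnames(targets), names(vec))
  if (length(common) < 4) abort("targets share too few samples with the expression matrix")
  tg <- targets[, common, drop = FALSE]
  v <- vec[common]
  tot <- 0; res <- 0; skipped <- 0L
  for (i in seq_len(nrow(tg))) {
    y <- tg[i, ]
    ok <- !is.na(y)
    if (sum(ok) < 4 || var(y[ok]) == 0) { skipped <- skipped + 1L; next }
    fit <- lm.fit(cbind(1, v[ok]), y[ok])
    tot <- tot + var(y[ok])
    res <- res + var(fit$residuals)
  }
  structure(list(fraction = if (tot > 0) 1 - res / tot else NA_real_,
                 proliferation_vector = vec,
                 n_targets = nrow(tg), n_skipped = skipped),
            class = "proliferation_variance")
}

#' @export
print.proliferation_variance <- function(x, ...) {
  cat(sprintf("<proliferation_variance> %.1f%% of target variance (%d targets, %d skipped)\n",
              100 * x$fraction, x$n_targets, x$n_skipped))
  invisible(x)
}

#' Term enrichment of a gene set by Fisher's exact test
#'
#' Per term: a 2x2 Fisher exact test (test vs non-test x has-term vs
#' lacks-term over the background) and the fold enrichment, i.e. the
#' proportion of test-set genes with the term divided by the proportion of
#' background genes with it. Benjamini-Hochberg adjusted p-values are
#' reported alongside. Terms absent from the background are skipped.
#'
#' @param test_set Character vector of gene ids, a subset of `background_set`.
#' @param background_set Character vector of gene ids.
#' @param annotations Tibble with columns `gene_id` and `term`.
#' @return A tibble: `term`, `n_test`, `n_background`, `fold`, `p_value`,
#'   `p_adjusted`.
#' @export
term_enrichment <- function(test_set, background_set, annotations) {
  if (!all(test_set %in% background_set)) abort("test_set must be a subset of background_set")
  ann <- annotations[annotations$gene_id %in% background_set, , drop = FALSE]
  terms <- unique(ann$term)
  n_bg <- length(unique(background_set))
  n_t <- length(unique(test_set))
  out <- purrr::map_dfr(terms, function(tm) {
    with_term <- unique(ann$gene_id[ann$term == tm])
    a <- length(intersect(test_set, with_term))
    b <- n_t - a
    c_ <- length(with_term) - a
    d <- n_bg - n_t - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    fold <- (a / n_t) / (length(with_term) / n_bg)
    tibble::tibble(term = tm, n_test = a, n_background = length(with_term),
                   fold = fold, p_value = p)
  })
  if (nrow(out)) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}
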