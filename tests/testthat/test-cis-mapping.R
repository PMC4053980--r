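test_that("cis pair construction honors window, MAF filter and feature extent", {
  cpgs <- cpg_table("c1", "chr1", 500000)
  snps <- snp_table(c("near", "edge", "far", "rare"), "chr1",
                    c(400000, 250000, 751000, 501000),
                    c(0.3, 0.2, 0.4, 0.08))
  pr <- build_cis_pairs(cpgs, snps, "mqtl")
  # SNP exactly 250 kb away is included (closed boundary); MAF 0.08 excluded
  expect_setequal(pr$locus_id, c("near", "edge"))
  expect_equal(pr$distance_bp[pr$locus_id == "edge"], 250000)

  # extended feature: gene [1,000,000, 1,020,000) pairs with [750,000, 1,270,000)
  genes <- gene_table("g1", "chr1", 1000000, 1020000, "+")
  set.seed(8)
  pos <- sort(sample.int(2e6, 400))
  snps2 <- snp_table(sprintf("r%03d", seq_along(pos)), "chr1", pos,
                     runif(400, 0.11, 0.5))
  pr2 <- build_cis_pairs(genes, snps2, "eqtl")
  # brute-force scan oracle
  inside <- pos >= 1000000 & pos < 1020000
  expected <- pos >= 750000 & pos <= 1020000 - 1 + 250000
  expect_setequal(pr2$locus_id, snps2$snp_id[expected])
  expect_true(all(pr2$distance_bp[pr2$locus_id %in% snps2$snp_id[inside]] == 0))
  d_oracle <- pmax(0, pmax(1000000 - pos, pos - (1020000 - 1)))[expected]
  expect_equal(pr2$distance_bp[match(snps2$snp_id[expected], pr2$locus_id)], d_oracle)

  # methylation-expression mode takes CpGs as loci without a MAF filter
  cpg_loci <- cpg_table(c("p1", "p2"), "chr1", c(900000, 1500000))
  pr3 <- build_cis_pairs(genes, cpg_loci, "methexpr")
  expect_equal(pr3$locus_id, "p1")
})

test_that("pooled permutation null at n = 6 matches exact enumeration", {
  set.seed(13)
  n <- 6
  f <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("f1", "f2"), paste0("s", 1:n)))
  l <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("l1", "l2"), paste0("s", 1:n)))
  pairs <- tidyr::expand_grid(feature_id = rownames(f), locus_id = rownames(l))
  res <- permutation_fdr_map(f, l, pairs, n_permutations = 600, seed = 2,
                             min_informative = 6)
  exact <- abs(c(spearman_null_exact(l[1, ], f[1, ]),
                 spearman_null_exact(l[2, ], f[1, ]),
                 spearman_null_exact(l[1, ], f[2, ]),
                 spearman_null_exact(l[2, ], f[2, ])))
  # distribution identity up to Monte-Carlo error: compare tail fractions
  # midpoints between atoms of the discrete n = 6 null, to avoid knife-edge
  # floating-point comparisons at the atoms themselves
  for (q in c(0.2, 0.5, 0.7, 0.9) - 1e-9) {
    expect_lt(abs(mean(res$null_abs_rho >= q) - mean(exact >= q)), 0.04)
  }
})

test_that("the empirical-FDR cutoff satisfies its defining tail-ratio rule", {
  coh <- mqtl_cohort(3, n_cpgs = 100, n_snps = 400, n_planted = 25,
                     chrom_length_bp = 4e6)
  pairs <- build_cis_pairs(coh$annotation$cpgs, coh$genotypes$loci, "mqtl")
  res <- permutation_fdr_map(coh$methylation$beta, coh$genotypes$dosage, pairs,
                             fdr = 0.05, n_permutations = 5, seed = 4)
  obs <- abs(res$pairs$rho)
  null <- res$null_abs_rho
  fdr_at <- function(c) (sum(null >= c) / res$n_permutations) / sum(obs >= c)
  expect_lte(fdr_at(res$rho_cutoff), 0.05)
  smaller <- sort(obs[obs < res$rho_cutoff], decreasing = TRUE)
  if (length(smaller)) expect_gt(fdr_at(smaller[1]), 0.05)
  # significance is the superlevel set of |rho|, and p is monotone in |rho|
  expect_equal(res$pairs$significant, obs >= res$rho_cutoff)
  o <- order(obs)
  expect_true(all(diff(res$pairs$p_empirical[o]) <= 1e-12))
})

test_that("observed statistics are invariant to a joint sample permutation", {
  coh <- mqtl_cohort(5, n_cpgs = 60, n_snps = 200, n_planted = 10,
                     chrom_length_bp = 2e6)
  pairs <- build_cis_pairs(coh$annotation$cpgs, coh$genotypes$loci, "mqtl")
  res1 <- permutation_fdr_map(coh$methylation$beta, coh$genotypes$dosage, pairs,
                              n_permutations = 2, seed = 6)
  set.seed(99)
  perm <- sample(ncol(coh$methylation$beta))
  res2 <- permutation_fdr_map(coh$methylation$beta[, perm],
                              coh$genotypes$dosage[, perm], pairs,
                              n_permutations = 2, seed = 6)
  expect_equal(res2$pairs$rho, res1$pairs$rho, tolerance = 1e-12)
})

test_that("tied-genotype permutation null differs from the untied null", {
  # exact at n = 6: the null distribution of rho against a ternary (tied)
  # vector is not the untied rank-permutation distribution
  x_untied <- 1:6
  y <- c(2.3, -1, 0.5, 4, 1.1, -0.7)
  x_tied <- c(0, 0, 1, 1, 2, 2)
  null_untied <- abs(spearman_null_exact(x_untied, y))
  null_tied <- abs(spearman_null_exact(x_tied, y))
  expect_false(isTRUE(all.equal(sort(unique(round(null_untied, 10))),
                                sort(unique(round(null_tied, 10))))))
  # the deep-tail mass differs, which is what moves an FDR cutoff
  q <- quantile(null_untied, 0.95)
  expect_gt(abs(mean(null_tied >= q) - 0.05), 0.005)
})

test_that("LD pruning emits the greedy-selected loci per distance bin", {
  # two loci in perfect LD: only the stronger contributes
  dos <- rbind(a = c(0, 1, 2, 0, 1, 2, 0, 1), b = c(0, 1, 2, 0, 1, 2, 0, 1),
               c = c(2, 0, 1, 1, 0, 2, 1, 0))
  colnames(dos) <- paste0("s", 1:8)
  pairs <- tibble::tibble(feature_id = "f", locus_id = c("a", "b", "c"),
                          distance_bp = c(1000, 2000, 150000),
                          rho = c(0.9, 0.8, 0.5),
                          p_empirical = c(0.001, 0.002, 0.05),
                          significant = TRUE)
  res <- structure(list(pairs = pairs, mode = "mqtl"), class = "association_result")
  qq <- ld_pruned_qq(res, dos)
  expect_setequal(qq$locus_id, c("a", "c"))
  # hand trace of the greedy loop on 4 loci with known R^2 structure
  set.seed(10)
  h <- sample(0:2, 20, replace = TRUE)
  dos2 <- rbind(l1 = h, l2 = h,                       # perfect proxies
                l3 = sample(0:2, 20, replace = TRUE), # independent
                l4 = h)                               # proxy of l1 again
  colnames(dos2) <- paste0("s", 1:20)
  pairs2 <- tibble::tibble(feature_id = "f", locus_id = c("l1", "l2", "l3", "l4"),
                           distance_bp = c(100, 200, 300, 400),
                           rho = c(0.9, 0.85, 0.6, 0.55),
                           p_empirical = c(0.001, 0.002, 0.01, 0.02),
                           significant = TRUE)
  res2 <- structure(list(pairs = pairs2, mode = "mqtl"), class = "association_result")
  qq2 <- ld_pruned_qq(res2, dos2)
  expect_setequal(qq2$locus_id, c("l1", "l3"))
  # mutually independent loci: every p emitted exactly once
  dos3 <- matrix(sample(0:2, 3 * 30, replace = TRUE), 3, 30,
                 dimnames = list(c("a", "b", "c"), paste0("s", 1:30)))
  res3 <- structure(list(pairs = pairs, mode = "mqtl"), class = "association_result")
  expect_equal(nrow(ld_pruned_qq(res3, dos3)), 3)
})
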