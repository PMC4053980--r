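mk_result <- function(feature_id, locus_id, significant = TRUE, mode = "mqtl",
                      fdr = 0.05) {
  structure(list(pairs = tibble::tibble(feature_id = feature_id,
                                        locus_id = locus_id,
                                        rho = 0.9, p_empirical = 1e-4,
                                        distance_bp = 0,
                                        significant = significant),
                 rho_cutoff = 0.5, p_cutoff = 1e-3, fdr = fdr, mode = mode,
                 n_permutations = 1L, null_size = 0L, pair_count = length(feature_id),
                 n_dropped = 0L, seed = 1, null_abs_rho = numeric()),
            class = "association_result")
}

test_that("emQTLs are methylation QTLs that are also expression QTLs", {
  mqtl <- mk_result(c("c1", "c2"), c("s1", "s2"))
  eqtl <- mk_result("g1", "s1", mode = "eqtl")
  aeqtl <- mk_result("aeR1", "s3", mode = "aeqtl")
  em <- find_emqtls(mqtl, eqtl, aeqtl)
  expect_equal(em$snps, "s1")           # via the eQTL arm
  expect_equal(em$genes, "g1")
  # disjoint significant sets give an empty emQTL set
  em0 <- find_emqtls(mk_result("c1", "s9"), eqtl, aeqtl)
  expect_length(em0$snps, 0)
  # mismatched FDR levels are rejected
  expect_error(find_emqtls(mqtl, mk_result("g1", "s1", fdr = 0.1)), "FDR")
})

test_that("aeRegions without gene overlap are reported as orphans", {
  mqtl <- mk_result("c1", "s1")
  eqtl <- mk_result("g0", "sX", significant = FALSE, mode = "eqtl")
  aeqtl <- mk_result(c("aeR1", "aeR2"), c("s1", "s1"), mode = "aeqtl")
  regions <- list(regions = tibble::tibble(
    region_id = c("aeR1", "aeR2"), chrom = "chr1",
    start = c(100, 5000), end = c(200, 5100), sign = 1, n_snps = 2L,
    snp_ids = list("a", "b")))
  genes <- gene_table("g1", "chr1", 150, 400, "+")
  em <- find_emqtls(mqtl, eqtl, aeqtl, aeregions = regions, genes = genes)
  expect_equal(em$genes, "g1")          # aeR1 overlaps g1
  expect_equal(em$orphan_aeregions, "aeR2")
})

test_that("MAF-matched enrichment recovers null, saturated and planted folds", {
  set.seed(30)
  snps <- snp_table(sprintf("r%04d", 1:2000), "chr1", seq_len(2000) * 100,
                    runif(2000, 0.05, 0.5))
  reference <- sample(snps$snp_id, 200)
  # target drawn uniformly at random: fold ~ 1
  target <- sample(snps$snp_id, 200)
  e1 <- maf_matched_enrichment(target, reference, snps, n_draws = 400, seed = 1)
  expect_equal(e1$fold, 1, tolerance = 0.25)
  # reference = all SNPs: fold exactly 1
  e2 <- maf_matched_enrichment(target, snps$snp_id, snps, n_draws = 100, seed = 1)
  expect_equal(e2$fold, 1)
  # constructed 3x enrichment: overlap three times the matched expectation
  base_rate <- 200 / 2000
  n_target <- 200
  want_overlap <- round(3 * base_rate * n_target)  # 60
  inside <- sample(reference, want_overlap)
  outside <- sample(setdiff(snps$snp_id, reference), n_target - want_overlap)
  e3 <- maf_matched_enrichment(c(inside, outside), reference, snps,
                               n_draws = 600, seed = 2)
  expect_equal(e3$fold, 3, tolerance = 0.2)
  # invariance to relabeling of SNP ids
  relab <- snps
  relab$snp_id <- paste0("x", snps$snp_id)
  e4 <- maf_matched_enrichment(paste0("x", c(inside, outside)),
                               paste0("x", reference), relab,
                               n_draws = 600, seed = 2)
  expect_equal(e4$fold, e3$fold)
})

test_that("variance partitioning recovers planted fractions and the 66% ratio", {
  # pure-noise expression gives R^2 ~ 0 for every model
  set.seed(31)
  X <- matrix(sample(0:2, 20 * 60, replace = TRUE), 20, 60,
              dimnames = list(paste0("s", 1:20), paste0("I", 1:60)))
  M <- matrix(runif(10 * 60), 10, 60, dimnames = list(paste0("c", 1:10),
                                                      paste0("I", 1:60)))
  vp0 <- variance_partition(rnorm(60), X, M, seed = 1)
  expect_lt(vp0$r2_seq, 0.15)
  expect_lt(vp0$r2_meth, 0.15)
  # planted single-SNP effect: r2_seq recovers the planted fraction within 0.1
  reps <- sapply(1:20, function(r) {
    set.seed(100 + r)
    g <- sample(0:2, 60, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    planted_frac <- 0.85
    sd_noise <- sd(g) * 0.8 * sqrt(1 / planted_frac - 1)
    y <- 0.8 * g + rnorm(60, 0, sd_noise)
    Xr <- rbind(X[1:19, ], causal = g)
    vp <- variance_partition(y, Xr, M, seed = r)
    vp$r2_seq - planted_frac
  })
  expect_lt(abs(mean(reps)), 0.1)
  # printed-scale ratio: 5.9 / 8.9 rounds to 66%
  expect_equal(round(100 * 5.9 / 8.9), 66)
})

test_that("independent fraction separates independent from mediated methylation", {
  run <- function(mediated, seed) {
    set.seed(seed)
    n <- 60
    g <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    meth <- if (mediated) g / 2 else rnorm(n)
    y <- 0.9 * g + 0.9 * meth + rnorm(n, 0, 0.4)
    X <- rbind(matrix(sample(0:2, 5 * n, replace = TRUE), 5, n), g)
    rownames(X) <- paste0("s", 1:6); colnames(X) <- paste0("I", 1:n)
    M <- rbind(matrix(runif(5 * n), 5, n), meth)
    rownames(M) <- paste0("c", 1:6); colnames(M) <- paste0("I", 1:n)
    variance_partition(y, X, M, seed = seed)$independent_fraction
  }
  indep <- mean(sapply(1:10, function(s) run(FALSE, s)))
  medi <- mean(sapply(1:10, function(s) run(TRUE, s + 50)))
  expect_gt(indep, 0.75)
  expect_lt(medi, 0.25)
})

test_that("proliferation signature variance attribution matches construction", {
  set.seed(33)
  n <- 60
  vec <- rnorm(n)
  markers <- t(sapply(1:10, function(i) 2 * vec + rnorm(n, 0, 0.3)))
  rownames(markers) <- paste0("m", 1:10); colnames(markers) <- paste0("I", 1:n)
  # targets independent of the vector: fraction ~ 0
  t0 <- matrix(rnorm(20 * n), 20, n, dimnames = list(paste0("t", 1:20),
                                                     colnames(markers)))
  pv0 <- proliferation_variance(markers, t0, paste0("m", 1:10))
  expect_lt(abs(pv0$fraction), 0.1)
  # targets built as scaled vector + noise at a 0.4 variance ratio
  z <- (vec - mean(vec)) / sd(vec)
  t1 <- t(sapply(1:30, function(i) sqrt(0.4) * z + rnorm(n, 0, sqrt(0.6))))
  rownames(t1) <- paste0("t", 1:30); colnames(t1) <- colnames(markers)
  pv1 <- proliferation_variance(markers, t1, paste0("m", 1:10))
  expect_equal(pv1$fraction, 0.4, tolerance = 0.08)
  # zero-variance target is skipped, fraction stays defined
  t2 <- rbind(t1, constant = rep(1, n))
  pv2 <- proliferation_variance(markers, t2, paste0("m", 1:10))
  expect_equal(pv2$n_skipped, 1L)
  expect_false(is.na(pv2$fraction))
  expect_error(proliferation_variance(markers, t1, "m1"), ">= 2")
})

test_that("Fisher term enrichment matches the hypergeometric tail and fold formula", {
  # term in all of the test set and half the background: fold = 2
  bg <- paste0("g", 1:100)
  test <- paste0("g", 1:10)
  ann <- tibble::tibble(gene_id = paste0("g", c(1:10, 11:50)), term = "T1")
  res <- term_enrichment(test, bg, ann)
  expect_equal(res$fold, (10 / 10) / (50 / 100))
  # contingency (a=8, b=2, c=10, d=80): p equals the hypergeometric tail sum
  bg2 <- paste0("g", 1:100)
  test2 <- paste0("g", 1:10)
  ann2 <- tibble::tibble(gene_id = paste0("g", c(1:8, 11:20)), term = "T2")
  res2 <- term_enrichment(test2, bg2, ann2)
  # oracle: two-sided Fisher p by enumerating hypergeometric outcomes
  m <- 18; k <- 10; N <- 100
  probs <- dhyper(0:10, m, N - m, k)
  p_oracle <- sum(probs[probs <= dhyper(8, m, N - m, k) * (1 + 1e-7)])
  expect_equal(res2$p_value, p_oracle, tolerance = 1e-10)
  expect_true(all(res2$p_adjusted >= res2$p_value))
  expect_error(term_enrichment(c("zz"), bg2, ann2), "subset")
})
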