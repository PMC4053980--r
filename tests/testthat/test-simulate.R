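test_that("a fixed seed reproduces the cohort exactly", {
  a <- small_cohort(3)
  b <- small_cohort(3)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$methylation$beta, b$methylation$beta)
  expect_identical(a$expression$level, b$expression$level)
  expect_identical(a$ae_track$raw_ratio, b$ae_track$raw_ratio)
  expect_identical(a$truth, b$truth)
})

test_that("generated containers satisfy the core type invariants", {
  coh <- small_cohort(5)
  expect_s3_class(coh$genotypes, "genotype_matrix")      # constructors validate
  expect_s3_class(coh$methylation, "methylation_matrix")
  expect_true(all(coh$methylation$beta > 0 & coh$methylation$beta < 1))
  expect_equal(ncol(coh$expression$level), 58)
  expect_equal(ncol(coh$methylation$beta), 62)
  # AE ratios exist exactly at heterozygous entries
  expect_identical(is.na(coh$ae_track$raw_ratio), coh$genotypes$dosage != 1)
})

test_that("annotation places CpGs with the configured TSS enrichment", {
  cfg <- sim_config(n_genes = 100, n_cpgs = 2000, n_snps = 10,
                    chrom_length_bp = 2e7, tss_cpg_fraction = 0.4, seed = 9)
  ann <- simulate_annotation(cfg)
  near <- vapply(ann$cpgs$position,
                 function(p) any(abs(p - ann$genes$tss) <= 1500), TRUE)
  # direct count: placed fraction plus uniform background, so at least ~0.4
  expect_gt(mean(near), 0.35)
  expect_lt(mean(near), 0.55)
  # genes do not overlap
  g <- ann$genes[order(ann$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  # n_genes = 0 leaves every CpG intergenic
  ann0 <- simulate_annotation(sim_config(n_genes = 0, n_cpgs = 50, n_snps = 10,
                                         chrom_length_bp = 1e6, seed = 2))
  expect_equal(nrow(ann0$genes), 0)
  expect_true(all(classify_position("chr1", ann0$cpgs$position, ann0$genes) ==
                    "intergenic"))
})

test_that("genotypes follow Hardy-Weinberg and the LD flip model", {
  snps <- snp_table(sprintf("r%03d", 1:60), "chr1",
                    seq(1000, by = 400, length.out = 60), rep(0.5, 60))
  cfg <- sim_config(n_samples = 800, n_genes = 0, n_cpgs = 1, n_snps = 60,
                    chrom_length_bp = 1e6, ld_block_bp = 1e9, seed = 4)
  # maf 0.5 and independent blocks: mean dosage ~ 1 (binomial expectation)
  cfg$ld_flip <- 0
  g <- simulate_genotypes(snps, cfg)
  expect_equal(mean(g$dosage), 1, tolerance = 0.05)
  # flip probability 0 inside one block: perfect copies, R^2 = 1
  r2_adj <- sapply(2:60, function(i) cor(g$dosage[i, ], g$dosage[i - 1, ])^2)
  expect_true(all(r2_adj > 0.999))
  # flip probability 0.5: adjacent R^2 ~ 0 (independence)
  cfg$ld_flip <- 0.5
  g2 <- simulate_genotypes(snps, cfg)
  r2_adj2 <- sapply(2:60, function(i) cor(g2$dosage[i, ], g2$dosage[i - 1, ])^2)
  expect_lt(mean(r2_adj2), 0.02)
})

test_that("planted methylation effects order group means by dosage", {
  coh <- small_cohort(11)
  tr <- coh$truth$mqtl
  strong <- tr[which.max(abs(tr$effect_size) * (tr$target_rho > 0.6)), ]
  b <- coh$methylation$beta[strong$probe_id, ]
  g <- coh$genotypes$dosage[strong$snp_id, ]
  mns <- tapply(b, g, mean)
  expect_true(all(diff(mns[order(as.numeric(names(mns)))]) *
                    sign(strong$effect_size) > 0))
  # no effects and no noise: every sample equals the CpG baseline
  cfg0 <- sim_config(n_genes = 0, n_cpgs = 20, n_snps = 20, chrom_length_bp = 1e6,
                     n_mqtl = 0, meth_logit_sd = 0, seed = 12,
                     n_eqtl = 0, n_coupling = 0, n_ae_regions = 0)
  coh0 <- simulate_cohort(cfg0)
  expect_equal(apply(coh0$methylation$beta, 1, sd), setNames(rep(0, 20),
               rownames(coh0$methylation$beta)))
})

test_that("population mean-beta distribution is bimodal by the modality rule", {
  coh <- small_cohort(13)
  expect_equal(count_modes(rowMeans(coh$methylation$beta)), 2)
})

test_that("expression carries the planted couplings and eQTLs", {
  # zero effects and zero noise give constant rows
  cfg0 <- sim_config(n_genes = 10, n_cpgs = 20, n_snps = 20, chrom_length_bp = 1e6,
                     n_mqtl = 0, n_eqtl = 0, n_coupling = 0, n_ae_regions = 0,
                     expr_sd = 0, seed = 14)
  coh0 <- simulate_cohort(cfg0)
  expect_true(all(apply(coh0$expression$level, 1, sd) < 1e-12))
  # one strong positive coupling: sample-level Spearman above 0.9
  coh <- simulate_cohort(sim_config(
    n_genes = 20, n_cpgs = 100, n_snps = 50, chrom_length_bp = 2e6,
    n_mqtl = 0, n_eqtl = 0, n_ae_regions = 0,
    n_coupling = 1, coupling_rho = c(0.995, 0.999),
    coupling_pos_fraction = 1, seed = 15))
  cp <- coh$truth$coupling
  expect_equal(nrow(cp), 1)
  samples <- colnames(coh$expression$level)
  rho <- spearman_rho(coh$methylation$beta[cp$probe_id, samples],
                      coh$expression$level[cp$gene_id, ])
  expect_gt(rho, 0.9)
})

test_that("allelic tracks honor carrier structure and region constraints", {
  ae <- ae_cohort(16, n_snps = 200, n_regions = 5)
  # homozygous entries are missing by definition
  expect_true(all(is.na(ae$track$raw_ratio[ae$genotypes$dosage != 1])))
  # every planted region has at least two carriers sharing the sign
  for (k in seq_len(nrow(ae$truth))) {
    expect_gte(length(ae$truth$carriers[[k]]), 2)
  }
  # regions with fewer than 2 SNPs are rejected
  cfg <- sim_config(n_genes = 0, n_cpgs = 1, n_snps = 50, chrom_length_bp = 1e6,
                    seed = 1)
  bad <- tibble::tibble(region_id = "r1", first_index = 1L, n_snps = 1L, sign = 1)
  expect_error(simulate_allelic_expression(ae$genotypes, ae$genotypes$loci, bad, cfg),
               ">= 2 SNPs")
})

test_that("a cohort written to disk reads back equal", {
  coh <- small_cohort(21)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_equal(read_omic_matrix(file.path(dir, "genotypes.tsv"), "genotype"),
               coh$genotypes$dosage)
  expect_equal(read_omic_matrix(file.path(dir, "methylation.tsv"), "beta"),
               coh$methylation$beta, tolerance = 1e-12)
  ae <- read_omic_matrix(file.path(dir, "ae_ratios.tsv"), "ae_ratio")
  expect_identical(is.na(ae), is.na(coh$ae_track$raw_ratio))
  genes <- read_feature_table(file.path(dir, "genes.tsv"), "gene")
  expect_equal(genes, coh$annotation$genes)
  isl <- read_bed(file.path(dir, "islands.bed"))
  expect_equal(isl$start, coh$annotation$islands$start)
})
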