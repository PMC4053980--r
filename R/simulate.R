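# Synthetic multi-omic cohort generator. Emulates the statistical structure
# the analysis assumes: a cohort of 62 individuals (expression assayed on a
# 58-sample subset), biallelic SNP dosages under Hardy-Weinberg with
# block-copy LD, bimodal methylation beta values with planted cis-mQTL
# effects acting on the logit scale, expression with planted cis-eQTLs and
# signed methylation coupling, allelic log2 ratios defined at heterozygous
# entries with contiguous same-sign AE regions, and BED-style chromatin mark
# tracks for a handful of pseudo cell lines. Every planted effect is recorded
# in truth tables so downstream stages can be scored against ground truth.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the emulated study conditions: 62 samples with
#' expression on 58 of them, MAF between 10% and 50%, a bimodal beta-value
#' landscape, planted cis effects with Spearman correlations in the ranges
#' used by the recovery analyses, and 5-SNP allelic-expression regions at
#' signal 0.6 over noise SD 0.15.
#'
#' @param n_samples Cohort size (default 62).
#' @param n_expression_samples Samples with expression data (default 58).
#' @param n_genes,n_cpgs,n_snps Feature counts (defaults 200 / 2000 / 5000).
#' @param chrom_length_bp Length of the single synthetic chromosome
#'   (default 5e7); multiple chromosomes can be emulated by concatenating
#'   cohorts.
#' @param maf_range Minor-allele-frequency range for drawn SNPs
#'   (default 0.1-0.5).
#' @param ld_block_bp LD block span; SNPs within a block are copied from their
#'   left neighbor with per-haplotype allele toggling (default 25000, two to
#'   three SNPs per block at the default SNP density).
#' @param ld_flip Per-haplotype toggle probability within a block; adjacent
#'   dosage correlation is `1 - 2 * ld_flip` (default 0.002, keeping
#'   within-block pairwise R^2 above the usual 0.8 proxy cutoff while blocks
#'   stay mutually independent).
#' @param hypo_fraction Fraction of CpGs in the low-methylation mode
#'   (default 0.55).
#' @param tss_cpg_fraction Fraction of CpGs placed within +/-1,500 bp of a TSS
#'   (default 0.4).
#' @param island_tss_fraction Fraction of TSSs carrying a CpG island
#'   (default 0.6).
#' @param n_mqtl,mqtl_rho Number of planted CpG~SNP effects and the target
#'   Spearman-correlation range (defaults 100 and 0.4-0.8).
#' @param n_eqtl,eqtl_rho Planted gene~SNP effects (defaults 40 and 0.5-0.8).
#' @param n_coupling,coupling_rho Planted gene~CpG couplings and target
#'   correlation range (defaults 30 and 0.5-0.8).
#' @param coupling_pos_fraction Fraction of couplings with positive sign
#'   (default 1/3, the observed sign split for promoter-proximal pairs).
#' @param n_ae_regions,ae_region_size Planted allelic-expression regions and
#'   SNPs per region (defaults 50 and 5).
#' @param ae_signal Persistent |log2 ratio| inside a planted region
#'   (default 0.6).
#' @param ae_carrier_fraction Expected fraction of samples carrying a region's
#'   imbalance (default 0.3; at least 2 carriers are forced).
#' @param meth_logit_sd Per-entry methylation noise SD on the logit scale
#'   (default 0.4).
#' @param expr_sd Per-entry expression noise SD (default 1).
#' @param ae_noise_sd Allelic-ratio noise SD (default 0.15).
#' @param n_mark_cell_lines Pseudo cell lines per chromatin mark, at most 5
#'   (default 5; the repressive mark uses 2, as in typical track
#'   availability).
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 62, n_expression_samples = 58,
                       n_genes = 200, n_cpgs = 2000, n_snps = 5000,
                       chrom_length_bp = 5e7,
                       maf_range = c(0.1, 0.5),
                       ld_block_bp = 25000, ld_flip = 0.002,
                       hypo_fraction = 0.55,
                       tss_cpg_fraction = 0.4,
                       island_tss_fraction = 0.6,
                       n_mqtl = 100, mqtl_rho = c(0.4, 0.8),
                       n_eqtl = 40, eqtl_rho = c(0.5, 0.8),
                       n_coupling = 30, coupling_rho = c(0.5, 0.8),
                       coupling_pos_fraction = 1 / 3,
                       n_ae_regions = 50, ae_region_size = 5,
                       ae_signal = 0.6, ae_carrier_fraction = 0.3,
                       meth_logit_sd = 0.4, expr_sd = 1, ae_noise_sd = 0.15,
                       n_mark_cell_lines = 5,
                       seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    if (n_samples < 1 || n_cpgs < 1 || n_snps < 1) abort("counts must be >= 1")
    if (n_genes < 0) abort("n_genes must be >= 0")
    if (n_expression_samples > n_samples) abort("n_expression_samples must be <= n_samples")
    if (maf_range[1] <= 0 || maf_range[2] > 0.5) abort("maf_range must lie in (0, 0.5]")
    fr <- c(hypo_fraction, tss_cpg_fraction, island_tss_fraction,
            coupling_pos_fraction, ae_carrier_fraction)
    if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
    if (ld_flip < 0 || ld_flip > 0.5) abort("ld_flip must lie in [0, 0.5]")
    if (ae_region_size < 2) abort("an AE region needs >= 2 SNPs")
    if (n_genes > 0 && chrom_length_bp / n_genes < 6e4) {
      abort("chromosome too short to place the requested genes without overlap")
    }
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d samples (%d with expression), %d genes, ",
                     "%d CpGs, %d SNPs on %.0f Mb, seed %d\n"),
              x$n_samples, x$n_expression_samples, x$n_genes, x$n_cpgs,
              x$n_snps, x$chrom_length_bp / 1e6, x$seed))
  invisible(x)
}

#' Simulate the genome annotation of a cohort
#'
#' Places non-overlapping genes on one synthetic chromosome, CpG probes with
#' excess density within +/-1,500 bp of TSSs and inside island intervals,
#' uniformly placed SNPs, CpG-island intervals at a subset of TSSs, and
#' chromatin-mark interval tracks (DHS, H3K4me3, H3K27me3, H3K36me3) for the
#' pseudo cell lines, enriched at a subset of TSSs / gene bodies.
#'
#' @param config A [sim_config()].
#' @return A list: `genes`, `cpgs`, `snps`, `islands`, `marks`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom <- "chr1"
  L <- config$chrom_length_bp
  ng <- config$n_genes
  if (ng > 0) {
    slot <- floor(L / ng)
    len <- round(runif(ng, 5e3, 5e4))
    start <- (seq_len(ng) - 1) * slot + round(runif(ng, 2e3, pmax(2e3, slot - len - 2e3)))
    end <- start + len
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    tss <- ifelse(strand == "+", start, end)
    tes <- ifelse(strand == "+", end, start)
    genes <- gene_table(sprintf("gene%04d", seq_len(ng)), chrom, tss, tes, strand)
  } else {
    genes <- gene_table(character(), character(), numeric(), numeric(), character())
  }
  # CpG islands: a subset of TSSs plus a few intergenic islands
  if (ng > 0) {
    isl_tss <- genes$tss[runif(ng) < config$island_tss_fraction]
    isl <- tibble::tibble(start = pmax(0, isl_tss - 500), end = isl_tss + 500)
  } else {
    isl <- tibble::tibble(start = numeric(), end = numeric())
  }
  n_inter <- max(1, round(0.1 * max(ng, 10)))
  ipos <- sort(sample.int(L - 2000, n_inter))
  isl <- dplyr::bind_rows(isl, tibble::tibble(start = ipos, end = ipos + 1000))
  isl <- isl[order(isl$start), , drop = FALSE]
  islands <- genomic_intervals(chrom, isl$start, isl$end,
                               sprintf("island%03d", seq_len(nrow(isl))))
  # CpGs: TSS-proximal fraction plus uniform remainder
  n_tss_cpg <- if (ng > 0) round(config$tss_cpg_fraction * config$n_cpgs) else 0
  pos_tss <- if (n_tss_cpg > 0) {
    anchor <- sample(genes$tss, n_tss_cpg, replace = TRUE)
    pmin(pmax(anchor + round(runif(n_tss_cpg, -1500, 1500)), 0), L - 1)
  } else numeric()
  pos_rest <- sample.int(L, config$n_cpgs - n_tss_cpg)
  pos <- sort(unique(c(pos_tss, pos_rest)))
  while (length(pos) < config$n_cpgs) {
    pos <- sort(unique(c(pos, sample.int(L, config$n_cpgs - length(pos)))))
  }
  pos <- pos[seq_len(config$n_cpgs)]
  near_tss <- if (ng > 0) {
    vapply(pos, function(p) any(abs(p - genes$tss) <= 1500), TRUE)
  } else rep(FALSE, length(pos))
  probe_type <- ifelse(runif(length(pos)) < ifelse(near_tss, 0.7, 0.2), "I", "II")
  cpgs <- cpg_table(sprintf("cg%05d", seq_along(pos)), chrom, pos, probe_type)
  # SNPs: uniform, unique positions, MAF drawn from the configured range
  spos <- sort(sample.int(L, config$n_snps))
  snps <- snp_table(sprintf("rs%05d", seq_along(spos)), chrom, spos,
                    runif(config$n_snps, config$maf_range[1], config$maf_range[2]))
  # Mark tracks
  marks <- list()
  mark_lines <- c(DHS = config$n_mark_cell_lines,
                  H3K4me3 = config$n_mark_cell_lines,
                  H3K27me3 = min(2, config$n_mark_cell_lines),
                  H3K36me3 = config$n_mark_cell_lines)
  if (ng > 0) {
    for (m in names(mark_lines)) {
      for (cl in seq_len(mark_lines[[m]])) {
        if (m %in% c("DHS", "H3K4me3")) {
          at <- genes$tss[runif(ng) < 0.4]
          iv <- tibble::tibble(start = pmax(0, at - 1000), end = at + 1000)
        } else if (m == "H3K36me3") {
          gi <- which(runif(ng) < 0.3)
          iv <- tibble::tibble(start = genes$start[gi], end = genes$end[gi])
        } else {
          gi <- which(runif(ng) < 0.2)
          iv <- tibble::tibble(start = genes$start[gi],
                               end = genes$start[gi] + 2000)
        }
        if (nrow(iv)) {
          marks[[length(marks) + 1]] <- tibble::tibble(
            mark = m, cell_line = sprintf("FB%02d", cl),
            chrom = chrom, start = iv$start, end = iv$end)
        }
      }
    }
  }
  marks <- if (length(marks)) dplyr::bind_rows(marks) else
    tibble::tibble(mark = character(), cell_line = character(),
                   chrom = character(), start = numeric(), end = numeric())
  list(genes = genes, cpgs = cpgs, snps = snps, islands = islands, marks = marks)
}

#' Simulate genotype dosages with Hardy-Weinberg sampling and block LD
#'
#' The first SNP of each LD block draws two haplotypes per sample as
#' independent Bernoulli(MAF); subsequent SNPs in the block copy the previous
#' SNP's haplotypes, toggling each allele with probability `ld_flip`, so the
#' adjacent-SNP dosage correlation is `1 - 2 * ld_flip`. The returned locus
#' table carries the realized (folded) empirical allele frequency as `maf`.
#'
#' @param snps A [snp_table()] (positions define block membership).
#' @param config A [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(snps, config) {
  set.seed(config$seed + 1L)
  n <- config$n_samples
  m <- nrow(snps)
  block <- floor(snps$position / config$ld_block_bp)
  h1 <- matrix(0L, m, n)
  h2 <- matrix(0L, m, n)
  for (i in seq_len(m)) {
    new_block <- i == 1 || block[i] != block[i - 1] ||
      snps$chrom[i] != snps$chrom[i - 1]
    if (new_block) {
      p <- snps$maf[i]
      h1[i, ] <- rbinom(n, 1, p)
      h2[i, ] <- rbinom(n, 1, p)
    } else {
      f1 <- rbinom(n, 1, config$ld_flip)
      f2 <- rbinom(n, 1, config$ld_flip)
      h1[i, ] <- (h1[i - 1, ] + f1) %% 2L
      h2[i, ] <- (h2[i - 1, ] + f2) %% 2L
    }
  }
  dosage <- h1 + h2
  dimnames(dosage) <- list(snps$snp_id, sprintf("S%03d", seq_len(n)))
  freq <- rowMeans(dosage) / 2
  loci <- snps
  loci$maf <- pmin(freq, 1 - freq)
  genotype_matrix(dosage, loci)
}

# Convert a target correlation into a linear effect size per dosage given the
# predictor SD and the residual noise SD: b = r / sqrt(1 - r^2) * sd_e / sd_g.
effect_from_rho <- function(rho, sd_g, sd_e) {
  rho / sqrt(1 - rho^2) * sd_e / pmax(sd_g, 1e-8)
}

#' Simulate methylation beta values with planted cis-mQTL effects
#'
#' Each CpG draws a baseline from a two-component logit-normal mixture (hypo
#' mode centered near beta 0.12, hyper mode near 0.87). Planted effects add
#' `effect_size * dosage` on the logit scale; i.i.d. Gaussian noise is also
#' applied on the logit scale, so values stay strictly inside (0, 1) by
#' construction (the inverse logit cannot leave the unit interval, whatever
#' the effect size).
#'
#' @param genotypes A [genotype_matrix()].
#' @param cpgs A [cpg_table()].
#' @param effects Tibble of planted effects: `probe_id`, `snp_id`,
#'   `effect_size` (logit shift per dosage copy). All ids must exist.
#' @param config A [sim_config()].
#' @return A [methylation_matrix()].
#' @export
simulate_methylation <- function(genotypes, cpgs, effects, config) {
  set.seed(config$seed + 2L)
  n <- config$n_samples
  m <- nrow(cpgs)
  if (nrow(effects)) {
    if (!all(effects$probe_id %in% cpgs$probe_id)) abort("effect probe_id not in cpgs")
    if (!all(effects$snp_id %in% genotypes$loci$snp_id)) abort("effect snp_id not in genotypes")
    if (any(!is.finite(effects$effect_size))) abort("effect sizes must be finite")
  }
  hypo <- runif(m) < config$hypo_fraction
  baseline <- ifelse(hypo, rnorm(m, -2.0, 0.5), rnorm(m, 1.9, 0.5))
  logit <- matrix(baseline, m, n) +
    matrix(rnorm(m * n, 0, config$meth_logit_sd), m, n)
  if (nrow(effects)) {
    pi <- match(effects$probe_id, cpgs$probe_id)
    si <- match(effects$snp_id, genotypes$loci$snp_id)
    for (k in seq_len(nrow(effects))) {
      logit[pi[k], ] <- logit[pi[k], ] +
        effects$effect_size[k] * genotypes$dosage[si[k], ]
    }
  }
  beta <- plogis(logit)
  dimnames(beta) <- list(cpgs$probe_id, colnames(genotypes$dosage))
  methylation_matrix(beta, cpgs)
}

#' Simulate expression with planted eQTLs and methylation coupling
#'
#' Gene expression is baseline + sum of SNP dosage effects + sum of signed
#' couplings to linked CpG beta values + Gaussian noise, restricted to the
#' expression sample subset.
#'
#' @param genotypes A [genotype_matrix()].
#' @param methylation A [methylation_matrix()] on the full cohort.
#' @param genes A [gene_table()].
#' @param eqtl_effects Tibble `gene_id`, `snp_id`, `effect_size`.
#' @param couplings Tibble `gene_id`, `probe_id`, `coupling` (signed
#'   coefficient on the CpG's beta value).
#' @param config A [sim_config()].
#' @return An [expression_matrix()] on the first `n_expression_samples`
#'   samples.
#' @export
simulate_expression <- function(genotypes, methylation, genes,
                                eqtl_effects, couplings, config) {
  set.seed(config$seed + 3L)
  samples <- colnames(genotypes$dosage)[seq_len(config$n_expression_samples)]
  ng <- nrow(genes)
  level <- matrix(rnorm(ng, 8, 2), ng, length(samples)) +
    matrix(rnorm(ng * length(samples), 0, config$expr_sd), ng, length(samples))
  dimnames(level) <- list(genes$gene_id, samples)
  if (nrow(eqtl_effects)) {
    if (!all(eqtl_effects$gene_id %in% genes$gene_id)) abort("eQTL gene_id not in genes")
    if (!all(eqtl_effects$snp_id %in% genotypes$loci$snp_id)) abort("eQTL snp_id not in genotypes")
    for (k in seq_len(nrow(eqtl_effects))) {
      g <- genotypes$dosage[eqtl_effects$snp_id[k], samples]
      level[eqtl_effects$gene_id[k], ] <- level[eqtl_effects$gene_id[k], ] +
        eqtl_effects$effect_size[k] * g
    }
  }
  if (nrow(couplings)) {
    if (!all(couplings$probe_id %in% methylation$probes$probe_id)) {
      abort("coupled CpG not present in the simulated methylation matrix")
    }
    for (k in seq_len(nrow(couplings))) {
      b <- methylation$beta[couplings$probe_id[k], samples]
      level[couplings$gene_id[k], ] <- level[couplings$gene_id[k], ] +
        couplings$coupling[k] * b
    }
  }
  expression_matrix(level, genes)
}

#' Simulate an allelic-expression log-ratio track with planted regions
#'
#' Ratios are defined only where the dosage equals 1 (heterozygous entries).
#' Inside a planted region, carrier samples get a persistent signed log2
#' ratio (the region's sign is shared across carriers) plus noise; everywhere
#' else the track is pure noise around zero.
#'
#' @param genotypes A [genotype_matrix()].
#' @param snps The [snp_table()] backing the track (same order as genotypes).
#' @param planted_regions Tibble with `region_id`, `first_index`, `n_snps`
#'   (consecutive track indices) and `sign`; built by [simulate_cohort()] or
#'   by hand. Regions need >= 2 SNPs.
#' @param config A [sim_config()].
#' @return A list: `track` (an [allele_ratio_track()]) and `truth` (the region
#'   table augmented with member `snp_ids` and carrier samples).
#' @export
simulate_allelic_expression <- function(genotypes, snps, planted_regions, config) {
  set.seed(config$seed + 4L)
  n <- config$n_samples
  m <- nrow(snps)
  if (nrow(planted_regions) && any(planted_regions$n_snps < 2)) {
    abort("planted AE regions need >= 2 SNPs")
  }
  het <- genotypes$dosage == 1
  raw <- matrix(NA_real_, m, n, dimnames = dimnames(genotypes$dosage))
  raw[het] <- rnorm(sum(het), 0, config$ae_noise_sd)
  truth <- planted_regions
  truth$snp_ids <- vector("list", nrow(truth))
  truth$carriers <- vector("list", nrow(truth))
  if (nrow(planted_regions)) {
    for (k in seq_len(nrow(planted_regions))) {
      idx <- planted_regions$first_index[k] +
        seq_len(planted_regions$n_snps[k]) - 1L
      if (max(idx) > m) abort("planted region runs past the SNP track")
      carriers <- which(runif(n) < config$ae_carrier_fraction)
      if (length(carriers) < 2) carriers <- sample.int(n, 2)
      sgn <- planted_regions$sign[k]
      for (j in carriers) {
        obs <- idx[het[idx, j]]
        raw[obs, j] <- sgn * config$ae_signal +
          rnorm(length(obs), 0, config$ae_noise_sd)
      }
      truth$snp_ids[[k]] <- snps$snp_id[idx]
      truth$carriers[[k]] <- colnames(raw)[carriers]
    }
  }
  list(track = allele_ratio_track(raw, snps), truth = truth)
}

pick_cis_locus <- function(anchor_pos, loci_pos, window = 250000) {
  ok <- which(abs(loci_pos - anchor_pos) <= window)
  if (!length(ok)) return(NA_integer_)
  ok[sample.int(length(ok), 1)]
}

#' Simulate a full synthetic cohort with planted effects
#'
#' Orchestrates the annotation, genotype, methylation, expression and
#' allelic-expression generators and plants cis effects with the configured
#' target correlations. Effect sizes are derived from the target Spearman
#' correlations via the linear-model relation
#' `b = rho / sqrt(1 - rho^2) * sd_noise / sd_dosage`.
#'
#' @param config A [sim_config()].
#' @return An object of class `cohort`: the annotation tables, the four assay
#'   containers and a `truth` list (`mqtl`, `eqtl`, `coupling`, `ae_regions`
#'   tibbles of planted effects).
#' @export
simulate_cohort <- function(config = sim_config()) {
  ann <- simulate_annotation(config)
  geno <- simulate_genotypes(ann$snps, config)
  set.seed(config$seed + 10L)
  sd_g <- apply(geno$dosage, 1, sd)
  # planted mQTLs: variable CpGs paired with a SNP inside the cis window
  n_mqtl <- min(config$n_mqtl, nrow(ann$cpgs))
  mqtl <- tibble::tibble(probe_id = character(), snp_id = character(),
                         target_rho = numeric(), effect_size = numeric())
  if (n_mqtl > 0) {
    probes <- sample(ann$cpgs$probe_id, n_mqtl)
    rows <- match(probes, ann$cpgs$probe_id)
    snp_idx <- vapply(ann$cpgs$position[rows], pick_cis_locus,
                      0L, loci_pos = ann$snps$position)
    keep <- !is.na(snp_idx)
    rho <- runif(sum(keep), config$mqtl_rho[1], config$mqtl_rho[2])
    mqtl <- tibble::tibble(
      probe_id = probes[keep],
      snp_id = ann$snps$snp_id[snp_idx[keep]],
      target_rho = rho,
      effect_size = effect_from_rho(rho, sd_g[snp_idx[keep]], config$meth_logit_sd))
  }
  meth <- simulate_methylation(geno, ann$cpgs, mqtl, config)
  # planted eQTLs and methylation couplings
  set.seed(config$seed + 11L)
  eqtl <- tibble::tibble(gene_id = character(), snp_id = character(),
                         target_rho = numeric(), effect_size = numeric())
  coupling <- tibble::tibble(gene_id = character(), probe_id = character(),
                             sign = numeric(), target_rho = numeric(),
                             coupling = numeric())
  if (nrow(ann$genes) > 0) {
    n_eqtl <- min(config$n_eqtl, nrow(ann$genes))
    if (n_eqtl > 0) {
      gsel <- sample(ann$genes$gene_id, n_eqtl)
      rows <- match(gsel, ann$genes$gene_id)
      mid <- (ann$genes$start[rows] + ann$genes$end[rows]) / 2
      snp_idx <- vapply(mid, pick_cis_locus, 0L, loci_pos = ann$snps$position)
      keep <- !is.na(snp_idx)
      rho <- runif(sum(keep), config$eqtl_rho[1], config$eqtl_rho[2])
      eqtl <- tibble::tibble(
        gene_id = gsel[keep],
        snp_id = ann$snps$snp_id[snp_idx[keep]],
        target_rho = rho,
        effect_size = effect_from_rho(rho, sd_g[snp_idx[keep]], config$expr_sd))
    }
    n_cpl <- min(config$n_coupling, nrow(ann$genes))
    if (n_cpl > 0) {
      gsel <- setdiff(ann$genes$gene_id, eqtl$gene_id)
      gsel <- sample(gsel, min(n_cpl, length(gsel)))
      rows <- match(gsel, ann$genes$gene_id)
      mid <- (ann$genes$start[rows] + ann$genes$end[rows]) / 2
      cpg_idx <- vapply(mid, pick_cis_locus, 0L, loci_pos = ann$cpgs$position)
      keep <- !is.na(cpg_idx)
      sgn <- ifelse(runif(sum(keep)) < config$coupling_pos_fraction, 1, -1)
      rho <- runif(sum(keep), config$coupling_rho[1], config$coupling_rho[2])
      sd_b <- apply(meth$beta[cpg_idx[keep], , drop = FALSE], 1, sd)
      coupling <- tibble::tibble(
        gene_id = gsel[keep],
        probe_id = ann$cpgs$probe_id[cpg_idx[keep]],
        sign = sgn,
        target_rho = rho,
        coupling = sgn * effect_from_rho(rho, sd_b, config$expr_sd))
    }
  }
  expr <- simulate_expression(geno, meth, ann$genes, eqtl, coupling, config)
  # planted AE regions: non-overlapping consecutive SNP runs
  set.seed(config$seed + 12L)
  n_reg <- config$n_ae_regions
  size <- config$ae_region_size
  max_start <- nrow(ann$snps) - size + 1L
  slots <- floor(max_start / max(n_reg, 1))
  regions <- tibble::tibble(region_id = character(), first_index = integer(),
                            n_snps = integer(), sign = numeric())
  if (n_reg > 0) {
    if (slots < size) abort("too many AE regions for the SNP track")
    first <- (seq_len(n_reg) - 1L) * slots +
      sample.int(max(1L, slots - size), n_reg, replace = TRUE)
    regions <- tibble::tibble(region_id = sprintf("true_aeR%03d", seq_len(n_reg)),
                              first_index = as.integer(first),
                              n_snps = size,
                              sign = sample(c(-1, 1), n_reg, replace = TRUE))
  }
  ae <- simulate_allelic_expression(geno, geno$loci, regions, config)
  structure(list(annotation = ann, genotypes = geno, methylation = meth,
                 expression = expr, ae_track = ae$track,
                 truth = list(mqtl = mqtl, eqtl = eqtl, coupling = coupling,
                              ae_regions = ae$truth),
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>\n")
  print(x$config)
  cat(sprintf("  planted: %d mQTLs, %d eQTLs, %d couplings, %d AE regions\n",
              nrow(x$truth$mqtl), nrow(x$truth$eqtl), nrow(x$truth$coupling),
              nrow(x$truth$ae_regions)))
  invisible(x)
}

#' Write a simulated cohort to a directory of TSV/BED files
#'
#' Emits the genotype, beta, expression and allelic-ratio matrices as TSV,
#' the coordinate tables as TSV, islands and marks as BED, and the planted
#' effects as `truth_*.tsv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_omic_matrix(cohort$genotypes$dosage, p("genotypes.tsv"), "snp_id")
  write_omic_matrix(cohort$methylation$beta, p("methylation.tsv"), "probe_id")
  write_omic_matrix(cohort$expression$level, p("expression.tsv"), "gene_id")
  write_omic_matrix(cohort$ae_track$raw_ratio, p("ae_ratios.tsv"), "snp_id")
  readr::write_tsv(cohort$annotation$genes, p("genes.tsv"), progress = FALSE)
  readr::write_tsv(cohort$annotation$cpgs, p("cpgs.tsv"), progress = FALSE)
  readr::write_tsv(cohort$genotypes$loci, p("snps.tsv"), progress = FALSE)
  write_bed(cohort$annotation$islands, p("islands.bed"))
  readr::write_tsv(cohort$annotation$marks, p("marks.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth$mqtl, p("truth_mqtl.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth$eqtl, p("truth_eqtl.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth$coupling, p("truth_coupling.tsv"), progress = FALSE)
  readr::write_tsv(dplyr::select(cohort$truth$ae_regions, -dplyr::any_of(c("snp_ids", "carriers"))),
                   p("truth_ae_regions.tsv"), progress = FALSE)
  invisible(dir)
}
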