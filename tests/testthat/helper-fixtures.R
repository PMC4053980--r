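# Shared fixture builders. Everything is generated in code; no stored data.

tiny_track <- function(values, samples = 1, positions = NULL) {
  # values: vector (one sample) or matrix (loci x samples) with NA allowed
  m <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (ncol(m) < samples) m <- cbind(m, matrix(NA_real_, nrow(m), samples - ncol(m)))
  if (is.null(positions)) positions <- seq_len(nrow(m)) * 100
  dimnames(m) <- list(sprintf("s%03d", seq_len(nrow(m))),
                      sprintf("I%02d", seq_len(ncol(m))))
  allele_ratio_track(m, snp_table(rownames(m), "chr1", positions,
                                  rep(0.3, nrow(m))))
}

small_cohort <- function(seed = 42, ...) {
  simulate_cohort(sim_config(n_genes = 30, n_cpgs = 150, n_snps = 400,
                             chrom_length_bp = 6e6, n_mqtl = 20, n_eqtl = 8,
                             n_coupling = 6, n_ae_regions = 10, seed = seed,
                             ...))
}

# cohort for mQTL calibration experiments: CpGs with planted cis-SNP effects
# spanning a target correlation range, no genes/AE
mqtl_cohort <- function(seed, n_cpgs = 500, n_snps = 2000, n_planted = 100,
                        rho_range = c(0.4, 0.8), chrom_length_bp = 2e7) {
  cfg <- sim_config(n_genes = 0, n_cpgs = n_cpgs, n_snps = n_snps,
                    chrom_length_bp = chrom_length_bp,
                    n_mqtl = n_planted, mqtl_rho = rho_range,
                    n_eqtl = 0, n_coupling = 0, n_ae_regions = 0, seed = seed)
  simulate_cohort(cfg)
}

# AE-only track under given signal/noise, with planted regions (t-style)
ae_cohort <- function(seed, n_snps = 1000, n_regions = 50, region_size = 5,
                      signal = 0.6, noise = 0.15, carrier = 0.3) {
  cfg <- sim_config(n_genes = 0, n_cpgs = 1, n_snps = n_snps,
                    chrom_length_bp = 2e7, n_mqtl = 0, n_eqtl = 0,
                    n_coupling = 0, n_ae_regions = n_regions,
                    ae_region_size = region_size, ae_signal = signal,
                    ae_noise_sd = noise, ae_carrier_fraction = carrier,
                    seed = seed)
  coh <- simulate_cohort(cfg)
  list(track = coh$ae_track, truth = coh$truth$ae_regions,
       genotypes = coh$genotypes)
}
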