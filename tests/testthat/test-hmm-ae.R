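test_that("single-locus smoothing equals the closed-form posterior", {
  spec <- hmm_spec()
  x <- 0.35
  lik <- spec$initial * dnorm(x, spec$state_means, spec$emission_sd)
  expected <- sum(lik / sum(lik) * spec$state_means)
  tr <- smooth_allelic_ratios(tiny_track(x, samples = 2), spec)
  expect_equal(tr$smoothed_ratio[1, 1], expected, tolerance = 1e-12)
  expect_true(is.na(tr$smoothed_ratio[1, 2]))  # empty chain stays missing
})

test_that("forward-backward equals exhaustive path enumeration on short chains", {
  spec <- hmm_spec()
  set.seed(21)
  for (len in c(3, 5, 6)) {
    x <- rnorm(len, 0, 0.4)
    post <- hmm_posterior_enumerate(x, spec)
    expected <- as.numeric(post %*% spec$state_means)
    got <- smooth_allelic_ratios(tiny_track(x), spec)$smoothed_ratio[, 1]
    expect_equal(unname(got), expected, tolerance = 1e-10)
  }
})

test_that("missing entries are skipped exactly, not bridged", {
  # a sample observed at a subset of loci must give the same posteriors as
  # the compacted chain over only those loci
  spec <- hmm_spec()
  set.seed(22)
  x <- rnorm(6, 0.2, 0.3)
  full <- rep(NA_real_, 9)
  obs_at <- c(1, 3, 4, 6, 8, 9)
  full[obs_at] <- x
  with_gaps <- smooth_allelic_ratios(tiny_track(full), spec)$smoothed_ratio[obs_at, 1]
  compact <- smooth_allelic_ratios(tiny_track(x), spec)$smoothed_ratio[, 1]
  expect_equal(unname(with_gaps), unname(compact), tolerance = 1e-12)
})

test_that("constant input at a state mean is shrunk only by the emission model", {
  spec <- hmm_spec(self_transition = 0.95)
  sm <- smooth_allelic_ratios(tiny_track(rep(0.8, 30)), spec)$smoothed_ratio[, 1]
  expect_true(all(abs(sm - 0.8) < 0.05))
})

test_that("aeSNP calls follow the threshold and minimum-sample rule", {
  sm <- matrix(0, 5, 4, dimnames = list(sprintf("s%03d", 1:5), paste0("I", 1:4)))
  sm[2, c(1, 3)] <- 0.25      # two samples above 0.2 -> called
  sm[3, 1] <- 0.25            # one sample only -> not called
  sm[4, c(1, 2, 4)] <- -0.5   # negative sign call
  raw <- sm
  tr <- allele_ratio_track(raw, snp_table(rownames(sm), "chr1", 1:5 * 10, rep(0.3, 5)),
                           smoothed_ratio = sm)
  calls <- call_aesnps(tr, 0.2, 2)
  expect_equal(calls$called, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(calls$sign[2], 1)
  expect_equal(calls$sign[4], -1)
  # all-zero track -> no calls
  tr0 <- allele_ratio_track(raw * 0, tr$loci, smoothed_ratio = sm * 0)
  expect_equal(sum(call_aesnps(tr0, 0.2, 2)$called), 0)
})

test_that("aeRegion segmentation needs two or more consecutive same-sign calls", {
  mk <- function(signs) {
    n <- length(signs)
    sm <- matrix(0, n, 3, dimnames = list(sprintf("s%03d", 1:n), paste0("I", 1:3)))
    for (i in seq_len(n)) if (!is.na(signs[i])) sm[i, 1:2] <- signs[i] * 0.5
    tr <- allele_ratio_track(sm, snp_table(rownames(sm), "chr1", 1:n * 10, rep(0.3, n)),
                             smoothed_ratio = sm)
    build_aeregions(call_aesnps(tr, 0.2, 2), tr)
  }
  # three consecutive positives form one region of 3
  r <- mk(c(1, 1, 1))
  expect_equal(nrow(r$regions), 1)
  expect_equal(r$regions$n_snps, 3)
  # sign change splits
  r <- mk(c(1, 1, -1, -1))
  expect_equal(nrow(r$regions), 2)
  expect_equal(r$regions$sign, c(1, -1))
  # isolated call, and a gap, produce nothing / break runs
  expect_equal(nrow(mk(c(NA, 1, NA))$regions), 0)
  r <- mk(c(1, 1, NA, 1, 1))
  expect_equal(nrow(r$regions), 2)
})

test_that("region scores are per-sample member means, untouched by other SNPs", {
  sm <- matrix(NA_real_, 6, 3, dimnames = list(sprintf("s%03d", 1:6), paste0("I", 1:3)))
  sm[2, ] <- c(0.4, 0.5, NA)
  sm[3, ] <- c(0.6, 0.3, NA)
  sm[5, ] <- c(0.9, 0.9, 0.9)  # unrelated called SNP elsewhere (isolated)
  tr <- allele_ratio_track(sm, snp_table(rownames(sm), "chr1", 1:6 * 10, rep(0.3, 6)),
                           smoothed_ratio = sm)
  reg <- build_aeregions(call_aesnps(tr, 0.2, 2), tr)
  expect_equal(nrow(reg$regions), 1)
  expect_equal(unname(reg$scores[1, ]), c(0.5, 0.4, NA))
  # adding a non-member SNP elsewhere leaves the region score unchanged
  sm2 <- rbind(sm, s007 = c(NA, NA, 0.7))
  tr2 <- allele_ratio_track(sm2, snp_table(rownames(sm2), "chr1", c(1:6 * 10, 100),
                                           rep(0.3, 7)), smoothed_ratio = sm2)
  reg2 <- build_aeregions(call_aesnps(tr2, 0.2, 2), tr2)
  expect_equal(reg2$scores[1, ], reg$scores[1, ])
})

test_that("threshold calibration handles silent tracks and degenerate nulls", {
  # silent track: no observed calls anywhere -> NA with warning
  sm0 <- matrix(0, 6, 4, dimnames = list(sprintf("s%03d", 1:6), paste0("I", 1:4)))
  tr0 <- allele_ratio_track(sm0, snp_table(rownames(sm0), "chr1", 1:6 * 10,
                                           rep(0.3, 6)))
  expect_warning(cal0 <- calibrate_ae_threshold(tr0, grid = seq(0.2, 1, 0.2),
                                                n_permutations = 2, seed = 1),
                 "no observed")
  expect_true(is.na(cal0$threshold))
  # a constant saturated track is its own permutation null (FDR = 1
  # everywhere), so no threshold can reach the target
  sm <- matrix(3, 6, 4, dimnames = dimnames(sm0))
  tr <- allele_ratio_track(sm, tr0$loci)
  expect_warning(cal <- calibrate_ae_threshold(tr, n_permutations = 2, seed = 1),
                 "no candidate")
  expect_true(is.na(cal$threshold))
})

test_that("calibrated threshold is stable when the permutation count doubles", {
  ae <- ae_cohort(31, n_snps = 400, n_regions = 20)
  c1 <- calibrate_ae_threshold(ae$track, n_permutations = 5, seed = 9)
  c2 <- calibrate_ae_threshold(ae$track, n_permutations = 10, seed = 9)
  expect_lte(abs(c1$threshold - c2$threshold), 0.05 + 1e-12)
})
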