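# Left-to-right HMM smoothing of allelic log2 ratios. States are a ladder of
# allelic-imbalance levels; "left-to-right" means banded transitions (the
# state index moves by at most one between consecutive observed SNPs). Each
# sample's observed (heterozygous) loci form the chain in genome order;
# posteriors come from a scaled forward-backward pass vectorized across
# samples, with a skip rule at missing entries that makes the computation
# exactly equal to running each sample's chain over its observed loci only.

#' Specify the allelic-expression smoothing HMM
#'
#' @param state_means Non-decreasing log2-ratio levels, one per state. The
#'   defaults put four states inside the +/-0.2 calling band and four outside
#'   it, so the 0.2 threshold separates balanced from imbalanced states.
#' @param emission_sd Gaussian emission standard deviation around the state
#'   mean (log2-ratio units).
#' @param self_transition Probability of staying in the same state; the
#'   remaining mass is split equally among the adjacent state(s).
#' @param initial Initial state distribution (default uniform).
#' @return An object of class `hmm_spec`.
#' @export
hmm_spec <- function(state_means = c(-1.2, -0.8, -0.4, -0.1, 0.1, 0.4, 0.8, 1.2),
                     emission_sd = 0.15,
                     self_transition = 0.9,
                     initial = NULL) {
  if (is.unsorted(state_means)) abort("state_means must be non-decreasing")
  if (emission_sd <= 0) abort("emission_sd must be positive")
  if (self_transition <= 0 || self_transition >= 1) {
    abort("self_transition must lie in (0, 1)")
  }
  s <- length(state_means)
  if (s < 2) abort("need at least 2 states")
  if (is.null(initial)) initial <- rep(1 / s, s)
  if (length(initial) != s || any(initial < 0) || abs(sum(initial) - 1) > 1e-8) {
    abort("initial must be a probability distribution over the states")
  }
  trans <- matrix(0, s, s)
  for (i in seq_len(s)) {
    nb <- intersect(c(i - 1L, i + 1L), seq_len(s))
    trans[i, i] <- self_transition
    trans[i, nb] <- (1 - self_transition) / length(nb)
  }
  structure(list(state_means = state_means, emission_sd = emission_sd,
                 self_transition = self_transition, initial = initial,
                 transition = trans),
            class = "hmm_spec")
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat(sprintf("<hmm_spec> %d states (%s), emission SD %.3g, self-transition %.2f\n",
              length(x$state_means),
              paste(format(x$state_means), collapse = ", "),
              x$emission_sd, x$self_transition))
  invisible(x)
}

# Forward-backward posteriors for one chromosome block of a track, vectorized
# across samples. obs: loci-by-sample matrix with NA at unobserved entries.
# Returns the posterior-mean smoothed value matrix (NA where obs is NA).
# At an unobserved entry a sample's forward/backward messages pass through
# unchanged, which is identical to deleting that position from its chain.
forward_backward_block <- function(obs, spec) {
  n_loci <- nrow(obs)
  n_samp <- ncol(obs)
  s <- length(spec$state_means)
  if (n_loci == 0) return(obs)
  emis <- function(t) {
    e <- vapply(spec$state_means,
                function(m) dnorm(obs[t, ], mean = m, sd = spec$emission_sd),
                numeric(n_samp))
    e <- matrix(t(e), nrow = s)    # s x n_samp
    e[, is.na(obs[t, ])] <- 1
    e
  }
  tA <- t(spec$transition)
  alpha <- array(NA_real_, c(s, n_samp, n_loci))
  started <- rep(FALSE, n_samp)
  cur <- matrix(spec$initial, s, n_samp)
  for (t in seq_len(n_loci)) {
    seen <- !is.na(obs[t, ])
    if (any(seen)) {
      e <- emis(t)
      prop <- cur
      adv <- seen & started
      if (any(adv)) prop[, adv] <- tA %*% cur[, adv, drop = FALSE]
      first <- seen & !started
      if (any(first)) prop[, first] <- spec$initial
      nxt <- prop[, seen, drop = FALSE] * e[, seen, drop = FALSE]
      norm <- colSums(nxt)
      norm[norm == 0] <- 1
      cur[, seen] <- sweep(nxt, 2, norm, "/")
      started <- started | seen
    }
    alpha[, , t] <- cur
  }
  post <- matrix(NA_real_, n_loci, n_samp, dimnames = dimnames(obs))
  bcur <- matrix(1, s, n_samp)
  for (t in rev(seq_len(n_loci))) {
    seen <- !is.na(obs[t, ])
    if (any(seen)) {
      a <- matrix(alpha[, , t], nrow = s)
      g <- a[, seen, drop = FALSE] * bcur[, seen, drop = FALSE]
      norm <- colSums(g)
      norm[norm == 0] <- 1
      g <- sweep(g, 2, norm, "/")
      post[t, seen] <- colSums(g * spec$state_means)
      # prepare the backward message for the previous observed position
      e <- emis(t)
      upd <- spec$transition %*% (e[, seen, drop = FALSE] * bcur[, seen, drop = FALSE])
      norm <- colSums(upd)
      norm[norm == 0] <- 1
      bcur[, seen] <- sweep(upd, 2, norm, "/")
    }
  }
  post
}

#' Smooth allelic log2 ratios with the left-to-right HMM
#'
#' Runs forward-backward per sample and chromosome over the observed
#' (heterozygous) loci and stores the posterior-weighted mean of the state
#' means as the smoothed score. Samples with no observed locus on a
#' chromosome simply stay all-missing there.
#'
#' @param track An [allele_ratio_track()].
#' @param spec An [hmm_spec()].
#' @return The track with `smoothed_ratio` filled in.
#' @export
smooth_allelic_ratios <- function(track, spec = hmm_spec()) {
  stopifnot(inherits(track, "allele_ratio_track"), inherits(spec, "hmm_spec"))
  sm <- track$raw_ratio
  sm[] <- NA_real_
  for (chr in unique(track$loci$chrom)) {
    rows <- which(track$loci$chrom == chr)
    sm[rows, ] <- forward_backward_block(track$raw_ratio[rows, , drop = FALSE], spec)
  }
  allele_ratio_track(track$raw_ratio, track$loci, smoothed_ratio = sm)
}

#' Brute-force HMM posteriors by exhaustive path enumeration
#'
#' Enumerates every state path for a single observed chain and accumulates
#' exact posterior state probabilities; the independent reference for the
#' forward-backward implementation. Only feasible for short chains
#' (`n_states^length(x)` paths).
#'
#' @param x Complete numeric vector of observed log2 ratios (one chain).
#' @param spec An [hmm_spec()].
#' @return Matrix of posterior state probabilities, `length(x)` by states.
#' @export
hmm_posterior_enumerate <- function(x, spec = hmm_spec()) {
  stopifnot(!anyNA(x))
  s <- length(spec$state_means)
  t_len <- length(x)
  if (s^t_len > 3e6) abort("chain too long for exhaustive enumeration")
  paths <- as.matrix(expand.grid(rep(list(seq_len(s)), t_len)))
  lik <- spec$initial[paths[, 1]] *
    dnorm(x[1], spec$state_means[paths[, 1]], spec$emission_sd)
  if (t_len > 1) {
    for (t in 2:t_len) {
      lik <- lik * spec$transition[cbind(paths[, t - 1], paths[, t])] *
        dnorm(x[t], spec$state_means[paths[, t]], spec$emission_sd)
    }
  }
  post <- matrix(0, t_len, s)
  for (t in seq_len(t_len)) {
    post[t, ] <- vapply(seq_len(s), function(k) sum(lik[paths[, t] == k]), 0)
  }
  post / rowSums(post)
}
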