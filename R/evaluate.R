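# Scoring of results against the ground truth of a synthetic cohort. A
# significant pair counts as a true recovery when its feature carries a
# planted effect from the paired locus or from an LD proxy of it (squared
# dosage correlation above the cutoff).

#' Realized false discovery rate of a mapping result against planted truth
#'
#' A significant pair is true when its feature has a planted effect whose
#' locus is the paired locus itself or an LD proxy of it (`R^2 > r2_cutoff`
#' between the dosages).
#'
#' @param result An `association_result`.
#' @param truth Tibble of planted effects with a feature-id column (first of
#'   `probe_id`/`gene_id`/`region_id` found) and `snp_id`.
#' @param genotypes A [genotype_matrix()] (or dosage matrix) for the proxy
#'   R^2 computation.
#' @param r2_cutoff LD proxy threshold (default 0.8).
#' @return A list: `fdr` (NA if no significant pairs), `n_significant`,
#'   `n_false`, `sensitivity` (fraction of planted effects with at least one
#'   significant pair at the planted locus or a proxy).
#' @export
planted_pair_fdr <- function(result, truth, genotypes, r2_cutoff = 0.8) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else genotypes
  sig <- significant_pairs(result)
  fcol <- intersect(c("probe_id", "gene_id", "region_id"), names(truth))[1]
  if (is.na(fcol)) abort("truth table lacks a feature id column")
  is_true <- logical(nrow(sig))
  proxy_cache <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(sig))) {
    j <- which(truth[[fcol]] == sig$feature_id[k])
    if (!length(j)) next
    for (ps in truth$snp_id[j]) {
      if (sig$locus_id[k] == ps) { is_true[k] <- TRUE; break }
      key <- paste0(ps, "|", sig$locus_id[k])
      r2 <- proxy_cache[[key]]
      if (is.null(r2)) {
        r2 <- suppressWarnings(cor(dos[ps, ], dos[sig$locus_id[k], ]))^2
        proxy_cache[[key]] <- r2
      }
      if (!is.na(r2) && r2 > r2_cutoff) { is_true[k] <- TRUE; break }
    }
  }
  recovered <- vapply(seq_len(nrow(truth)), function(j) {
    hits <- sig[sig$feature_id == truth[[fcol]][j], , drop = FALSE]
    if (!nrow(hits)) return(FALSE)
    any(vapply(hits$locus_id, function(s) {
      if (s == truth$snp_id[j]) return(TRUE)
      r2 <- suppressWarnings(cor(dos[truth$snp_id[j], ], dos[s, ]))^2
      !is.na(r2) && r2 > r2_cutoff
    }, TRUE))
  }, TRUE)
  list(fdr = if (nrow(sig)) mean(!is_true) else NA_real_,
       n_significant = nrow(sig), n_false = sum(!is_true),
       sensitivity = if (nrow(truth)) mean(recovered) else NA_real_)
}

#' Score aeSNP calls and recovered regions against planted AE regions
#'
#' @param calls Tibble from [call_aesnps()].
#' @param truth The `ae_regions` truth table of a simulated track (list column
#'   `snp_ids` of planted members).
#' @param regions Optional [build_aeregions()] result; if given, member
#'   recovery is judged by coverage with recovered regions, otherwise by
#'   per-SNP calls.
#' @return A list: `false_call_rate` (fraction of called aeSNPs outside any
#'   planted region; NA if nothing is called), `n_called`, and
#'   `member_recovery` (fraction of planted member SNPs called/covered).
#' @export
ae_call_score <- function(calls, truth, regions = NULL) {
  planted <- unique(unlist(truth$snp_ids))
  called <- calls$snp_id[calls$called]
  covered <- if (!is.null(regions)) unique(unlist(regions$regions$snp_ids)) else called
  list(false_call_rate = if (length(called)) mean(!called %in% planted) else NA_real_,
       n_called = length(called),
       member_recovery = if (length(planted)) mean(planted %in% covered) else NA_real_)
}
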