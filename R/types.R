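# Validated containers shared by every stage: coordinate tibbles for the
# annotation (genes, CpG probes, SNPs, intervals) and feature-by-sample
# matrices for the assays. Matrices stay plain numeric matrices with feature
# ids as rownames and sample ids as colnames; the constructors only enforce
# invariants and attach a class so downstream code can dispatch.

check_string <- function(x, what) {
  if (!is.character(x) || anyNA(x) || any(!nzchar(x))) {
    abort(paste0(what, " must be non-empty character values"))
  }
  invisible(x)
}

check_unique <- function(x, what) {
  if (anyDuplicated(x)) {
    dup <- unique(x[duplicated(x)])
    abort(paste0("duplicate ", what, ": ", paste(head(dup, 3), collapse = ", ")))
  }
  invisible(x)
}

#' Construct a table of genomic intervals
#'
#' Intervals follow the BED convention: 0-based start, exclusive end.
#'
#' @param chrom Chromosome names.
#' @param start,end Integer positions, `start >= 0`, `end > start`.
#' @param name Optional labels (recycled `NA` if missing).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_) {
  check_string(chrom, "chrom")
  if (any(start < 0)) abort("interval start must be >= 0")
  if (any(end <= start)) abort("interval end must be > start")
  tibble::tibble(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), name = as.character(name))
}

#' Construct a gene model table
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome names.
#' @param tss,tes Transcription start / end positions (`tss != tes`).
#' @param strand `"+"` or `"-"`.
#' @return A tibble with the input columns plus `start`/`end`, the gene body
#'   interval `[min(tss, tes), max(tss, tes))`.
#' @export
gene_table <- function(gene_id, chrom, tss, tes, strand) {
  check_string(gene_id, "gene_id"); check_unique(gene_id, "gene_id")
  check_string(chrom, "chrom")
  if (any(tss == tes)) abort("tss must differ from tes")
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  tibble::tibble(gene_id = gene_id, chrom = chrom, tss = as.numeric(tss),
                 tes = as.numeric(tes), strand = strand,
                 start = pmin(tss, tes), end = pmax(tss, tes))
}

#' Construct a CpG probe table
#'
#' @param probe_id Unique probe identifiers.
#' @param chrom Chromosome names.
#' @param position Single-base probe coordinates (`>= 0`).
#' @param probe_type `"I"` or `"II"` (Infinium design type).
#' @return A tibble with one row per probe.
#' @export
cpg_table <- function(probe_id, chrom, position, probe_type = "II") {
  check_string(probe_id, "probe_id"); check_unique(probe_id, "probe_id")
  check_string(chrom, "chrom")
  if (any(position < 0)) abort("probe position must be >= 0")
  probe_type <- rep_len(probe_type, length(probe_id))
  if (!all(probe_type %in% c("I", "II"))) abort("probe_type must be 'I' or 'II'")
  tibble::tibble(probe_id = probe_id, chrom = chrom,
                 position = as.numeric(position), probe_type = probe_type)
}

#' Construct a SNP locus table
#'
#' @param snp_id Unique SNP identifiers.
#' @param chrom Chromosome names.
#' @param position Base positions.
#' @param maf Minor allele frequency, in `[0, 0.5]`.
#' @return A tibble with one row per SNP.
#' @export
snp_table <- function(snp_id, chrom, position, maf) {
  check_string(snp_id, "snp_id"); check_unique(snp_id, "snp_id")
  check_string(chrom, "chrom")
  if (any(position < 0)) abort("SNP position must be >= 0")
  if (any(maf < 0 | maf > 0.5)) abort("maf must lie in [0, 0.5]")
  tibble::tibble(snp_id = snp_id, chrom = chrom,
                 position = as.numeric(position), maf = as.numeric(maf))
}

check_matrix_alignment <- function(mat, ids, what) {
  if (!is.matrix(mat) || !is.numeric(mat)) abort(paste0(what, " must be a numeric matrix"))
  if (is.null(colnames(mat)) || (nrow(mat) > 0 && is.null(rownames(mat)))) {
    abort(paste0(what, " must carry feature rownames and sample colnames"))
  }
  if (!identical(rownames(mat) %||% character(0), as.character(ids))) {
    abort(paste0(what, " rownames must match the feature table ids, in order"))
  }
  check_unique(colnames(mat), "sample id")
  invisible(mat)
}

#' Genotype dosage matrix
#'
#' @param dosage Numeric SNP-by-sample matrix of allele dosages in `[0, 2]`
#'   (real-valued dosages from imputation are accepted).
#' @param loci A [snp_table()] aligned with the matrix rows.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, loci) {
  check_matrix_alignment(dosage, loci$snp_id, "dosage")
  vals <- dosage[!is.na(dosage)]
  if (any(vals < 0 | vals > 2)) abort("dosage entries must lie in [0, 2]")
  structure(list(dosage = dosage, loci = loci, samples = colnames(dosage)),
            class = "genotype_matrix")
}

#' Methylation beta-value matrix
#'
#' @param beta Numeric probe-by-sample matrix; non-missing entries must lie in
#'   `[0, 1]` (out-of-range values are rejected, never clipped).
#' @param probes A [cpg_table()] aligned with the matrix rows.
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(beta, probes) {
  check_matrix_alignment(beta, probes$probe_id, "beta")
  vals <- beta[!is.na(beta)]
  if (any(vals < 0 | vals > 1)) abort("beta values must lie in [0, 1]")
  structure(list(beta = beta, probes = probes, samples = colnames(beta)),
            class = "methylation_matrix")
}

#' Expression matrix
#'
#' @param level Numeric gene-by-sample matrix; entries finite or missing. The
#'   sample set may be a subset of the cohort (assays can cover subsets).
#' @param genes A [gene_table()] aligned with the matrix rows.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(level, genes) {
  check_matrix_alignment(level, genes$gene_id, "level")
  if (any(is.infinite(level))) abort("expression values must be finite or missing")
  structure(list(level = level, genes = genes, samples = colnames(level)),
            class = "expression_matrix")
}

#' Allelic expression log-ratio track
#'
#' Log2 allelic ratios are defined only at heterozygous entries; everything
#' else is missing. Loci must be in genome order (strictly increasing position
#' within each chromosome) because the HMM smoother walks them as a chain.
#'
#' @param raw_ratio Numeric SNP-by-sample matrix of log2 allelic ratios with
#'   `NA` where the sample is homozygous or untyped.
#' @param loci A [snp_table()] aligned with the matrix rows.
#' @param smoothed_ratio Optional matrix of HMM-smoothed scores; must have the
#'   same missingness pattern as `raw_ratio`.
#' @return An object of class `allele_ratio_track`.
#' @export
allele_ratio_track <- function(raw_ratio, loci, smoothed_ratio = NULL) {
  check_matrix_alignment(raw_ratio, loci$snp_id, "raw_ratio")
  ord <- order(loci$chrom, loci$position)
  if (!identical(ord, seq_len(nrow(loci)))) {
    abort("loci must be sorted by chromosome and position")
  }
  bad <- unlist(lapply(split(loci$position, loci$chrom), function(p) any(diff(p) <= 0)))
  if (any(bad)) abort("loci positions must be strictly increasing within chromosome")
  if (!is.null(smoothed_ratio)) {
    check_matrix_alignment(smoothed_ratio, loci$snp_id, "smoothed_ratio")
    if (!identical(is.na(smoothed_ratio), is.na(raw_ratio))) {
      abort("smoothed_ratio must have the same missingness pattern as raw_ratio")
    }
  }
  structure(list(raw_ratio = raw_ratio, smoothed_ratio = smoothed_ratio,
                 loci = loci, samples = colnames(raw_ratio)),
            class = "allele_ratio_track")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d SNPs x %d samples\n", nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %d CpG probes x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples\n",
              nrow(x$level), ncol(x$level)))
  invisible(x)
}

#' @export
print.allele_ratio_track <- function(x, ...) {
  cat(sprintf("<allele_ratio_track> %d SNPs x %d samples (%.1f%% informative)%s\n",
              nrow(x$raw_ratio), ncol(x$raw_ratio),
              100 * mean(!is.na(x$raw_ratio)),
              if (is.null(x$smoothed_ratio)) "" else ", smoothed"))
  invisible(x)
}
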