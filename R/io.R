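# Plain-text interchange: BED intervals, TSV feature-by-sample matrices with
# a header row of sample ids and a first column of feature ids, TSV coordinate
# tables, and the association-result table with its threshold provenance in
# "#" header comments. Loaders reject, never silently repair, invariant
# violations.

#' Read genomic intervals from a BED file
#'
#' BED convention: 0-based start, exclusive end, at least three tab-separated
#' columns, optional fourth column taken as the interval name.
#'
#' @param path Path to a BED file.
#' @return A tibble as from [genomic_intervals()], input order preserved.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(genomic_intervals(character(), numeric(), numeric() + 1)[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 columns", which(nf < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) abort(sprintf("malformed BED line %d: non-numeric coordinates", bad[1]))
  bad <- which(end <= start | start < 0)
  if (length(bad)) abort(sprintf("invalid interval on BED line %d: need 0 <= start < end", bad[1]))
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), NA_character_)
  genomic_intervals(chrom, start, end, name)
}

#' Write genomic intervals to a BED file
#'
#' @param intervals A tibble with `chrom`, `start`, `end` and optional `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  has_name <- "name" %in% names(intervals) && !all(is.na(intervals$name))
  lines <- paste(intervals$chrom, format(intervals$start, scientific = FALSE, trim = TRUE),
                 format(intervals$end, scientific = FALSE, trim = TRUE),
                 sep = "\t")
  if (has_name) lines <- paste(lines, intervals$name, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

read_matrix_body <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  if (ncol(tab) < 2) abort("matrix TSV needs a feature-id column plus sample columns")
  ids <- tab[[1]]
  check_unique(ids, "feature id")
  body <- as.matrix(tab[, -1, drop = FALSE])
  mat <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(ids, colnames(body))))
  nonnum <- !is.na(body) & is.na(mat)
  if (any(nonnum)) {
    idx <- which(nonnum, arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric cell at feature '%s', sample '%s'",
                  ids[idx[1]], colnames(body)[idx[2]]))
  }
  mat
}

#' Read a feature-by-sample matrix from TSV
#'
#' The header row holds sample ids and the first column feature ids. Empty
#' cells become missing values (permitted for `ae_ratio` and `expression`).
#' Kind-specific invariants are enforced: beta values must lie in `[0, 1]`
#' (rejected, not clipped), dosages in `[0, 2]`.
#'
#' @param path Path to a TSV matrix.
#' @param kind One of `"genotype"`, `"beta"`, `"expression"`, `"ae_ratio"`.
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
read_omic_matrix <- function(path, kind = c("genotype", "beta", "expression", "ae_ratio")) {
  kind <- match.arg(kind)
  mat <- read_matrix_body(path)
  vals <- mat[!is.na(mat)]
  switch(kind,
    genotype = {
      if (anyNA(mat)) abort("genotype matrix must not contain missing values")
      if (any(vals < 0 | vals > 2)) abort("dosage entries must lie in [0, 2]")
    },
    beta = {
      if (anyNA(mat)) abort("beta matrix must not contain missing values")
      if (any(vals < 0 | vals > 1)) abort("beta values must lie in [0, 1]")
    },
    expression = if (any(is.infinite(vals))) abort("expression values must be finite"),
    ae_ratio = if (any(is.infinite(vals))) abort("allelic ratios must be finite")
  )
  mat
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param mat Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param id_column Name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_omic_matrix <- function(mat, path, id_column = "feature_id") {
  tab <- tibble::as_tibble(mat, rownames = id_column)
  readr::write_tsv(tab, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a coordinate table (genes, CpG probes or SNPs) from TSV
#'
#' @param path Path to a TSV with a header row.
#' @param kind One of `"gene"`, `"cpg"`, `"snp"`; selects the required columns
#'   and the validating constructor.
#' @return The corresponding validated tibble.
#' @export
read_feature_table <- function(path, kind = c("gene", "cpg", "snp")) {
  kind <- match.arg(kind)
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  need <- switch(kind,
    gene = c("gene_id", "chrom", "tss", "tes", "strand"),
    cpg = c("probe_id", "chrom", "position", "probe_type"),
    snp = c("snp_id", "chrom", "position", "maf"))
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  switch(kind,
    gene = gene_table(tab$gene_id, tab$chrom, tab$tss, tab$tes, tab$strand),
    cpg = cpg_table(tab$probe_id, tab$chrom, tab$position, tab$probe_type),
    snp = snp_table(tab$snp_id, tab$chrom, tab$position, tab$maf))
}

#' Write an association result to TSV
#'
#' The file carries the threshold provenance (mode, FDR level, permutation
#' count, seed, realized rho and p cutoffs) as `#`-prefixed header comments
#' above a table of columns `feature_id`, `locus_id`, `rho`, `p_empirical`,
#' `distance_bp`, `significant`.
#'
#' @param result An `association_result`, see [permutation_fdr_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(result, path) {
  stopifnot(inherits(result, "association_result"))
  hdr <- c(
    sprintf("# mode=%s", result$mode),
    sprintf("# fdr=%.6g", result$fdr),
    sprintf("# n_permutations=%d", result$n_permutations),
    sprintf("# seed=%s", format(result$seed)),
    sprintf("# rho_cutoff=%.17g", result$rho_cutoff),
    sprintf("# p_cutoff=%.17g", result$p_cutoff)
  )
  tab <- result$pairs[, c("feature_id", "locus_id", "rho", "p_empirical",
                          "distance_bp", "significant")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  if (nrow(tab)) {
    body <- paste(tab$feature_id, tab$locus_id,
                  vapply(tab$rho, function(v) trimws(format(v, digits = 17)), ""),
                  vapply(tab$p_empirical, function(v) trimws(format(v, digits = 17)), ""),
                  format(tab$distance_bp, scientific = FALSE, trim = TRUE),
                  ifelse(tab$significant, "TRUE", "FALSE"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read an association table written by [write_association_table()]
#'
#' @param path Path to the TSV.
#' @return A list with `pairs` (tibble) and the provenance fields parsed from
#'   the header comments.
#' @export
read_association_table <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "=", fixed = TRUE))
  meta <- setNames(as.list(kv[, 2]), kv[, 1])
  tab <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                         col_types = "ccnnnl", progress = FALSE)
  list(pairs = tab,
       mode = meta$mode,
       fdr = as.numeric(meta$fdr),
       n_permutations = as.integer(meta$n_permutations),
       seed = as.integer(meta$seed),
       rho_cutoff = as.numeric(meta$rho_cutoff),
       p_cutoff = as.numeric(meta$p_cutoff))
}
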