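# Genomic-context classification of CpG probes and loci: position relative to
# genes (TSS / body / intergenic), CpG-island context (island / shore /
# shelf / open sea), hypo/hyper methylation class, chromatin-mark overlap
# counts across cell lines, modality of the per-site beta distribution, and
# the TSS running-median profile stratified by expression quartile.

#' Classify points relative to gene models
#'
#' `TSS` if within 1,500 bp of any TSS (closed boundary); otherwise `body` if
#' inside any annotated gene interval; otherwise `intergenic`.
#'
#' @param chrom,position Vectors describing the points.
#' @param genes A [gene_table()].
#' @param tss_flank Flank around the TSS in bp (default 1500).
#' @return Character vector in `{"TSS", "body", "intergenic"}`.
#' @export
classify_position <- function(chrom, position, genes, tss_flank = 1500) {
  chrom <- rep_len(chrom, length(position))
  vapply(seq_along(position), function(i) {
    g <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return("intergenic")
    if (any(abs(position[i] - g$tss) <= tss_flank)) return("TSS")
    if (any(position[i] >= g$start & position[i] < g$end)) return("body")
    "intergenic"
  }, "")
}

#' Classify points relative to CpG islands
#'
#' `island` if inside an island interval; `shore` if within (0, 2 kb) of the
#' nearest island edge; `shelf` if within [2 kb, 4 kb]; `open_sea` beyond.
#'
#' @param chrom,position Vectors describing the points.
#' @param islands Interval tibble as from [genomic_intervals()] (0-based
#'   half-open).
#' @return Character vector in `{"island", "shore", "shelf", "open_sea"}`.
#' @export
classify_island_context <- function(chrom, position, islands) {
  chrom <- rep_len(chrom, length(position))
  vapply(seq_along(position), function(i) {
    isl <- islands[islands$chrom == chrom[i], , drop = FALSE]
    if (nrow(isl) == 0) return("open_sea")
    inside <- position[i] >= isl$start & position[i] < isl$end
    if (any(inside)) return("island")
    d <- min(pmax(isl$start - position[i], position[i] - (isl$end - 1)))
    if (d < 2000) "shore" else if (d <= 4000) "shelf" else "open_sea"
  }, "")
}

#' Hypo / intermediate / hyper methylation class
#'
#' @param mean_beta Per-probe mean beta values in `[0, 1]`.
#' @return Character vector: `hypo` (< 0.3), `hyper` (> 0.7), else
#'   `intermediate`.
#' @export
methylation_class <- function(mean_beta) {
  if (any(mean_beta < 0 | mean_beta > 1, na.rm = TRUE)) {
    abort("mean_beta must lie in [0, 1]")
  }
  out <- rep("intermediate", length(mean_beta))
  out[mean_beta < 0.3] <- "hypo"
  out[mean_beta > 0.7] <- "hyper"
  out[is.na(mean_beta)] <- NA_character_
  out
}

#' Count cell lines with a chromatin mark overlapping each point
#'
#' For every mark, the number of cell lines having at least one interval that
#' contains the point; a locus "has" the mark if the count is at least one.
#'
#' @param chrom,position Vectors describing the points.
#' @param marks A tibble of mark intervals with columns `mark`, `cell_line`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @return A tibble with one row per point and one count column per mark.
#' @export
mark_overlap_counts <- function(chrom, position, marks) {
  chrom <- rep_len(chrom, length(position))
  mark_names <- sort(unique(marks$mark))
  out <- tibble::tibble(chrom = chrom, position = position)
  for (m in mark_names) {
    sub <- marks[marks$mark == m, , drop = FALSE]
    out[[m]] <- vapply(seq_along(position), function(i) {
      hit <- sub$chrom == chrom[i] & sub$start <= position[i] & position[i] < sub$end
      length(unique(sub$cell_line[hit]))
    }, 0L)
  }
  out
}

#' Count the modes of a beta-value distribution
#'
#' Gaussian-kernel density (Silverman's rule-of-thumb bandwidth, boundary
#' reflection onto `[0, 1]`) evaluated on 100 equal-width bins over `[0, 1]`.
#' A mode is a bin that is a strict local maximum (boundary bins compare to
#' their single neighbor) with density at least 1.2 times the mean bin
#' density.
#'
#' @param values Numeric beta values; at least `min_n` non-missing.
#' @param n_bins Number of bins (default 100).
#' @param min_n Minimum non-missing values (default 10).
#' @param bw Kernel bandwidth; default Silverman's rule on the sample.
#' @return Integer mode count.
#' @export
count_modes <- function(values, n_bins = 100, min_n = 10, bw = NULL) {
  x <- values[!is.na(values)]
  if (length(x) < min_n) abort(sprintf("count_modes needs >= %d non-missing values", min_n))
  if (any(x < 0 | x > 1)) abort("beta values must lie in [0, 1]")
  if (is.null(bw)) bw <- stats::bw.nrd0(x)
  if (bw <= 0) bw <- 1e-3
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  # reflect about both boundaries so mass does not leak outside [0, 1]
  aug <- c(x, -x, 2 - x)
  dens <- vapply(mids, function(m) sum(dnorm(m, aug, bw)), 0) * 3 /
    (length(aug) * 1)
  thr <- 1.2 * mean(dens)
  is_mode <- logical(n_bins)
  for (i in seq_len(n_bins)) {
    left_ok <- i == 1 || dens[i] > dens[i - 1]
    right_ok <- i == n_bins || dens[i] > dens[i + 1]
    is_mode[i] <- left_ok && right_ok && dens[i] >= thr
  }
  sum(is_mode)
}

#' Annotate CpG probes with genomic and methylation context
#'
#' Convenience wrapper combining [classify_position()],
#' [classify_island_context()], [methylation_class()],
#' [mark_overlap_counts()] and [count_modes()] into one per-probe tibble.
#'
#' @param methylation A [methylation_matrix()].
#' @param genes A [gene_table()].
#' @param islands CpG-island intervals ([genomic_intervals()]).
#' @param marks Optional mark interval tibble (see [mark_overlap_counts()]).
#' @return A tibble with one row per probe: position class, island class,
#'   methylation class, mode count and per-mark cell-line counts.
#' @export
annotate_cpgs <- function(methylation, genes, islands, marks = NULL) {
  pr <- methylation$probes
  mean_beta <- rowMeans(methylation$beta, na.rm = TRUE)
  out <- tibble::tibble(
    probe_id = pr$probe_id,
    chrom = pr$chrom,
    position = pr$position,
    mean_beta = mean_beta,
    position_class = classify_position(pr$chrom, pr$position, genes),
    island_class = classify_island_context(pr$chrom, pr$position, islands),
    methylation_class = methylation_class(mean_beta),
    n_modes = vapply(seq_len(nrow(pr)), function(i) {
      count_modes(methylation$beta[i, ])
    }, 0L)
  )
  if (!is.null(marks)) {
    counts <- mark_overlap_counts(pr$chrom, pr$position, marks)
    out <- dplyr::bind_cols(out, counts[, setdiff(names(counts), c("chrom", "position")),
                                        drop = FALSE])
  }
  out
}

#' Running-median methylation profile around TSSs by expression quartile
#'
#' Assigns every probe to its nearest gene by absolute signed TSS distance
#' (ties to the lexicographically lower gene id), computes the chosen
#' per-probe statistic (mean or SD of beta), and returns the running median
#' against signed TSS distance within each expression quartile.
#'
#' @param methylation A [methylation_matrix()].
#' @param genes A [gene_table()].
#' @param gene_quartiles Named integer vector (1-4) of expression quartiles,
#'   names = gene ids.
#' @param statistic `"mean"` or `"sd"` of the per-probe beta values.
#' @param window Running-median window in probes (odd; default 201, truncated
#'   to the quartile's probe count; 1 returns the raw statistic).
#' @return A tibble: `probe_id`, `gene_id`, `quartile`, `signed_distance`,
#'   `value` (raw statistic) and `running_median`.
#' @export
tss_profile <- function(methylation, genes, gene_quartiles,
                        statistic = c("mean", "sd"), window = 201) {
  statistic <- match.arg(statistic)
  pr <- methylation$probes
  stat <- if (statistic == "mean") rowMeans(methylation$beta, na.rm = TRUE)
          else apply(methylation$beta, 1, sd, na.rm = TRUE)
  genes_o <- genes[order(genes$gene_id), , drop = FALSE]
  assign <- purrr::map_dfr(seq_len(nrow(pr)), function(i) {
    g <- genes_o[genes_o$chrom == pr$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    d <- pr$position[i] - g$tss
    j <- which.min(abs(d))   # first minimum = lower gene id after ordering
    tibble::tibble(probe_id = pr$probe_id[i], gene_id = g$gene_id[j],
                   signed_distance = d[j], value = stat[i])
  })
  assign$quartile <- unname(gene_quartiles[assign$gene_id])
  assign <- assign[!is.na(assign$quartile), , drop = FALSE]
  out <- dplyr::group_by(assign, .data$quartile)
  out <- dplyr::arrange(out, .data$signed_distance, .by_group = TRUE)
  out <- dplyr::mutate(out, running_median = {
    k <- min(window, dplyr::n())
    if (k %% 2 == 0) k <- k - 1
    if (k <= 1) .data$value else as.numeric(stats::runmed(.data$value, k))
  })
  dplyr::ungroup(out)
}
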