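# ggplot2 views of the main result types.

#' @describeIn permutation_fdr_map QQ-style plot of empirical p-values against
#'   uniform quantiles, with the significance cutoff marked.
#' @param object,x An `association_result`.
#' @param ... Unused.
#' @export
autoplot.association_result <- function(object, ...) {
  pr <- dplyr::arrange(object$pairs, .data$p_empirical)
  pr$expected <- (seq_len(nrow(pr)) - 0.5) / nrow(pr)
  ggplot2::ggplot(pr, ggplot2::aes(-log10(.data$expected), -log10(.data$p_empirical))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "-log10 expected p", y = "-log10 empirical p",
                  title = sprintf("%s: %d significant pairs at FDR %.0f%%",
                                  object$mode, sum(pr$significant),
                                  100 * object$fdr)) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of per-probe mean beta values
#'
#' The population view of methylation: mean beta per CpG, typically bimodal
#' with a hypomethylated and a hypermethylated mode, optionally stratified by
#' a context class.
#'
#' @param methylation A [methylation_matrix()].
#' @param class_by Optional character vector (one per probe) to facet by,
#'   e.g. the island class from [annotate_cpgs()].
#' @return A ggplot object.
#' @export
plot_beta_distribution <- function(methylation, class_by = NULL) {
  df <- tibble::tibble(mean_beta = rowMeans(methylation$beta, na.rm = TRUE))
  if (!is.null(class_by)) df$class <- class_by
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$mean_beta)) +
    ggplot2::geom_histogram(bins = 50, boundary = 0) +
    ggplot2::labs(x = "mean beta value", y = "CpG probes") +
    ggplot2::theme_minimal()
  if (!is.null(class_by)) p <- p + ggplot2::facet_wrap(~class)
  p
}

#' @describeIn ld_pruned_qq QQ plot of the LD-pruned p-values per distance bin.
#' @param qq_data The tibble returned by [ld_pruned_qq()].
#' @return A ggplot object.
#' @export
plot_qq_bins <- function(qq_data) {
  ggplot2::ggplot(qq_data,
                  ggplot2::aes(-log10(.data$expected), -log10(.data$p_empirical),
                               colour = .data$bin)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "-log10 expected p", y = "-log10 empirical p",
                  colour = "distance bin") +
    ggplot2::theme_minimal()
}

#' @describeIn calibrate_ae_threshold Empirical FDR against the candidate
#'   threshold grid, with the chosen threshold marked.
#' @export
autoplot.ae_threshold <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$threshold, .data$fdr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$target_fdr, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 3) +
    ggplot2::labs(x = "|smoothed log2 ratio| threshold", y = "empirical FDR") +
    ggplot2::theme_minimal()
}
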