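#' Manhattan-style plot of per-gene burden results
#'
#' Gene index against -log10 p, with the Bonferroni threshold drawn as a
#' horizontal line. Requires ggplot2.
#'
#' @param results data frame from [test_all_genes()] (threshold read from its
#'   attribute unless supplied).
#' @param threshold significance threshold to draw (optional).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, threshold = attr(results, "threshold")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_manhattan requires the ggplot2 package", call. = FALSE)
  }
  d <- results[order(results$gene), , drop = FALSE]
  d$index <- seq_len(nrow(d))
  d$neglog10p <- -log10(pmax(d$p_value, .Machine$double.xmin))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = index, y = neglog10p)) +
    ggplot2::geom_point(ggplot2::aes(shape = eligible)) +
    ggplot2::labs(x = "gene", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold) && is.finite(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed")
  }
  p
}
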