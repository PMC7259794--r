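#' Plots for pipeline results
#'
#' ggplot2 graphics for the common diagnostics: a differential-peak
#' volcano with the mark thresholds, the concordance between mark and
#' expression fold changes, and the conservation-tier profile of attached
#' RAREs.
#'
#' @name plots
NULL

#' Volcano plot of differential peaks
#'
#' @param peaks A peak tibble with `log2fc` and either `bh_p` or `pvalue`.
#' @param cfg A [pipeline_config()] supplying the threshold lines.
#' @return A ggplot object.
#' @export
plot_peak_volcano <- function(peaks, cfg = pipeline_config()) {
  p <- peaks
  if (all(is.na(p$bh_p))) p$bh_p <- bh_adjust(p$pvalue)
  thr <- mark_threshold(unique(p$mark)[1], cfg)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$bh_p))) +
    ggplot2::geom_point(ggplot2::aes(colour = abs(.data$log2fc) > thr &
                                       .data$bh_p < cfg$bh_alpha),
                        alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(cfg$bh_alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "peak log2FC (KO vs WT)",
                  y = "-log10 BH-adjusted p",
                  title = paste(unique(p$mark), "differential peaks")) +
    ggplot2::theme_minimal()
}

#' Mark-change vs expression-change concordance
#'
#' One point per linked peak; the quadrant pattern shows the expected
#' anti-correlation for H3K27ac and correlation for H3K27me3 with
#' expression change on loss of RA.
#'
#' @param candidates An `ra_candidates` tibble.
#' @param de The DE gene tibble (for the expression log2FC axis).
#' @return A ggplot object.
#' @export
plot_concordance <- function(candidates, de) {
  d <- dplyr::distinct(candidates[, c("gene_id", "mark", "peak_region",
                                      "peak_log2fc", "concordant")])
  d <- dplyr::inner_join(d, de[, c("gene_id", "log2fc")], by = "gene_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$peak_log2fc, y = .data$log2fc,
                                  colour = .data$concordant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::facet_wrap(~mark) +
    ggplot2::labs(x = "peak log2FC (KO vs WT)",
                  y = "gene expression log2FC (KO vs WT)") +
    ggplot2::theme_minimal()
}

#' Conservation-tier profile of attached RAREs
#'
#' @param candidates An `ra_candidates` tibble with `conserved_to` filled.
#' @param cfg A [pipeline_config()] (clade order on the axis).
#' @return A ggplot object.
#' @export
plot_conservation_tiers <- function(candidates, cfg = pipeline_config()) {
  d <- dplyr::distinct(candidates[!is.na(candidates$rare_region),
                                  c("rare_region", "rare_type",
                                    "element_class", "conserved_to")])
  d$conserved_to <- factor(d$conserved_to,
                           levels = c("none", cfg$clade_order))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conserved_to,
                                  fill = .data$element_class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "most distal conserved clade", y = "RAREs",
                  fill = "class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Summary bar chart for a pipeline run
#'
#' @param object An `ra_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ra_run <- function(object, ...) {
  s <- tidyr::pivot_longer(object$summary, dplyr::everything(),
                           names_to = "quantity", values_to = "n")
  s$quantity <- factor(s$quantity, levels = rev(names(object$summary)))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n, y = .data$quantity)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "count", y = NULL) +
    ggplot2::theme_minimal()
}
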