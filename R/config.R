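#' Pipeline configuration
#'
#' Bundles every tunable threshold of the candidate-target pipeline. The
#' defaults are the published study's cutoffs: expression |log2FC| above
#' 0.85 with FPKM above 0.5 in both conditions; mark |log2FC| above 0.51
#' (H3K27ac) or 0.47 (H3K27me3) with Benjamini-Hochberg adjusted p below
#' 0.05; motif
#' scanning at up to 2 half-site mismatches with the highly conserved tier
#' requiring at most 1. All threshold comparisons are strict.
#'
#' @param rna_abs_log2fc_min Minimum |log2FC| (KO vs WT) for a gene to count
#'   as differentially expressed. Default 0.85.
#' @param fpkm_min Expression floor applied to both conditions (FPKM).
#'   Default 0.5.
#' @param k27ac_abs_log2fc_min Minimum |log2FC| for H3K27ac peaks. Default 0.51.
#' @param k27me3_abs_log2fc_min Minimum |log2FC| for H3K27me3 peaks. Default 0.47.
#' @param bh_alpha Significance level on BH-adjusted peak p-values. Default 0.05.
#' @param scan_mismatch_tol Maximum total half-site mismatches when scanning
#'   peaks for RAREs. Default 2.
#' @param high_conf_mismatch_tol Mismatch tolerance for the highly conserved
#'   tier and for conservation calls in ortholog windows. Default 1.
#' @param clade_order Clades from proximal to distal. Default
#'   `c("rodent", "human", "bird", "reptile", "frog", "fish")`.
#' @param halfsite_consensus 6-letter IUPAC half-site consensus. Default
#'   "RGKTCA" (R = A/G, K = G/T), which covers the printed perfect
#'   half-sites AGGTCA, GGGTCA, AGTTCA, GGTTCA.
#' @param distance_anchor Anchor for peak-to-TSS distance: "midpoint"
#'   (default) or "edge" (distance from the nearer peak edge, 0 if the TSS
#'   is inside the peak).
#' @param strict_containment If `TRUE`, a RARE must lie wholly inside a
#'   linked peak to be attached; if `FALSE` (default), >= 1 bp overlap
#'   suffices.
#' @param rna_bh_alpha Optional BH significance filter on expression
#'   p-values (a `pvalue` column, if present). `NULL` (default) disables it.
#' @param seed Optional integer seed recorded for stochastic modules.
#' @return A list of class `ra_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$rna_abs_log2fc_min
#' @export
pipeline_config <- function(rna_abs_log2fc_min = 0.85,
                            fpkm_min = 0.5,
                            k27ac_abs_log2fc_min = 0.51,
                            k27me3_abs_log2fc_min = 0.47,
                            bh_alpha = 0.05,
                            scan_mismatch_tol = 2L,
                            high_conf_mismatch_tol = 1L,
                            clade_order = c("rodent", "human", "bird",
                                            "reptile", "frog", "fish"),
                            halfsite_consensus = "RGKTCA",
                            distance_anchor = c("midpoint", "edge"),
                            strict_containment = FALSE,
                            rna_bh_alpha = NULL,
                            seed = NULL) {
  stopifnot(
    rna_abs_log2fc_min > 0, fpkm_min > 0,
    k27ac_abs_log2fc_min > 0, k27me3_abs_log2fc_min > 0,
    bh_alpha > 0, bh_alpha < 1,
    scan_mismatch_tol >= 0,
    high_conf_mismatch_tol >= 0,
    high_conf_mismatch_tol <= scan_mismatch_tol,
    nchar(halfsite_consensus) == 6
  )
  distance_anchor <- match.arg(distance_anchor)
  structure(
    list(
      rna_abs_log2fc_min = rna_abs_log2fc_min,
      fpkm_min = fpkm_min,
      k27ac_abs_log2fc_min = k27ac_abs_log2fc_min,
      k27me3_abs_log2fc_min = k27me3_abs_log2fc_min,
      bh_alpha = bh_alpha,
      scan_mismatch_tol = as.integer(scan_mismatch_tol),
      high_conf_mismatch_tol = as.integer(high_conf_mismatch_tol),
      clade_order = clade_order,
      halfsite_consensus = toupper(halfsite_consensus),
      distance_anchor = distance_anchor,
      strict_containment = strict_containment,
      rna_bh_alpha = rna_bh_alpha,
      seed = seed
    ),
    class = "ra_config"
  )
}

#' @export
print.ra_config <- function(x, ...) {
  cat("RA target pipeline configuration\n")
  cat(sprintf("  expression: |log2FC| > %g, FPKM (both) > %g\n",
              x$rna_abs_log2fc_min, x$fpkm_min))
  cat(sprintf("  peaks: H3K27ac |log2FC| > %g, H3K27me3 |log2FC| > %g, BH p < %g\n",
              x$k27ac_abs_log2fc_min, x$k27me3_abs_log2fc_min, x$bh_alpha))
  cat(sprintf("  scan: consensus %s, tolerance %d (highly conserved: %d)\n",
              x$halfsite_consensus, x$scan_mismatch_tol, x$high_conf_mismatch_tol))
  cat("  clades:", paste(x$clade_order, collapse = " < "), "\n")
  invisible(x)
}

mark_threshold <- function(mark, cfg) {
  ifelse(mark == "H3K27ac", cfg$k27ac_abs_log2fc_min, cfg$k27me3_abs_log2fc_min)
}

MARK_LEVELS <- c("H3K27ac", "H3K27me3")
DIRECTION_LEVELS <- c("RA_activated", "RA_repressed")
MOTIF_SPACERS <- c(DR1 = 1L, DR2 = 2L, DR5 = 5L)
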