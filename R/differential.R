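#' Differential filters and multiple-testing adjustment
#'
#' Applies the study's effect-size and significance cutoffs to expression
#' and peak tables. All comparisons are strict: a gene at exactly the
#' log2FC cutoff is excluded.
#'
#' @name differential
NULL

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjusted[i] = min over ranks j >= rank(i) of p_(j) * n / j`, capped at
#' 1, with input order preserved. Re-implemented here because the pipeline
#' adjusts peak p-values itself when the upstream differential test did
#' not.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same order and length.
#' @examples
#' bh_adjust(c(0.04, 0.01)) # 0.04, 0.02
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be in [0, 1] and non-missing", call. = FALSE)
  }
  n <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(pvalues[o] * n / (n:1)))
  adj[ro]
}

#' Partition genes into RA-activated and RA-repressed sets
#'
#' A gene is RA-activated when its expression falls on loss of RA
#' (log2FC KO vs WT strictly below `-rna_abs_log2fc_min`) and RA-repressed
#' when it rises (strictly above `+rna_abs_log2fc_min`); in both cases the
#' FPKM floor must be strictly exceeded in both conditions. The two sets
#' are disjoint by construction.
#'
#' @param expr Expression tibble from [read_diff_expr()] (columns
#'   `gene_id`, `log2fc`, `fpkm_wt`, `fpkm_ko`, optionally `pvalue`).
#' @param cfg A [pipeline_config()].
#' @return A tibble with columns `gene_id`, `direction`
#'   ("RA_activated"/"RA_repressed") and the expression columns, sorted by
#'   `gene_id`.
#' @export
filter_de_genes <- function(expr, cfg = pipeline_config()) {
  keep <- abs(expr$log2fc) > cfg$rna_abs_log2fc_min &
    expr$fpkm_wt > cfg$fpkm_min & expr$fpkm_ko > cfg$fpkm_min
  if (!is.null(cfg$rna_bh_alpha)) {
    if (!"pvalue" %in% names(expr)) {
      stop("rna_bh_alpha is set but expression table has no pvalue column",
           call. = FALSE)
    }
    keep <- keep & bh_adjust(expr$pvalue) < cfg$rna_bh_alpha
  }
  out <- expr[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc < 0, "RA_activated", "RA_repressed")
  dplyr::arrange(tibble::as_tibble(out), .data$gene_id)
}

#' Filter peaks to the significant RA-regulated set
#'
#' A peak is retained when its |log2FC| strictly exceeds its mark's
#' threshold and its BH-adjusted p-value is below `bh_alpha`. Missing
#' `bh_p` values are computed by [bh_adjust()] over all peaks of the mark;
#' present values are trusted as externally adjusted. Each retained peak
#' is tagged `decreased_in_KO` or `increased_in_KO` by the sign of its
#' log2FC.
#'
#' @param peaks Peak tibble from [read_diff_peaks()]; all rows must share
#'   one mark.
#' @param cfg A [pipeline_config()].
#' @return The retained rows with `bh_p` filled and a `peak_direction`
#'   column.
#' @export
filter_diff_peaks <- function(peaks, cfg = pipeline_config()) {
  if (nrow(peaks) == 0) {
    return(dplyr::mutate(peaks, peak_direction = character(0)))
  }
  marks <- unique(peaks$mark)
  if (length(marks) > 1) {
    stop("mixed marks in one filter call: ", paste(marks, collapse = ", "),
         "; filter each mark separately", call. = FALSE)
  }
  if (all(is.na(peaks$bh_p))) {
    peaks$bh_p <- bh_adjust(peaks$pvalue)
  } else if (any(is.na(peaks$bh_p))) {
    stop("bh_p present for some peaks but not all; supply all or none",
         call. = FALSE)
  }
  thr <- mark_threshold(marks, cfg)
  out <- peaks[abs(peaks$log2fc) > thr & peaks$bh_p < cfg$bh_alpha, ,
               drop = FALSE]
  out$peak_direction <- ifelse(out$log2fc < 0, "decreased_in_KO",
                               "increased_in_KO")
  tibble::as_tibble(out)
}
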