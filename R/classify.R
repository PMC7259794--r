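#' Candidate-target integration and enhancer/silencer classification
#'
#' A candidate RA target is a differentially expressed gene with at least
#' one linked significant RA-regulated peak. RAREs found inside a linked
#' peak are attached to the gene and classified by the gene's regulation
#' direction: elements near RA-activated genes are candidate enhancers,
#' elements near RA-repressed genes candidate silencers. The direction of
#' the histone-mark change is recorded as a concordance flag, not a veto:
#' gene direction dominates (a silencer can sit in an H3K27ac-gain peak).
#'
#' @name classify_integrate
NULL

empty_candidates <- function() {
  out <- tibble::tibble(
    gene_id = character(), direction = character(), mark = character(),
    peak_id = character(), peak_region = character(),
    peak_log2fc = numeric(), link_type = character(), distance = integer(),
    tad_id = character(), concordant = logical(), rare_type = character(),
    rare_region = character(), rare_strand = character(),
    rare_mismatches = integer(), element_class = character(),
    conserved_to = character())
  class(out) <- c("ra_candidates", class(tibble::tibble()))
  out
}

#' Element class from regulation direction
#'
#' @param direction Character vector, "RA_activated" or "RA_repressed".
#' @return "enhancer" for RA-activated genes, "silencer" for RA-repressed.
#' @examples
#' classify_element("RA_repressed") # "silencer"
#' @export
classify_element <- function(direction) {
  if (!all(direction %in% DIRECTION_LEVELS)) {
    stop("direction must be RA_activated or RA_repressed", call. = FALSE)
  }
  ifelse(direction == "RA_activated", "enhancer", "silencer")
}

#' Is a peak's mark change concordant with the gene's regulation?
#'
#' For an RA-activated gene (expression falls in the KO) the concordant
#' pattern is H3K27ac down or H3K27me3 up in the KO; for an RA-repressed
#' gene, H3K27ac up or H3K27me3 down. Vectorised.
#'
#' @param mark "H3K27ac" or "H3K27me3".
#' @param peak_log2fc Peak log2 fold change, KO vs WT.
#' @param direction "RA_activated" or "RA_repressed".
#' @return Logical vector.
#' @export
mark_concordance <- function(mark, peak_log2fc, direction) {
  stopifnot(all(mark %in% MARK_LEVELS), all(direction %in% DIRECTION_LEVELS))
  (direction == "RA_activated" &
     ((mark == "H3K27ac" & peak_log2fc < 0) |
        (mark == "H3K27me3" & peak_log2fc > 0))) |
    (direction == "RA_repressed" &
       ((mark == "H3K27ac" & peak_log2fc > 0) |
          (mark == "H3K27me3" & peak_log2fc < 0)))
}

#' Build the candidate-target table
#'
#' One row per gene x linked peak x attached RARE; linked peaks without an
#' attached RARE contribute one row with empty RARE fields. A RARE is
#' attached when it overlaps the linked peak by at least 1 bp (or lies
#' wholly inside it under `cfg$strict_containment`). A RARE attached to
#' genes of opposite directions receives both classifications, with a
#' warning.
#'
#' @param sig_peaks Significant peaks for both marks (rows of
#'   [filter_diff_peaks()] output, bound together).
#' @param de DE gene set from [filter_de_genes()].
#' @param links Peak-gene links from [link_peaks_to_genes()].
#' @param rares RARE matches from [scan_peaks()] (may be empty).
#' @param cfg A [pipeline_config()].
#' @return A tibble of class `ra_candidates` with columns `gene_id`,
#'   `direction`, `mark`, `peak_id`, `peak_region`, `peak_log2fc`,
#'   `link_type`, `distance`, `tad_id`, `concordant`, `rare_type`,
#'   `rare_region`, `rare_strand`, `rare_mismatches`, `element_class`,
#'   `conserved_to` (NA until [add_conservation()]).
#' @export
build_candidates <- function(sig_peaks, de, links, rares = NULL,
                             cfg = pipeline_config()) {
  if (nrow(sig_peaks) == 0 || nrow(links) == 0 || nrow(de) == 0) {
    return(empty_candidates())
  }
  de_small <- tibble::tibble(gene_id = de$gene_id, direction = de$direction)
  lk <- dplyr::inner_join(links, de_small, by = "gene_id")
  pk <- tibble::tibble(
    peak_id = sig_peaks$peak_id,
    chrom = sig_peaks$chrom, p_start = sig_peaks$start, p_end = sig_peaks$end,
    mark = sig_peaks$mark, peak_log2fc = sig_peaks$log2fc
  )
  out <- dplyr::inner_join(lk, pk, by = "peak_id")
  out$concordant <- mark_concordance(out$mark, out$peak_log2fc, out$direction)
  out$peak_region <- format_region(out$chrom, out$p_start, out$p_end)

  if (!is.null(rares) && nrow(rares) > 0) {
    rr <- tibble::tibble(
      peak_id = rares$peak_id,
      rare_type = rares$motif_type,
      r_start = rares$start, r_end = rares$end,
      rare_region = format_region(rares$chrom, rares$start, rares$end),
      rare_strand = rares$strand,
      rare_mismatches = rares$mismatches
    )
    out <- dplyr::left_join(out, rr, by = "peak_id",
                            relationship = "many-to-many")
    contained <- !is.na(out$r_start) &
      if (cfg$strict_containment) {
        out$r_start >= out$p_start & out$r_end <= out$p_end
      } else {
        pmin(out$r_end, out$p_end) > pmax(out$r_start, out$p_start)
      }
    drop_rare <- !is.na(out$r_start) & !contained
    out$rare_type[drop_rare] <- NA_character_
    out$rare_region[drop_rare] <- NA_character_
    out$rare_strand[drop_rare] <- NA_character_
    out$rare_mismatches[drop_rare] <- NA_integer_
    out$r_start[drop_rare] <- NA_integer_
    out$r_end[drop_rare] <- NA_integer_
    # collapse duplicate no-RARE rows created by dropped attachments, then
    # keep a bare row only for (gene, peak) pairs with no attached RARE
    out <- dplyr::distinct(out)
    key <- paste(out$gene_id, out$peak_id)
    has_rare <- key %in% key[!is.na(out$rare_type)]
    out <- out[!(is.na(out$rare_type) & has_rare), , drop = FALSE]
  } else {
    out$rare_type <- NA_character_
    out$rare_region <- NA_character_
    out$rare_strand <- NA_character_
    out$rare_mismatches <- NA_integer_
  }
  out$element_class <- ifelse(is.na(out$rare_type), NA_character_,
                              classify_element(out$direction))
  out$conserved_to <- NA_character_

  both <- dplyr::distinct(out[!is.na(out$rare_region), c("rare_region", "direction")])
  dup <- both$rare_region[duplicated(both$rare_region)]
  if (length(dup) > 0) {
    dup <- unique(dup)
    shown <- utils::head(dup, 3)
    warning(length(dup), " RARE(s) attached to genes of opposite ",
            "regulation direction, classified per target gene (e.g. ",
            paste(shown, collapse = ", "), ")", call. = FALSE)
  }

  out <- dplyr::arrange(out, .data$chrom, .data$p_start, .data$gene_id,
                        .data$rare_region)
  out <- out[, c("gene_id", "direction", "mark", "peak_id", "peak_region",
                 "peak_log2fc", "link_type", "distance", "tad_id",
                 "concordant", "rare_type", "rare_region", "rare_strand",
                 "rare_mismatches", "element_class", "conserved_to")]
  class(out) <- c("ra_candidates", class(tibble::tibble()))
  out
}

#' Headline summary counts for a candidate table
#'
#' Set-union semantics over `gene_id`: `n_genes_union` counts distinct
#' genes linked to a significant peak of either mark; RARE counts are over
#' distinct (region, type, class) elements.
#'
#' @param candidates An `ra_candidates` tibble.
#' @param cfg A [pipeline_config()] (for the highly conserved tier).
#' @return A one-row tibble with columns `n_genes_k27ac`,
#'   `n_genes_k27me3`, `n_genes_union`, `n_genes_with_rare`,
#'   `n_rare_enhancers`, `n_rare_silencers`, `n_highly_conserved`.
#' @export
summarize_candidates <- function(candidates, cfg = pipeline_config()) {
  genes_ac <- unique(candidates$gene_id[candidates$mark == "H3K27ac"])
  genes_me3 <- unique(candidates$gene_id[candidates$mark == "H3K27me3"])
  rare_rows <- dplyr::distinct(
    candidates[!is.na(candidates$rare_region),
               c("rare_region", "rare_type", "element_class",
                 "rare_mismatches", "conserved_to")])
  distal <- distal_clades(cfg)
  tibble::tibble(
    n_genes_k27ac = length(genes_ac),
    n_genes_k27me3 = length(genes_me3),
    n_genes_union = length(union(genes_ac, genes_me3)),
    n_genes_with_rare =
      length(unique(candidates$gene_id[!is.na(candidates$rare_region)])),
    n_rare_enhancers = sum(rare_rows$element_class == "enhancer"),
    n_rare_silencers = sum(rare_rows$element_class == "silencer"),
    n_highly_conserved = sum(
      rare_rows$conserved_to %in% distal &
        rare_rows$rare_mismatches <= cfg$high_conf_mismatch_tol,
      na.rm = TRUE)
  )
}

#' Union of mark-linked gene sets
#'
#' @param genes_k27ac,genes_k27me3 Character vectors of gene ids linked to
#'   significant peaks of each mark.
#' @return Number of distinct genes linked to either mark.
#' @examples
#' union_gene_count(c("a", "b"), c("b", "c")) # 3
#' @export
union_gene_count <- function(genes_k27ac, genes_k27me3) {
  length(union(unique(genes_k27ac), unique(genes_k27me3)))
}
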