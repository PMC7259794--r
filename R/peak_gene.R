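#' Linking RA-regulated peaks to genes
#'
#' Each significant peak is linked primarily to the gene with the nearest
#' annotated promoter (TSS), and secondarily to every differentially
#' expressed gene whose TSS lies in the same topologically associating
#' domain (TAD). Distances are measured from the peak midpoint by default
#' (configurable to peak edge); TAD membership is by TSS containment, and
#' a peak belongs to the single TAD containing its midpoint.
#'
#' @name peak_gene_assignment
NULL

peak_anchor <- function(peaks, anchor = "midpoint") {
  interval_midpoint(peaks$start, peaks$end)
}

link_distance <- function(peak, tss, anchor = "midpoint") {
  if (anchor == "edge") {
    inside <- tss >= peak$start & tss < peak$end
    d <- pmin(abs(tss - peak$start), abs(tss - (peak$end - 1)))
    d[inside] <- 0L
    as.integer(d)
  } else {
    as.integer(abs(interval_midpoint(peak$start, peak$end) - tss))
  }
}

#' Link each peak to the gene with the nearest TSS
#'
#' Ties on distance are broken lexicographically by `gene_id`. Peaks on a
#' chromosome with no annotated gene are returned with `gene_id = NA`
#' (logged), never silently dropped.
#'
#' @param peaks Peak tibble (columns `chrom`, `start`, `end`, `peak_id`).
#' @param genes Gene tibble from [read_gene_bed()].
#' @param anchor "midpoint" (default) or "edge".
#' @param quiet Suppress the unassigned-peak message.
#' @return A tibble with columns `peak_id`, `gene_id`, `link_type`
#'   ("nearest"), `distance`, `tad_id` (NA).
#' @export
nearest_gene <- function(peaks, genes, anchor = c("midpoint", "edge"),
                         quiet = FALSE) {
  anchor <- match.arg(anchor)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(peak_id = character(), gene_id = character(),
                          link_type = character(), distance = integer(),
                          tad_id = character()))
  }
  out <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    g <- genes[genes$chrom == p$chrom, , drop = FALSE]
    if (nrow(g) == 0) {
      return(tibble::tibble(peak_id = p$peak_id, gene_id = NA_character_,
                            link_type = "nearest", distance = NA_integer_,
                            tad_id = NA_character_))
    }
    d <- link_distance(p, g$tss, anchor)
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[order(g$gene_id[best])][1]
    tibble::tibble(peak_id = p$peak_id, gene_id = g$gene_id[best],
                   link_type = "nearest", distance = d[best],
                   tad_id = NA_character_)
  })
  n_unassigned <- sum(is.na(out$gene_id))
  if (n_unassigned > 0 && !quiet) {
    message(n_unassigned, " peak(s) on chromosomes without genes left unassigned")
  }
  out
}

#' Assign each peak to the TAD containing its midpoint
#'
#' Half-open containment: a midpoint exactly at a TAD's `end` is outside
#' it. Peaks in inter-TAD gaps get `tad_id = NA`.
#'
#' @param peaks Peak tibble.
#' @param tads TAD tibble from [read_tad_bed()] (validated non-overlapping).
#' @return A tibble with columns `peak_id`, `tad_id`.
#' @export
assign_tad <- function(peaks, tads) {
  validate_tads(tads)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(peak_id = character(), tad_id = character()))
  }
  mid <- peak_anchor(peaks)
  tad_id <- vapply(seq_len(nrow(peaks)), function(i) {
    hit <- which(tads$chrom == peaks$chrom[i] &
                   tads$start <= mid[i] & mid[i] < tads$end)
    if (length(hit) == 0) NA_character_ else tads$tad_id[hit[1]]
  }, character(1))
  tibble::tibble(peak_id = peaks$peak_id, tad_id = tad_id)
}

#' Link peaks to differentially expressed genes in the same TAD
#'
#' For each peak assigned to a TAD, one link is made to every gene whose
#' TSS lies inside that TAD and whose `gene_id` is differentially
#' expressed, excluding the gene already linked as nearest. More than one
#' regulated gene per TAD is supported.
#'
#' @param peaks Peak tibble.
#' @param tads TAD tibble.
#' @param genes Gene tibble.
#' @param de DE gene set from [filter_de_genes()].
#' @param nearest Nearest-gene links from [nearest_gene()] (used for the
#'   exclusion rule); if `NULL`, computed internally.
#' @param anchor Distance anchor, as in [nearest_gene()].
#' @return A tibble with columns `peak_id`, `gene_id`, `link_type`
#'   ("tad"), `distance`, `tad_id`.
#' @export
tad_links <- function(peaks, tads, genes, de, nearest = NULL,
                      anchor = c("midpoint", "edge")) {
  anchor <- match.arg(anchor)
  if (is.null(nearest)) nearest <- nearest_gene(peaks, genes, anchor, quiet = TRUE)
  assignments <- assign_tad(peaks, tads)
  de_ids <- unique(de$gene_id)
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    tid <- assignments$tad_id[assignments$peak_id == p$peak_id][1]
    if (is.na(tid)) return(NULL)
    tad <- tads[tads$tad_id == tid, ][1, ]
    near_gene <- nearest$gene_id[nearest$peak_id == p$peak_id]
    g <- genes[genes$chrom == tad$chrom &
                 genes$tss >= tad$start & genes$tss < tad$end &
                 genes$gene_id %in% de_ids &
                 !genes$gene_id %in% near_gene, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    g <- g[order(g$gene_id), ]
    tibble::tibble(peak_id = p$peak_id, gene_id = g$gene_id,
                   link_type = "tad",
                   distance = link_distance(p, g$tss, anchor),
                   tad_id = tid)
  })
}

#' All peak-gene links (nearest plus same-TAD)
#'
#' Convenience wrapper combining [nearest_gene()] and [tad_links()].
#' Without a TAD table the pipeline degrades to nearest-only linking.
#'
#' @inheritParams tad_links
#' @param quiet Suppress messages.
#' @return A tibble of links; a (peak, gene) pair appears at most once.
#' @export
link_peaks_to_genes <- function(peaks, genes, de, tads = NULL,
                                anchor = c("midpoint", "edge"),
                                quiet = FALSE) {
  anchor <- match.arg(anchor)
  near <- nearest_gene(peaks, genes, anchor, quiet = quiet)
  if (is.null(tads)) {
    if (!quiet) message("no TAD table supplied: TAD rescue disabled")
    return(near[!is.na(near$gene_id), , drop = FALSE])
  }
  tl <- tad_links(peaks, tads, genes, de, nearest = near, anchor = anchor)
  dplyr::bind_rows(near[!is.na(near$gene_id), , drop = FALSE], tl)
}
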