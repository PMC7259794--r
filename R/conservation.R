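#' Cross-species conservation of RAREs
#'
#' Conservation in a clade is operationalised as: the supplied orthologous
#' sequence window for that clade contains a same-type DR match (both
#' strands) within the high-confidence mismatch tolerance. The
#' conservation tier of a RARE is the most distal clade with a match, in
#' the order rodent < human < bird < reptile < frog < fish; a distal match
#' sets the tier even when intermediate clades are missing. The highly
#' conserved set retains RAREs with a tier beyond mammals (bird, reptile,
#' frog, or fish) and at most 1 half-site mismatch.
#'
#' @name conservation
NULL

# clades counted as "conserved beyond mammals"
distal_clades <- function(cfg = pipeline_config()) {
  setdiff(cfg$clade_order, c("rodent", "human"))
}

#' Is a motif of the given type present in an ortholog window?
#'
#' Alignment gaps (`-`) are stripped before scanning; a gap-only or absent
#' window is not conserved.
#'
#' @param window DNA string over ACGTN- (one clade's orthologous window),
#'   or `NA`.
#' @param motif_type "DR1", "DR2", or "DR5".
#' @param tol Mismatch tolerance (default 1, the high-confidence level).
#' @param consensus Half-site consensus.
#' @return `TRUE` if the window contains at least one same-type match
#'   within tolerance on either strand.
#' @export
rare_conserved_in <- function(window, motif_type, tol = 1L,
                              consensus = "RGKTCA") {
  if (is.null(window) || length(window) == 0 || is.na(window)) return(FALSE)
  stopifnot(motif_type %in% names(MOTIF_SPACERS))
  clean <- stringr::str_remove_all(toupper(window), "-")
  if (nchar(clean) < 12L + MOTIF_SPACERS[[motif_type]]) return(FALSE)
  hits <- scan_rares(clean, tol = tol, consensus = consensus,
                     spacers = MOTIF_SPACERS[motif_type])
  nrow(hits) > 0
}

#' Per-clade conservation flags for one RARE
#'
#' @param motif_type "DR1", "DR2", or "DR5".
#' @param windows Named character vector or list (clade -> window
#'   sequence); clades absent from `windows` are flagged `FALSE`.
#' @param cfg A [pipeline_config()].
#' @return Named logical vector with names exactly `cfg$clade_order`.
#' @export
conservation_flags <- function(motif_type, windows, cfg = pipeline_config()) {
  vapply(cfg$clade_order, function(clade) {
    w <- windows[[clade]]
    if (is.null(w)) FALSE
    else rare_conserved_in(w, motif_type, cfg$high_conf_mismatch_tol,
                           cfg$halfsite_consensus)
  }, logical(1))
}

#' Conservation tier from per-clade flags
#'
#' @param flags Named logical vector over `cfg$clade_order` (or a data
#'   frame of such columns for the vectorised form).
#' @param cfg A [pipeline_config()].
#' @return The most distal clade whose flag is `TRUE`, or "none".
#' @examples
#' conservation_tier(c(rodent = TRUE, human = TRUE, bird = TRUE,
#'                     reptile = FALSE, frog = FALSE, fish = FALSE)) # "bird"
#' @export
conservation_tier <- function(flags, cfg = pipeline_config()) {
  if (is.data.frame(flags)) {
    stopifnot(all(cfg$clade_order %in% names(flags)))
    m <- as.matrix(flags[, cfg$clade_order, drop = FALSE])
    return(apply(m, 1, function(f) {
      on <- which(f)
      if (length(on) == 0) "none" else cfg$clade_order[max(on)]
    }))
  }
  stopifnot(all(cfg$clade_order %in% names(flags)))
  on <- which(flags[cfg$clade_order])
  if (length(on) == 0) "none" else cfg$clade_order[max(on)]
}

#' Fill the `conserved_to` column of a candidate table
#'
#' Looks up each attached RARE's windows by its identifier
#' "chrom:start-end:type" (1-based region string plus DR type), computes
#' per-clade flags and the tier. RAREs without windows get tier "none".
#'
#' @param candidates An `ra_candidates` tibble.
#' @param ortholog_windows Named list (clade) of named character vectors
#'   (RARE id -> window), as from [read_ortholog_windows()]; `NULL` leaves
#'   every tier "none".
#' @param cfg A [pipeline_config()].
#' @return The candidate table with `conserved_to` filled.
#' @export
add_conservation <- function(candidates, ortholog_windows = NULL,
                             cfg = pipeline_config()) {
  has_rare <- !is.na(candidates$rare_region)
  candidates$conserved_to[has_rare] <- "none"
  if (is.null(ortholog_windows) || !any(has_rare)) return(candidates)
  ids <- paste0(candidates$rare_region[has_rare], ":",
                candidates$rare_type[has_rare])
  uniq <- unique(ids)
  tiers <- vapply(uniq, function(id) {
    type <- sub("^.*:", "", id)
    wins <- lapply(ortholog_windows, function(clade_seqs) {
      if (id %in% names(clade_seqs)) clade_seqs[[id]] else NULL
    })
    conservation_tier(conservation_flags(type, wins, cfg), cfg)
  }, character(1))
  candidates$conserved_to[has_rare] <- unname(tiers[ids])
  candidates
}

#' Apply the highly conserved filter
#'
#' Retains RAREs whose conservation tier is beyond mammals (bird, reptile,
#' frog, or fish) and whose mismatch count is at most
#' `cfg$high_conf_mismatch_tol`, then collects the distinct genes (nearest
#' plus same-TAD) linked to the retained RAREs.
#'
#' @param candidates An `ra_candidates` tibble with `conserved_to` filled
#'   (see [add_conservation()]).
#' @param cfg A [pipeline_config()].
#' @return A list with `rares` (distinct retained RARE tibble), `genes`
#'   (sorted character vector), `n_rares`, `n_genes`.
#' @export
filter_highly_conserved <- function(candidates, cfg = pipeline_config()) {
  keep <- !is.na(candidates$rare_region) &
    candidates$conserved_to %in% distal_clades(cfg) &
    candidates$rare_mismatches <= cfg$high_conf_mismatch_tol
  kept <- candidates[keep, , drop = FALSE]
  rares <- dplyr::distinct(
    kept[, c("rare_region", "rare_type", "rare_mismatches", "element_class",
             "conserved_to")])
  genes <- sort(unique(kept$gene_id))
  list(rares = rares, genes = genes,
       n_rares = nrow(rares), n_genes = length(genes))
}
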