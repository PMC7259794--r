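#' End-to-end candidate-target pipeline
#'
#' Chains the full analysis: differential filters on expression and peaks,
#' peak-to-gene linking (nearest promoter, then same-TAD rescue), RARE
#' scanning inside significant peaks, enhancer/silencer classification,
#' and conservation tiering. All stages are deterministic given the same
#' inputs and configuration.
#'
#' @param expr Expression tibble (see [read_diff_expr()]).
#' @param peaks_k27ac,peaks_k27me3 Peak tibbles (see [read_diff_peaks()]);
#'   either may be `NULL`.
#' @param genome Named character vector of chromosome sequences.
#' @param genes Gene tibble (see [read_gene_bed()]).
#' @param tads TAD tibble or `NULL` (nearest-only linking).
#' @param ortholog_windows Conservation windows (see
#'   [read_ortholog_windows()]) or `NULL`.
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage record-count messages.
#' @return An object of class `ra_run`: a list with `candidates` (the
#'   `ra_candidates` tibble), `summary` (one-row count tibble), `de`,
#'   `sig_peaks`, `links`, `rares`, `config`, and `manifest` (stage
#'   record counts and config snapshot).
#' @examples
#' sim <- simulate_ra_inputs(simulation_params(n_genes = 40,
#'   n_true_targets = 4, n_null_peaks = 20, seed = 7))
#' run <- run_ra_pipeline(sim$expr, sim$peaks_k27ac, sim$peaks_k27me3,
#'   sim$genome, sim$genes, sim$tads, sim$ortholog_windows, quiet = TRUE)
#' glance(run)
#' @export
run_ra_pipeline <- function(expr, peaks_k27ac = NULL, peaks_k27me3 = NULL,
                            genome = NULL, genes = NULL, tads = NULL,
                            ortholog_windows = NULL,
                            cfg = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  de <- filter_de_genes(expr, cfg)
  say("expression: ", nrow(expr), " genes -> ", nrow(de),
      " differentially expressed")

  sig_list <- list()
  for (pk in list(peaks_k27ac, peaks_k27me3)) {
    if (is.null(pk) || nrow(pk) == 0) next
    sig <- filter_diff_peaks(pk, cfg)
    say(unique(pk$mark), ": ", nrow(pk), " peaks -> ", nrow(sig),
        " significant")
    sig_list[[length(sig_list) + 1]] <- sig
  }
  sig_peaks <- dplyr::bind_rows(sig_list)
  if (nrow(sig_peaks) == 0) {
    say("no significant peaks under the configured thresholds")
    sig_peaks <- tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      mark = character(), log2fc = numeric(), pvalue = numeric(),
      bh_p = numeric(), peak_id = character(),
      peak_direction = character())
  }

  links <- link_peaks_to_genes(sig_peaks, genes, de, tads, cfg$distance_anchor,
                               quiet = quiet)
  say("links: ", sum(links$link_type == "nearest"), " nearest + ",
      sum(links$link_type == "tad"), " same-TAD")

  rares <- scan_peaks(sig_peaks, genome, cfg$scan_mismatch_tol,
                      cfg$halfsite_consensus)
  say("RARE scan: ", nrow(rares), " matches in ",
      length(unique(rares$peak_id)), " peaks (tolerance ",
      cfg$scan_mismatch_tol, ")")

  candidates <- build_candidates(sig_peaks, de, links, rares, cfg)
  candidates <- add_conservation(candidates, ortholog_windows, cfg)
  summary <- summarize_candidates(candidates, cfg)
  say("candidates: ", summary$n_genes_union, " genes (",
      summary$n_genes_with_rare, " with a RARE)")

  manifest <- list(
    config = unclass(cfg),
    counts = list(
      genes_in = nrow(expr), genes_de = nrow(de),
      peaks_in = sum(vapply(list(peaks_k27ac, peaks_k27me3),
                            function(x) if (is.null(x)) 0L else nrow(x),
                            integer(1))),
      peaks_significant = nrow(sig_peaks),
      links = nrow(links), rare_matches = nrow(rares),
      candidate_genes = summary$n_genes_union),
    seed = cfg$seed
  )
  structure(
    list(candidates = candidates, summary = summary, de = de,
         sig_peaks = sig_peaks, links = links, rares = rares,
         config = cfg, manifest = manifest),
    class = "ra_run")
}

#' @export
print.ra_run <- function(x, ...) {
  s <- x$summary
  cat("RA candidate-target run\n")
  cat(sprintf("  significant peaks: %d | links: %d | RARE matches: %d\n",
              nrow(x$sig_peaks), nrow(x$links), nrow(x$rares)))
  cat(sprintf("  candidate genes: %d (H3K27ac %d, H3K27me3 %d), %d with a RARE\n",
              s$n_genes_union, s$n_genes_k27ac, s$n_genes_k27me3,
              s$n_genes_with_rare))
  cat(sprintf("  RARE enhancers: %d | silencers: %d | highly conserved: %d\n",
              s$n_rare_enhancers, s$n_rare_silencers, s$n_highly_conserved))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Candidate table of a pipeline run
#'
#' @param x An `ra_run`.
#' @param ... Unused.
#' @return The candidate table as a plain tibble (one row per gene x peak
#'   x RARE).
#' @export
tidy.ra_run <- function(x, ...) {
  out <- x$candidates
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a pipeline run
#'
#' @param x An `ra_run`.
#' @param ... Unused.
#' @return The summary-count tibble from [summarize_candidates()].
#' @export
glance.ra_run <- function(x, ...) {
  x$summary
}

#' Write the outputs of a pipeline run
#'
#' Candidate table (TSV, deterministic order), summary counts (JSON), and
#' the run manifest (JSON). Re-running on identical inputs and config
#' produces byte-identical files.
#'
#' @param run An `ra_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_candidate_table(run$candidates, file.path(dir, "candidates.tsv"))
  jsonlite::write_json(as.list(run$summary), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Check the packaged conserved-RARE table
#'
#' Runs the scanner's printed-sequence classifier and the highly conserved
#' filter over the packaged fixture of conserved RAREs and reports the
#' retained RARE count, the distinct linked-gene count (nearest plus
#' same-TAD columns), and the maximum half-site mismatch count. `ok` is
#' `TRUE` when the tallies equal the fixture's published values (24 RAREs,
#' 38 genes, at most 1 mismatch).
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress the printed report.
#' @return A list: `n_rares`, `n_genes`, `max_mismatches`, `ok`.
#' @export
check_conserved_rare_table <- function(cfg = pipeline_config(),
                                       quiet = FALSE) {
  fx <- load_table2_fixture()
  cls <- classify_printed_rare(fx$sequence_printed, cfg$halfsite_consensus)
  flags <- fx[, paste0("conserved_", cfg$clade_order)]
  names(flags) <- cfg$clade_order
  tier <- conservation_tier(flags, cfg)

  # fixture rows in candidate shape: one row per RARE x linked gene
  cand <- purrr::map_dfr(seq_len(nrow(fx)), function(i) {
    genes <- c(fx$nearest_gene[i], fx$tad_genes[[i]])
    tibble::tibble(
      gene_id = genes,
      rare_region = fx$region[i],
      rare_type = fx$motif_type[i],
      rare_mismatches = cls$mismatches[i],
      element_class = fx$element_class[i],
      conserved_to = tier[i])
  })
  kept <- filter_highly_conserved(cand, cfg)
  max_mm <- max(cls$mismatches)
  ok <- kept$n_rares == 24 && kept$n_genes == 38 &&
    max_mm <= cfg$high_conf_mismatch_tol
  if (!quiet) {
    cat("RAREs:", kept$n_rares, "\n")
    cat("genes:", kept$n_genes, "\n")
    cat("max mismatches:", max_mm, "\n")
    cat(if (ok) "OK\n" else "MISMATCH with packaged table\n")
  }
  invisible(list(n_rares = kept$n_rares, n_genes = kept$n_genes,
                 max_mismatches = max_mm, ok = ok))
}
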