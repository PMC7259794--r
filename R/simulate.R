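#' Synthetic inputs with planted RAREs and known truth
#'
#' Generates a random genome, gene and TAD annotations, differential peak
#' and expression tables, and per-clade ortholog windows with the
#' statistical structure the pipeline assumes: true RA targets have
#' concordant mark/expression log2 fold changes beyond threshold with a
#' RARE planted inside the regulated peak and near-certain raw p-values;
#' null genes and peaks have near-zero log2FCs and uniform p-values.
#' Everything is reproducible from the seed, and a truth manifest records
#' every planted feature for recovery testing.
#'
#' @name synthetic_data
NULL

#' Parameters for the synthetic generator
#'
#' Defaults emulate the observed structure of the real study: true targets
#' with |RNA log2FC| well above the 0.85 cutoff and mark |log2FC| above
#' the mark cutoffs, nulls tight around zero.
#'
#' @param n_chroms Number of chromosomes. Default 4.
#' @param chrom_length Chromosome length in bp. Default 1e6.
#' @param n_genes Total genes (true + null). Default 550.
#' @param n_tads_per_chrom TADs tiling each chromosome. Default 25 (about
#'   40 kb per TAD at the default chromosome length).
#' @param n_true_targets Genes given true RA regulation. Default 50.
#' @param fraction_repressed Fraction of true targets RA-represses.
#'   Default 0.25.
#' @param rare_type_probs Sampling distribution of planted motif types.
#' @param mismatch_probs Sampling distribution of planted half-site
#'   mismatch counts (names "0", "1").
#' @param effect_mu,effect_sigma Mean/sd of |log2FC| for true signals
#'   (mark and expression), truncated above the relevant threshold.
#'   Defaults 2.0 / 0.3.
#' @param null_sigma Sd of null log2FCs. Default 0.2.
#' @param n_null_peaks Unregulated peaks added per run (split between
#'   marks). Default 200.
#' @param frac_tad_linked Fraction of true peaks placed away from the
#'   promoter (elsewhere in the gene's TAD) so the TAD-rescue path is
#'   exercised. Default 0.2.
#' @param tier_probs Sampling distribution of planted conservation tiers
#'   over "none" plus the clade order; defaults give the nested pattern
#'   where proximal conservation is more common than distal.
#' @param seed Integer seed.
#' @return A list of class `ra_sim_params`.
#' @export
simulation_params <- function(n_chroms = 4L,
                              chrom_length = 1e6,
                              n_genes = 550L,
                              n_tads_per_chrom = 25L,
                              n_true_targets = 50L,
                              fraction_repressed = 0.25,
                              rare_type_probs = c(DR1 = 1/3, DR2 = 1/3, DR5 = 1/3),
                              mismatch_probs = c("0" = 0.5, "1" = 0.5),
                              effect_mu = 2.0,
                              effect_sigma = 0.3,
                              null_sigma = 0.2,
                              n_null_peaks = 200L,
                              frac_tad_linked = 0.2,
                              tier_probs = c(none = 0.2, rodent = 0.2,
                                             human = 0.2, bird = 0.1,
                                             reptile = 0.1, frog = 0.1,
                                             fish = 0.1),
                              seed = 1L) {
  stopifnot(
    n_true_targets <= n_genes,
    abs(sum(rare_type_probs) - 1) < 1e-9,
    abs(sum(mismatch_probs) - 1) < 1e-9,
    abs(sum(tier_probs) - 1) < 1e-9,
    effect_mu > 0.85  # above every default threshold
  )
  structure(as.list(environment()), class = "ra_sim_params")
}

DNA <- c("A", "C", "G", "T")

random_dna_chars <- function(n) sample(DNA, n, replace = TRUE)

# instantiate one 6-bp half-site conforming to the consensus
instantiate_halfsite <- function(sets) {
  vapply(sets, function(s) s[sample.int(length(s), 1)], character(1))
}

# introduce `k` mismatches into a 12-letter pair of half-sites
mutate_halfsites <- function(hs, sets12, k) {
  if (k == 0) return(hs)
  pos <- sample.int(12, k)
  for (p in pos) {
    hs[p] <- sample(setdiff(DNA, sets12[[p]]), 1)
  }
  hs
}

build_rare_seq <- function(motif_type, mismatches, sets) {
  spacer_len <- MOTIF_SPACERS[[motif_type]]
  hs <- c(instantiate_halfsite(sets), instantiate_halfsite(sets))
  hs <- mutate_halfsites(hs, c(sets, sets), mismatches)
  c(hs[1:6], random_dna_chars(spacer_len), hs[7:12])
}

#' Generate a full synthetic input set
#'
#' @param params A [simulation_params()].
#' @param cfg A [pipeline_config()] (thresholds the truncations respect).
#' @return A list with elements `genome` (named character vector), `genes`,
#'   `tads`, `peaks_k27ac`, `peaks_k27me3`, `expr` (tibbles in the reader
#'   schemas), `ortholog_windows` (clade -> named vector), and `truth`
#'   (list of `genes`, `peaks`, `rares` tibbles).
#' @export
simulate_ra_inputs <- function(params = simulation_params(),
                               cfg = pipeline_config()) {
  set.seed(params$seed)
  L <- as.integer(params$chrom_length)
  chroms <- paste0("chr", seq_len(params$n_chroms))

  genome_chars <- lapply(chroms, function(ch) random_dna_chars(L))
  names(genome_chars) <- chroms

  # TADs: contiguous tiles per chromosome; breakpoints on a 20 kb grid so
  # every TAD comfortably holds a peak
  tads <- purrr::map_dfr(chroms, function(ch) {
    k <- params$n_tads_per_chrom
    grid <- seq(2e4, L - 2e4, by = 2e4)
    stopifnot(length(grid) >= k - 1)
    cuts <- sort(sample(grid, k - 1))
    tibble::tibble(chrom = ch,
                   start = c(0, cuts), end = c(cuts, L),
                   tad_id = paste0(ch, "_tad", seq_len(k)))
  })

  # genes: one per equal slot, non-overlapping by construction
  per_chrom <- diff(round(seq(0, params$n_genes, length.out = params$n_chroms + 1)))
  genes <- purrr::map_dfr(seq_along(chroms), function(ci) {
    n <- per_chrom[ci]
    if (n == 0) return(NULL)
    slot <- floor(L / n)
    len <- sample(2000:min(5000, slot - 1000), n, replace = TRUE)
    offset <- vapply(seq_len(n), function(i) {
      sample.int(slot - len[i] - 500, 1)
    }, integer(1))
    start <- (seq_len(n) - 1L) * slot + offset
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tibble::tibble(chrom = chroms[ci], start = start, end = start + len,
                   strand = strand)
  })
  genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
  genes$tss <- as.integer(ifelse(genes$strand == "+", genes$start,
                                 genes$end - 1))
  genes <- genes[, c("chrom", "start", "end", "gene_id", "strand", "tss")]

  # true targets and directions
  true_idx <- sort(sample.int(nrow(genes), params$n_true_targets))
  direction <- ifelse(
    stats::runif(params$n_true_targets) < params$fraction_repressed,
    "RA_repressed", "RA_activated")

  tad_of <- function(ch, pos) {
    hit <- tads[tads$chrom == ch & tads$start <= pos & pos < tads$end, ]
    if (nrow(hit) == 0) NA_character_ else hit$tad_id[1]
  }

  rtrunc_above <- function(n, mu, sigma, floor_at) {
    x <- abs(stats::rnorm(n, mu, sigma))
    while (any(x <= floor_at)) {
      i <- x <= floor_at
      x[i] <- abs(stats::rnorm(sum(i), mu, sigma))
    }
    x
  }

  sets <- consensus_sets(cfg$halfsite_consensus)
  clade_order <- cfg$clade_order

  true_peaks <- vector("list", params$n_true_targets)
  true_rares <- vector("list", params$n_true_targets)
  windows <- stats::setNames(
    replicate(length(clade_order), character(0), simplify = FALSE),
    clade_order)

  placed <- tibble::tibble(chrom = character(), start = integer(),
                           end = integer())
  for (t in seq_len(params$n_true_targets)) {
    g <- genes[true_idx[t], ]
    gene_tad <- tad_of(g$chrom, g$tss)
    width <- sample(600:2000, 1)
    via_tad <- stats::runif(1) < params$frac_tad_linked
    tad_row <- tads[tads$tad_id == gene_tad, ]
    ok <- FALSE
    for (try in 1:200) {
      if (via_tad) {
        mid <- sample(seq(tad_row$start + width, tad_row$end - width), 1)
      } else {
        mid <- g$tss + sample(-10000:10000, 1)
      }
      p_start <- as.integer(mid - floor(width / 2))
      p_end <- p_start + width
      if (p_start < 0 || p_end > L) next
      if (!identical(tad_of(g$chrom, interval_midpoint(p_start, p_end)),
                     gene_tad)) next
      clash <- placed$chrom == g$chrom &
        pmin(placed$end, p_end) > pmax(placed$start, p_start)
      if (any(clash)) next
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not place a peak for target ", g$gene_id,
           " after bounded retries; try fewer genes or targets",
           call. = FALSE)
    }
    placed <- dplyr::bind_rows(placed,
      tibble::tibble(chrom = g$chrom, start = p_start, end = p_end))

    mark <- sample(MARK_LEVELS, 1)
    # concordant sign: activated -> ac down / me3 up in the KO
    sign <- if (direction[t] == "RA_activated") {
      if (mark == "H3K27ac") -1 else 1
    } else {
      if (mark == "H3K27ac") 1 else -1
    }
    lfc <- sign * rtrunc_above(1, params$effect_mu, params$effect_sigma,
                               mark_threshold(mark, cfg))
    true_peaks[[t]] <- tibble::tibble(
      chrom = g$chrom, start = p_start, end = p_end, mark = mark,
      log2fc = lfc, pvalue = stats::runif(1, 0, 1e-4),
      gene_id = g$gene_id, status = "true",
      link_via = if (via_tad) "tad" else "nearest")

    # plant the RARE by substitution inside the peak
    motif_type <- sample(names(params$rare_type_probs), 1,
                         prob = params$rare_type_probs)
    mism <- as.integer(sample(names(params$mismatch_probs), 1,
                              prob = params$mismatch_probs))
    rare_chars <- build_rare_seq(motif_type, mism, sets)
    rlen <- length(rare_chars)
    r_start <- p_start + sample.int(width - rlen, 1) - 1L
    genome_chars[[g$chrom]][(r_start + 1):(r_start + rlen)] <- rare_chars

    tier <- sample(names(params$tier_probs), 1, prob = params$tier_probs)
    rare_region <- format_region(g$chrom, r_start, r_start + rlen)
    true_rares[[t]] <- tibble::tibble(
      chrom = g$chrom, start = r_start, end = r_start + rlen,
      region = rare_region, motif_type = motif_type, mismatches = mism,
      element_class = classify_element(direction[t]), tier = tier,
      gene_id = g$gene_id)
  }
  true_peaks <- dplyr::bind_rows(true_peaks)
  true_rares <- dplyr::bind_rows(true_rares)
  if (nrow(true_peaks) == 0) {
    true_peaks <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      mark = character(), log2fc = numeric(), pvalue = numeric(),
      gene_id = character(), status = character(), link_via = character())
    true_rares <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      region = character(), motif_type = character(),
      mismatches = integer(), element_class = character(),
      tier = character(), gene_id = character())
  }

  # ortholog windows: mouse RARE +/- 30 bp copied for clades up to the
  # planted tier, random (rejected for same-type matches) beyond
  for (t in seq_len(nrow(true_rares))) {
    r <- true_rares[t, ]
    w_start <- max(0L, r$start - 30L)
    w_end <- min(L, r$end + 30L)
    mouse_win <- paste(genome_chars[[r$chrom]][(w_start + 1):w_end],
                       collapse = "")
    rare_id <- paste0(r$region, ":", r$motif_type)
    tier_rank <- match(r$tier, clade_order, nomatch = 0L)
    for (ci in seq_along(clade_order)) {
      if (ci <= tier_rank) {
        win <- mouse_win
      } else {
        win <- scrambled_window(nchar(mouse_win), r$motif_type, cfg)
      }
      windows[[clade_order[ci]]][rare_id] <- win
    }
  }

  # null peaks
  null_peaks <- NULL
  if (params$n_null_peaks > 0) {
    width <- sample(600:2000, params$n_null_peaks, replace = TRUE)
    start <- vapply(width, function(w) sample.int(L - w, 1), integer(1))
    null_peaks <- tibble::tibble(
      chrom = sample(chroms, params$n_null_peaks, replace = TRUE),
      start = start, end = start + width,
      mark = rep_len(MARK_LEVELS, params$n_null_peaks),
      log2fc = stats::rnorm(params$n_null_peaks, 0, params$null_sigma),
      pvalue = stats::runif(params$n_null_peaks),
      gene_id = NA_character_, status = "null", link_via = NA_character_)
  }
  all_peaks <- dplyr::bind_rows(true_peaks, null_peaks)
  all_peaks$bh_p <- NA_real_
  all_peaks$peak_id <- paste0(all_peaks$mark, ":",
                              format_region(all_peaks$chrom, all_peaks$start,
                                            all_peaks$end))
  peak_cols <- c("chrom", "start", "end", "mark", "log2fc", "pvalue",
                 "bh_p", "peak_id")

  # expression table
  expr <- tibble::tibble(
    gene_id = genes$gene_id,
    log2fc = stats::rnorm(nrow(genes), 0, params$null_sigma),
    fpkm_wt = stats::rlnorm(nrow(genes), 1, 1),
    fpkm_ko = stats::rlnorm(nrow(genes), 1, 1))
  e_sign <- ifelse(direction == "RA_activated", -1, 1)
  expr$log2fc[true_idx] <- e_sign *
    rtrunc_above(params$n_true_targets, params$effect_mu,
                 params$effect_sigma, cfg$rna_abs_log2fc_min)
  expr$fpkm_wt[true_idx] <- pmax(expr$fpkm_wt[true_idx], 2 * cfg$fpkm_min)
  expr$fpkm_ko[true_idx] <- pmax(expr$fpkm_ko[true_idx], 2 * cfg$fpkm_min)

  truth_genes <- tibble::tibble(gene_id = genes$gene_id,
                                direction = "null")
  truth_genes$direction[true_idx] <- direction

  list(
    genome = vapply(genome_chars, paste, character(1), collapse = ""),
    genes = genes,
    tads = tads,
    peaks_k27ac = all_peaks[all_peaks$mark == "H3K27ac", peak_cols],
    peaks_k27me3 = all_peaks[all_peaks$mark == "H3K27me3", peak_cols],
    expr = expr,
    ortholog_windows = windows,
    truth = list(
      genes = truth_genes,
      peaks = all_peaks[, c("peak_id", "chrom", "start", "end", "mark",
                            "status", "gene_id", "link_via")],
      rares = true_rares
    ),
    params = params
  )
}

# random window guaranteed to contain no same-type match within the
# high-confidence tolerance
scrambled_window <- function(len, motif_type, cfg) {
  for (i in 1:50) {
    win <- paste(random_dna_chars(len), collapse = "")
    if (!rare_conserved_in(win, motif_type, cfg$high_conf_mismatch_tol,
                           cfg$halfsite_consensus)) {
      return(win)
    }
  }
  strrep("A", len)  # all-A never matches the consensus
}

#' Write a synthetic input set to disk
#'
#' Produces files in exactly the formats the readers consume: genome.fa,
#' genes.bed, tads.bed, peaks_H3K27ac.tsv, peaks_H3K27me3.tsv,
#' expression.tsv, orthologs_<clade>.fa, and truth.json.
#'
#' @param sim Output of [simulate_ra_inputs()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(gen, file.path(dir, "genome.fa"))
  readr::write_tsv(
    dplyr::mutate(sim$genes[, c("chrom", "start", "end", "gene_id")],
                  score = 0, strand = sim$genes$strand),
    file.path(dir, "genes.bed"), col_names = FALSE)
  readr::write_tsv(sim$tads, file.path(dir, "tads.bed"), col_names = FALSE)
  readr::write_tsv(sim$peaks_k27ac[, 1:7], file.path(dir, "peaks_H3K27ac.tsv"))
  readr::write_tsv(sim$peaks_k27me3[, 1:7], file.path(dir, "peaks_H3K27me3.tsv"))
  readr::write_tsv(sim$expr, file.path(dir, "expression.tsv"))
  for (clade in names(sim$ortholog_windows)) {
    w <- sim$ortholog_windows[[clade]]
    if (length(w) == 0) next
    Biostrings::writeXStringSet(Biostrings::BStringSet(w),
                                file.path(dir, paste0("orthologs_", clade, ".fa")))
  }
  jsonlite::write_json(
    list(genes = sim$truth$genes, peaks = sim$truth$peaks,
         rares = sim$truth$rares, seed = sim$params$seed),
    file.path(dir, "truth.json"))
  invisible(dir)
}

#' Precision/recall of a pipeline run against the truth manifest
#'
#' Gene recall is the fraction of true targets recovered as candidates
#' with at least one attached RARE of the planted type; gene precision is
#' the fraction of candidate genes that are true targets. RARE recovery is
#' the fraction of planted RAREs present in the candidate table at the
#' planted coordinates with the planted type, and class accuracy the
#' fraction of recovered RAREs whose enhancer/silencer call matches the
#' truth. An empty candidate table against nonempty truth reports
#' precision 1 with `empty_prediction = TRUE`.
#'
#' @param candidates An `ra_candidates` tibble (or an `ra_run`).
#' @param truth The `truth` element of [simulate_ra_inputs()] output.
#' @return A list: `gene_precision`, `gene_recall`, `rare_recovery`,
#'   `class_confusion` (table), `empty_prediction`.
#' @export
recovery_report <- function(candidates, truth) {
  if (inherits(candidates, "ra_run")) candidates <- candidates$candidates
  true_genes <- truth$genes$gene_id[truth$genes$direction != "null"]
  pred_genes <- unique(candidates$gene_id)
  empty <- length(pred_genes) == 0

  rare_key <- function(region, type) paste(region, type)
  pred_rares <- candidates[!is.na(candidates$rare_region), , drop = FALSE]
  truth_key <- rare_key(truth$rares$region, truth$rares$motif_type)
  pred_key <- rare_key(pred_rares$rare_region, pred_rares$rare_type)
  rare_found <- truth_key %in% pred_key
  # class is judged on the row linking the RARE to its planted gene; a
  # RARE shared with an opposite-direction gene in the same TAD carries a
  # second classification on that gene's own row by design
  gene_key <- paste(pred_key, pred_rares$gene_id)
  hit <- match(paste(truth_key, truth$rares$gene_id), gene_key)
  pred_class <- pred_rares$element_class[hit]

  genes_with_typed_rare <- unique(pred_rares$gene_id[pred_key %in% truth_key])
  gene_recall <- if (length(true_genes) == 0) 1 else
    mean(true_genes %in% genes_with_typed_rare)
  gene_precision <- if (empty) 1 else mean(pred_genes %in% true_genes)

  confusion <- table(truth = truth$rares$element_class,
                     predicted = factor(
                       ifelse(rare_found & !is.na(pred_class), pred_class,
                              "missed"),
                       levels = c("enhancer", "silencer", "missed")))
  list(
    gene_precision = gene_precision,
    gene_recall = gene_recall,
    rare_recovery = if (nrow(truth$rares) == 0) 1 else mean(rare_found),
    class_accuracy = if (any(rare_found))
      mean(pred_class[rare_found] == truth$rares$element_class[rare_found])
    else NA_real_,
    class_confusion = confusion,
    empty_prediction = empty
  )
}
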