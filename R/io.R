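#' Readers and writers for pipeline inputs and outputs
#'
#' Peak, expression, gene, and TAD tables are TSV/BED with 0-based
#' half-open coordinates; genome and ortholog-window sequences are FASTA.
#' All readers validate and fail hard on malformed rows, reporting line
#' numbers, rather than silently coercing.
#'
#' @name io_formats
NULL

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

check_numeric_column <- function(raw, parsed, col, path) {
  bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
  if (length(bad) > 0) {
    stop("file '", path, "': non-numeric ", col, " at data line ", bad[1],
         " ('", raw[bad[1]], "')", call. = FALSE)
  }
  invisible(TRUE)
}

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Read a differential peak table
#'
#' @param path TSV with header columns `chrom`, `start`, `end`, `log2fc`,
#'   `pvalue` and optionally `bh_p`; coordinates 0-based half-open;
#'   `log2fc` is mark signal KO vs WT.
#' @param mark The histone mark of the file: "H3K27ac" or "H3K27me3".
#' @param quiet Suppress the record-count message. Default `FALSE`.
#' @return A tibble of peaks in file order with columns `chrom`, `start`,
#'   `end`, `mark`, `log2fc`, `pvalue`, `bh_p` (NA when absent from the
#'   file) and a `peak_id` region string.
#' @export
read_diff_peaks <- function(path, mark = c("H3K27ac", "H3K27me3"),
                            quiet = FALSE) {
  mark <- match.arg(mark)
  raw <- read_tsv_quiet(path)
  require_columns(raw, c("chrom", "start", "end", "log2fc", "pvalue"), path)
  out <- tibble::tibble(
    chrom = raw$chrom,
    start = suppressWarnings(as.numeric(raw$start)),
    end = suppressWarnings(as.numeric(raw$end)),
    mark = mark,
    log2fc = suppressWarnings(as.numeric(raw$log2fc)),
    pvalue = suppressWarnings(as.numeric(raw$pvalue)),
    bh_p = if ("bh_p" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$bh_p))
    } else {
      NA_real_
    }
  )
  for (col in c("start", "end", "log2fc", "pvalue")) {
    check_numeric_column(raw[[col]], out[[col]], col, path)
  }
  if (nrow(out) > 0) {
    bad <- which(out$start >= out$end)
    if (length(bad) > 0) {
      stop("file '", path, "': start >= end at data line ", bad[1],
           call. = FALSE)
    }
    if (any(out$pvalue < 0 | out$pvalue > 1, na.rm = TRUE)) {
      stop("file '", path, "': pvalue outside [0,1]", call. = FALSE)
    }
    out$peak_id <- format_region(out$chrom, out$start, out$end)
    out$peak_id <- paste0(mark, ":", out$peak_id)
  } else {
    out$peak_id <- character(0)
  }
  if (!quiet) {
    message("read ", nrow(out), " ", mark, " peaks from '", path, "'",
            if (all(is.na(out$bh_p))) "" else " (externally adjusted bh_p)")
  }
  out
}

#' Read a differential expression table
#'
#' @param path TSV with header columns `gene_id`, `log2fc`, `fpkm_wt`,
#'   `fpkm_ko`; `log2fc` is expression KO vs WT.
#' @param quiet Suppress the record-count message. Default `FALSE`.
#' @return A tibble with one row per gene. Duplicate `gene_id` is an error.
#' @export
read_diff_expr <- function(path, quiet = FALSE) {
  raw <- read_tsv_quiet(path)
  require_columns(raw, c("gene_id", "log2fc", "fpkm_wt", "fpkm_ko"), path)
  out <- tibble::tibble(
    gene_id = raw$gene_id,
    log2fc = suppressWarnings(as.numeric(raw$log2fc)),
    fpkm_wt = suppressWarnings(as.numeric(raw$fpkm_wt)),
    fpkm_ko = suppressWarnings(as.numeric(raw$fpkm_ko))
  )
  for (col in c("log2fc", "fpkm_wt", "fpkm_ko")) {
    check_numeric_column(raw[[col]], out[[col]], col, path)
  }
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup) > 0) {
    stop("file '", path, "': duplicate gene_id: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(out$fpkm_wt < 0 | out$fpkm_ko < 0, na.rm = TRUE)) {
    stop("file '", path, "': negative FPKM", call. = FALSE)
  }
  if (!quiet) message("read ", nrow(out), " genes from '", path, "'")
  out
}

#' Read a genome FASTA
#'
#' @param path FASTA file. Record names are taken up to the first
#'   whitespace; sequences are uppercased.
#' @return Named character vector, one element per chromosome.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: '", path, "'", call. = FALSE)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate record name in '", path, "': ",
         nm[duplicated(nm)][1], call. = FALSE)
  }
  stats::setNames(toupper(as.character(seqs)), nm)
}

#' Read a BED6 gene annotation
#'
#' @param path BED6: chrom, start, end, gene_id, score, strand. The TSS is
#'   `start` for plus-strand genes and `end - 1` for minus-strand genes.
#' @return A tibble with columns `chrom`, `start`, `end`, `gene_id`,
#'   `strand`, `tss`.
#' @export
read_gene_bed <- function(path) {
  raw <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "gene_id", "score", "strand"),
    col_types = "cnnccc", progress = FALSE)
  if (any(is.na(raw$strand) | !raw$strand %in% c("+", "-"))) {
    bad <- which(is.na(raw$strand) | !raw$strand %in% c("+", "-"))[1]
    stop("file '", path, "': gene without valid strand at data line ", bad,
         call. = FALSE)
  }
  validate_intervals(raw$chrom, raw$start, raw$end, "gene")
  tibble::tibble(
    chrom = raw$chrom, start = raw$start, end = raw$end,
    gene_id = raw$gene_id, strand = raw$strand,
    tss = as.integer(ifelse(raw$strand == "+", raw$start, raw$end - 1))
  )
}

#' Read a BED TAD annotation
#'
#' @param path BED3+name: chrom, start, end, optional tad_id. TADs on one
#'   chromosome must not overlap.
#' @return A tibble with columns `chrom`, `start`, `end`, `tad_id`.
#' @export
read_tad_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  n_col <- length(strsplit(first, "\t")[[1]])
  if (n_col >= 4) {
    raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "tad_id"),
                           col_types = "cnnc", progress = FALSE)
  } else {
    raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                           col_types = "cnn", progress = FALSE)
    raw$tad_id <- paste0("tad_", seq_len(nrow(raw)))
  }
  validate_intervals(raw$chrom, raw$start, raw$end, "TAD")
  validate_tads(raw)
  tibble::as_tibble(raw)
}

validate_tads <- function(tads) {
  by_chrom <- split(tads, tads$chrom)
  for (tt in by_chrom) {
    tt <- tt[order(tt$start), ]
    if (nrow(tt) > 1) {
      ov <- which(tt$start[-1] < tt$end[-nrow(tt)])
      if (length(ov) > 0) {
        i <- ov[1]
        stop("overlapping TADs: ",
             format_region(tt$chrom[i], tt$start[i], tt$end[i]), " and ",
             format_region(tt$chrom[i + 1], tt$start[i + 1], tt$end[i + 1]),
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Load the packaged conserved-RARE fixture
#'
#' A verbatim transcription of the published table of 24 highly conserved
#' RAREs: printed sequence (half-sites and spacer separated by spaces),
#' DR type, mm10 coordinates, nearest regulated gene, other regulated
#' genes in the same TAD, enhancer/silencer section, and per-clade
#' conservation flags.
#'
#' @return A tibble with 24 rows: `nearest_gene`, `tad_genes` (list column
#'   of character vectors), `sequence_printed`, `motif_type`,
#'   `element_class`, `conserved_rodent` .. `conserved_fish` (logical),
#'   `region`, `chrom`, `start`, `end` (0-based half-open).
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "conserved_rares.tsv", package = "raretarget")
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  flags <- paste0("conserved_", c("rodent", "human", "bird", "reptile",
                                  "frog", "fish"))
  out <- tibble::tibble(
    nearest_gene = raw$nearest_gene,
    tad_genes = purrr::map(raw$tad_genes, function(x) {
      if (is.na(x) || x == "" || tolower(x) == "none") character(0)
      else stringr::str_trim(strsplit(x, ",")[[1]])
    }),
    sequence_printed = raw$sequence,
    motif_type = raw$motif_type,
    element_class = raw$element_class,
    region = raw$region
  )
  for (f in flags) out[[f]] <- raw[[f]] == "1"
  coords <- parse_region(out$region)
  out$chrom <- coords$chrom
  out$start <- coords$start
  out$end <- coords$end

  # integrity checks: row count, printed spacer consistent with type,
  # printed sequence length equal to interval length
  if (nrow(out) != 24) {
    stop("conserved-RARE fixture corrupted: expected 24 rows, found ",
         nrow(out), call. = FALSE)
  }
  cls <- classify_printed_rare(out$sequence_printed)
  if (!identical(cls$motif_type, out$motif_type)) {
    stop("conserved-RARE fixture corrupted: spacer/type mismatch",
         call. = FALSE)
  }
  if (!all(nchar(cls$sequence) == out$end - out$start)) {
    stop("conserved-RARE fixture corrupted: sequence/interval length mismatch",
         call. = FALSE)
  }
  out
}

#' Load the packaged differential-peak worked example
#'
#' Transcribes the published table comparing RA-regulated H3K27ac and
#' H3K27me3 peaks (mm10, KO vs WT log2 fold changes) with the expression
#' change of the nearby gene: 16 H3K27ac rows and 11 H3K27me3 rows.
#'
#' @return A tibble with columns `mark`, `region`, `chrom`, `start`, `end`,
#'   `mark_log2fc`, `rare_types` (list column), `gene_id`, `rna_log2fc`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "differential_peak_examples.tsv",
                      package = "raretarget")
  raw <- readr::read_tsv(path, col_types = "ccdccd", progress = FALSE)
  coords <- parse_region(raw$region)
  out <- tibble::tibble(
    mark = raw$mark,
    region = raw$region,
    chrom = coords$chrom, start = coords$start, end = coords$end,
    mark_log2fc = raw$mark_log2fc,
    rare_types = purrr::map(raw$rare_types, function(x) {
      if (is.na(x) || x == "-") character(0)
      else stringr::str_trim(strsplit(x, ",")[[1]])
    }),
    gene_id = raw$gene_id,
    rna_log2fc = raw$rna_log2fc
  )
  if (nrow(out) != 27) {
    stop("differential-peak fixture corrupted: expected 27 rows, found ",
         nrow(out), call. = FALSE)
  }
  out
}

#' Write the candidate-target table
#'
#' One row per gene x peak x RARE (peaks without RAREs still get one row
#' with empty RARE fields). Rows are ordered deterministically by
#' (chrom, start, gene_id, RARE start) so identical inputs give
#' byte-identical files.
#'
#' @param candidates A candidate table as returned by [build_candidates()]
#'   or [run_ra_pipeline()]`$candidates`.
#' @param path Output TSV path.
#' @return The written tibble, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  cols <- c("gene_id", "direction", "mark", "peak_region", "peak_log2fc",
            "link_type", "distance", "concordant", "rare_type",
            "rare_region", "rare_strand", "rare_mismatches",
            "element_class", "conserved_to")
  out <- candidates
  for (col in setdiff(cols, names(out))) out[[col]] <- NA
  out <- out[, cols]
  coords <- parse_region(out$peak_region)
  ord <- order(coords$chrom, coords$start, out$gene_id,
               out$rare_region, method = "radix")
  out <- out[ord, ]
  readr::write_tsv(out, path, na = "")
  invisible(out)
}

#' Read back a candidate-target table
#'
#' @param path TSV written by [write_candidate_table()].
#' @return A tibble with the same columns.
#' @export
read_candidate_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", direction = "c", mark = "c", peak_region = "c",
    peak_log2fc = "d", link_type = "c", distance = "d", concordant = "l",
    rare_type = "c", rare_region = "c", rare_strand = "c",
    rare_mismatches = "d", element_class = "c", conserved_to = "c"
  ), na = "", progress = FALSE)
}

#' Read per-species ortholog windows
#'
#' One FASTA per clade; record IDs are RARE identifiers
#' "chrom:start-end:type" (1-based inclusive region string plus DR type).
#'
#' @param paths Named character vector of FASTA paths, names are clades.
#' @return Named list (clade) of named character vectors (RARE id ->
#'   window sequence).
#' @export
read_ortholog_windows <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    stop("ortholog window paths must be named by clade", call. = FALSE)
  }
  lapply(paths, function(p) {
    seqs <- Biostrings::readBStringSet(p)
    stats::setNames(toupper(as.character(seqs)), sub("\\s.*$", "", names(seqs)))
  })
}
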