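#' DR1/DR2/DR5 RARE scanning by consensus half-site matching
#'
#' A retinoic acid response element (RARE) is a direct repeat of two 6-bp
#' nuclear-receptor half-sites separated by a 1, 2, or 5 bp spacer (DR1,
#' DR2, DR5). The scanner matches both half-sites of every candidate
#' window, on both strands, against an IUPAC half-site consensus (default
#' RGKTCA) and counts mismatched positions; the spacer is unconstrained.
#' A window is reported when the total mismatch count over the 12
#' half-site positions is within tolerance.
#'
#' @name rare_scanner
NULL

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

consensus_sets <- function(consensus) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  unknown <- setdiff(letters, names(IUPAC_SETS))
  if (length(unknown) > 0) {
    stop("consensus contains non-IUPAC letters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lapply(letters, function(l) IUPAC_SETS[[l]])
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chars <- function(chars) {
  unname(rev(COMPLEMENT[chars]))
}

#' Count half-site mismatches against the consensus
#'
#' Positions failing the IUPAC class of the consensus count as mismatches;
#' `N` in the sequence never matches.
#'
#' @param six_mer Character vector of 6-letter DNA strings (ACGTN).
#' @param consensus 6-letter IUPAC consensus, default "RGKTCA".
#' @return Integer vector of mismatch counts in 0..6.
#' @examples
#' count_halfsite_mismatches("GGGTCA") # 0
#' count_halfsite_mismatches("GGGTTA") # 1
#' @export
count_halfsite_mismatches <- function(six_mer, consensus = "RGKTCA") {
  six_mer <- toupper(six_mer)
  if (any(nchar(six_mer) != 6)) {
    stop("half-site must be exactly 6 letters", call. = FALSE)
  }
  sets <- consensus_sets(consensus)
  if (length(sets) != 6) stop("consensus must be 6 letters", call. = FALSE)
  vapply(strsplit(six_mer, ""), function(ch) {
    sum(vapply(seq_len(6), function(j) !(ch[j] %in% sets[[j]]), logical(1)))
  }, integer(1))
}

# Mismatch count of every 6-mer window of a character vector; entry i is
# the mismatch count of the window starting at position i (1-based).
halfsite_profile <- function(chars, sets) {
  L <- length(chars)
  n <- L - 5L
  if (n < 1) return(integer(0))
  mism <- matrix(TRUE, nrow = n, ncol = 6)
  for (j in 1:6) {
    mism[, j] <- !(chars[j:(j + n - 1L)] %in% sets[[j]])
  }
  as.integer(rowSums(mism))
}

scan_one_strand <- function(chars, sets, tol, spacers) {
  L <- length(chars)
  mm <- halfsite_profile(chars, sets)
  out <- vector("list", length(spacers))
  for (k in seq_along(spacers)) {
    s <- spacers[k]
    w <- 12L + s
    n <- L - w + 1L
    if (n < 1) next
    i <- seq_len(n)
    total <- mm[i] + mm[i + 6L + s]
    hit <- which(total <= tol)
    if (length(hit) == 0) next
    out[[k]] <- tibble::tibble(
      offset0 = hit - 1L,           # 0-based offset of window start
      spacer = s,
      mismatches = total[hit]
    )
  }
  dplyr::bind_rows(out)
}

#' Scan a DNA sequence for DR1/DR2/DR5 RAREs
#'
#' Every (offset, spacer, strand) window whose two half-sites together have
#' at most `tol` mismatches to the consensus is reported. Minus-strand
#' matches are reported in genomic (plus-strand) coordinates with the
#' matched sequence read off the minus strand. Matches are sorted by
#' (start, motif_type, strand).
#'
#' @param seq A single DNA string (letters ACGTN; case-insensitive).
#' @param chrom Chromosome name for output coordinates. Default "seq".
#' @param origin_start 0-based genomic position of the first letter of
#'   `seq`. Default 0.
#' @param tol Maximum total half-site mismatches. Default 2.
#' @param consensus 6-letter IUPAC half-site consensus. Default "RGKTCA".
#' @param spacers Spacer lengths to scan, named by motif type. Default
#'   DR1/DR2/DR5.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `motif_type`, `spacer`, `mismatches`,
#'   `sequence`.
#' @examples
#' scan_rares("GGTTCACCGAAAGTTCA", tol = 1) # one perfect DR5
#' @export
scan_rares <- function(seq, chrom = "seq", origin_start = 0, tol = 2L,
                       consensus = "RGKTCA", spacers = MOTIF_SPACERS) {
  stopifnot(length(seq) == 1)
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    stop("sequence contains letters other than ACGTN: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sets <- consensus_sets(consensus)
  L <- length(chars)

  plus <- scan_one_strand(chars, sets, tol, spacers)
  if (nrow(plus) > 0) plus$strand <- "+"
  minus <- scan_one_strand(revcomp_chars(chars), sets, tol, spacers)
  if (nrow(minus) > 0) {
    # window at offset i (0-based) in the reverse complement starts, in
    # plus-strand coordinates, at L - i - width
    minus$offset0 <- L - minus$offset0 - (12L + minus$spacer)
    minus$strand <- "-"
  }
  hits <- dplyr::bind_rows(plus, minus)
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), motif_type = character(), spacer = integer(),
      mismatches = integer(), sequence = character()
    ))
  }
  width <- 12L + hits$spacer
  fwd <- substring(seq, hits$offset0 + 1L, hits$offset0 + width)
  matched <- ifelse(
    hits$strand == "+", fwd,
    vapply(fwd, function(x) paste(revcomp_chars(strsplit(x, "")[[1]]),
                                  collapse = ""), character(1))
  )
  type_by_spacer <- stats::setNames(names(spacers), as.character(spacers))
  out <- tibble::tibble(
    chrom = chrom,
    start = as.integer(origin_start + hits$offset0),
    end = as.integer(origin_start + hits$offset0 + width),
    strand = hits$strand,
    motif_type = unname(type_by_spacer[as.character(hits$spacer)]),
    spacer = as.integer(hits$spacer),
    mismatches = as.integer(hits$mismatches),
    sequence = unname(matched)
  )
  dplyr::arrange(out, .data$start, .data$motif_type, .data$strand)
}

#' Classify a printed RARE sequence
#'
#' Printed RAREs are written "HALFSITE SPACER HALFSITE" with single spaces.
#' The motif type follows from the spacer length (1/2/5 bp) and mismatches
#' are summed over both half-sites against the consensus.
#'
#' @param printed Character vector of spaced RARE strings, e.g.
#'   `"GGTTCA CCGAA AGTTCA"`.
#' @param consensus Half-site consensus, default "RGKTCA".
#' @return A tibble with columns `sequence` (unspaced), `motif_type`,
#'   `spacer`, `mismatches`.
#' @examples
#' classify_printed_rare("GTGTCA A AGTTCA") # DR1, 1 mismatch
#' @export
classify_printed_rare <- function(printed, consensus = "RGKTCA") {
  parts <- stringr::str_split(stringr::str_trim(printed), "\\s+")
  purrr::map_dfr(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) != 3 || nchar(p[1]) != 6 || nchar(p[3]) != 6) {
      stop("printed RARE must be 'HALF SPACER HALF': '", printed[i], "'",
           call. = FALSE)
    }
    sp <- nchar(p[2])
    if (!sp %in% MOTIF_SPACERS) {
      stop("spacer length ", sp, " is not a DR1/DR2/DR5 spacer: '",
           printed[i], "'", call. = FALSE)
    }
    tibble::tibble(
      sequence = paste0(p, collapse = ""),
      motif_type = names(MOTIF_SPACERS)[MOTIF_SPACERS == sp],
      spacer = as.integer(sp),
      mismatches = count_halfsite_mismatches(p[1], consensus) +
        count_halfsite_mismatches(p[3], consensus)
    )
  })
}

#' Scan peak sequences for RAREs
#'
#' Extracts each peak's genomic sequence and scans it; output coordinates
#' are genomic. Peaks extending past the chromosome end are an error.
#'
#' @param peaks A tibble of peaks with columns `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `peak_id` (carried through).
#' @param genome Named character vector of chromosome sequences, as from
#'   [read_genome_fasta()].
#' @param tol Maximum total half-site mismatches. Default 2.
#' @param consensus Half-site consensus, default "RGKTCA".
#' @return A tibble of RARE matches (see [scan_rares()]) with a `peak_id`
#'   column identifying the source peak.
#' @export
scan_peaks <- function(peaks, genome, tol = 2L, consensus = "RGKTCA") {
  if (nrow(peaks) == 0) {
    empty <- scan_rares("", tol = tol, consensus = consensus)
    return(dplyr::mutate(empty, peak_id = character()))
  }
  validate_intervals(peaks$chrom, peaks$start, peaks$end, "peak")
  if (!"peak_id" %in% names(peaks)) {
    peaks <- dplyr::mutate(peaks,
      peak_id = format_region(.data$chrom, .data$start, .data$end))
  }
  missing_chrom <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    stop("peaks on chromosomes absent from genome: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  too_long <- peaks$end > nchar(genome[peaks$chrom])
  if (any(too_long)) {
    stop("peak beyond chromosome end: ",
         format_region(peaks$chrom[too_long][1], peaks$start[too_long][1],
                       peaks$end[too_long][1]), call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    seq <- substring(genome[[p$chrom]], p$start + 1, p$end)
    hits <- scan_rares(seq, chrom = p$chrom, origin_start = p$start,
                       tol = tol, consensus = consensus)
    if (nrow(hits) > 0) hits$peak_id <- p$peak_id else hits$peak_id <- character(0)
    hits
  })
}
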