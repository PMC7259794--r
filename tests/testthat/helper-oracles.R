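# Independent oracles and small fixture builders used across tests.
# Deliberately written with different primitives than the package code
# (substr/chartr loops rather than vectorised profiles) so agreement is
# meaningful.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

oracle_halfsite_mm <- function(six, consensus = "RGKTCA") {
  cons <- strsplit(consensus, "")[[1]]
  ch <- strsplit(six, "")[[1]]
  mm <- 0L
  for (j in 1:6) {
    if (!(ch[j] %in% IUPAC_ORACLE[[cons[j]]])) mm <- mm + 1L
  }
  mm
}

# brute-force enumeration of every (offset, spacer, strand) triple
oracle_scan_rares <- function(seq, tol, consensus = "RGKTCA") {
  L <- nchar(seq)
  spacers <- c(DR1 = 1L, DR2 = 2L, DR5 = 5L)
  rows <- list()
  for (strand in c("+", "-")) {
    x <- if (strand == "+") seq else oracle_revcomp(seq)
    for (ti in seq_along(spacers)) {
      s <- spacers[[ti]]
      w <- 12L + s
      if (L < w) next
      for (i in seq_len(L - w + 1L)) {
        h1 <- substr(x, i, i + 5L)
        h2 <- substr(x, i + 6L + s, i + 11L + s)
        mm <- oracle_halfsite_mm(h1, consensus) +
          oracle_halfsite_mm(h2, consensus)
        if (mm <= tol) {
          start0 <- if (strand == "+") i - 1L else L - i - w + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            start = start0, end = start0 + w, strand = strand,
            motif_type = names(spacers)[ti], spacer = s, mismatches = mm,
            sequence = substr(x, i, i + w - 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), motif_type = character(),
                      spacer = integer(), mismatches = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$motif_type, out$strand), , drop = FALSE]
}

# literal step-up definition: adjusted_i = min over sorted ranks j with
# p_(j) >= p_i of p_(j) * n / j, capped at 1
oracle_bh <- function(p) {
  n <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    j <- which(ps >= pi)
    min(1, min(ps[j] * n / j))
  }, numeric(1))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# compare package scan output with the oracle on one sequence
expect_scan_matches_oracle <- function(seq, tol) {
  got <- as.data.frame(scan_rares(seq, tol = tol))
  got <- got[, c("start", "end", "strand", "motif_type", "spacer",
                 "mismatches", "sequence")]
  want <- oracle_scan_rares(seq, tol)
  rownames(got) <- NULL
  rownames(want) <- NULL
  # oracle reports the minus-strand sequence as read on the minus strand,
  # same convention as the scanner
  expect_equal(got, want, ignore_attr = TRUE,
               label = paste0("scan of '", seq, "' tol ", tol))
}

make_gene_tbl <- function(chrom, tss, gene_id, strand = "+") {
  tibble::tibble(
    chrom = chrom,
    start = ifelse(strand == "+", tss, pmax(0, tss - 999)),
    end = ifelse(strand == "+", tss + 1000, tss + 1),
    gene_id = gene_id, strand = strand, tss = as.integer(tss))
}

make_peak_tbl <- function(chrom, start, end, mark = "H3K27ac",
                          log2fc = -1, pvalue = 1e-6, bh_p = 1e-6) {
  tibble::tibble(
    chrom = chrom, start = start, end = end, mark = mark,
    log2fc = log2fc, pvalue = pvalue, bh_p = bh_p,
    peak_id = paste0(mark, ":", format_region(chrom, start, end)))
}
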