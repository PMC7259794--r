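test_that("half-site mismatch counting follows the IUPAC consensus", {
  expect_equal(count_halfsite_mismatches("GGGTCA"), 0L)
  expect_equal(count_halfsite_mismatches("AGTTCA"), 0L)
  expect_equal(count_halfsite_mismatches("GGGTTA"), 1L)
  expect_equal(count_halfsite_mismatches("GTGTCA"), 1L)
  expect_equal(count_halfsite_mismatches("NNNNNN"), 6L)
  expect_equal(count_halfsite_mismatches(c("GGTTCA", "AGGTCA")), c(0L, 0L))
  expect_error(count_halfsite_mismatches("GGGTC"), "6 letters")
  # a stricter literal consensus counts the degenerate positions
  expect_equal(count_halfsite_mismatches("GGTTCA", "AGGTCA"), 2L)
})

test_that("scanner finds the printed worked-example motifs", {
  # perfect DR5 spanning the whole 17 bp
  hox <- scan_rares("GGTTCACCGAAAGTTCA", tol = 1)
  expect_equal(nrow(hox), 1)
  expect_equal(hox$motif_type, "DR5")
  expect_equal(hox$strand, "+")
  expect_equal(hox$mismatches, 0L)
  expect_equal(hox$start, 0L)
  expect_equal(hox$end, 17L)

  # DR1 with one mismatch in the first half-site
  nr2f1 <- scan_rares("GTGTCAAAGTTCA", tol = 1)
  expect_equal(nrow(nr2f1), 1)
  expect_equal(nr2f1$motif_type, "DR1")
  expect_equal(nr2f1$mismatches, 1L)
  # and it disappears at tolerance 0
  expect_equal(nrow(scan_rares("GTGTCAAAGTTCA", tol = 0)), 0)

  # strand symmetry: the reverse complement is found on the minus strand
  fwd <- "GGGTCAGAAGGTCA"
  rc <- oracle_revcomp(fwd)
  hit_fwd <- scan_rares(fwd, tol = 1)
  hit_rc <- scan_rares(rc, tol = 1)
  expect_equal(nrow(hit_fwd), nrow(hit_rc))
  expect_true(any(hit_rc$strand == "-" & hit_rc$motif_type == "DR2" &
                    hit_rc$mismatches == min(hit_fwd$mismatches)))
  expect_true("GGGTCAGAAGGTCA" %in% hit_rc$sequence)

  expect_equal(nrow(scan_rares(strrep("A", 17), tol = 1)), 0)
  expect_equal(nrow(scan_rares("", tol = 2)), 0)
  expect_error(scan_rares("ACGTX"), "ACGTN")
})

test_that("genomic coordinates are offset by the scan origin", {
  hit <- scan_rares("GGTTCACCGAAAGTTCA", chrom = "chr6",
                    origin_start = 52153425, tol = 1)
  expect_equal(format_region(hit$chrom, hit$start, hit$end),
               "chr6:52153426-52153442")
})

test_that("scanner equals the brute-force enumerator on random sequences", {
  set.seed(404)
  for (i in 1:400) {
    len <- sample(13:40, 1)
    tol <- sample(0:2, 1)
    expect_scan_matches_oracle(random_dna(len), tol)
  }
  # sequences enriched for half-sites to exercise overlapping hits
  for (i in 1:100) {
    seq <- paste0(random_dna(5), "GGGTCA", random_dna(sample(1:6, 1)),
                  "AGTTCA", random_dna(5))
    expect_scan_matches_oracle(seq, sample(0:2, 1))
  }
})

test_that("match sets grow monotonically with tolerance", {
  set.seed(505)
  key <- function(h) paste(h$start, h$motif_type, h$strand)
  for (i in 1:50) {
    seq <- random_dna(60)
    prev <- scan_rares(seq, tol = 0)
    for (tol in 1:3) {
      cur <- scan_rares(seq, tol = tol)
      expect_true(all(key(prev) %in% key(cur)))
      prev <- cur
    }
  }
})

test_that("every printed conserved RARE classifies as its printed type", {
  fx <- load_table2_fixture()
  cls <- classify_printed_rare(fx$sequence_printed)
  expect_identical(cls$motif_type, fx$motif_type)
  expect_true(all(cls$mismatches <= 1))
  # the classifier rejects malformed printed strings
  expect_error(classify_printed_rare("GGGTCA ABC"), "HALF SPACER HALF")
  expect_error(classify_printed_rare("GGGTCA ACG AGGTCA"), "spacer length")
})

test_that("peak scanning reports planted motifs at genomic coordinates", {
  set.seed(606)
  left <- strrep("A", 40)
  rare <- "GGGTCAGGAGGTCA" # perfect DR2
  genome <- c(chr9 = paste0(left, rare, strrep("A", 46)))
  peak <- make_peak_tbl("chr9", 10, 90)
  hits <- scan_peaks(peak, genome, tol = 1)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 40L)
  expect_equal(hits$end, 54L)
  expect_equal(hits$motif_type, "DR2")
  expect_equal(hits$peak_id, peak$peak_id)

  none <- scan_peaks(make_peak_tbl("chr9", 0, 30), genome, tol = 1)
  expect_equal(nrow(none), 0)

  beyond <- make_peak_tbl("chr9", 50, 500)
  expect_error(scan_peaks(beyond, genome), "beyond chromosome end")
})
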