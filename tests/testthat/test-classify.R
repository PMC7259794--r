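test_that("element class follows the gene's regulation direction", {
  expect_equal(classify_element("RA_activated"), "enhancer")
  expect_equal(classify_element("RA_repressed"), "silencer")
  expect_equal(classify_element(c("RA_activated", "RA_repressed")),
               c("enhancer", "silencer"))
  expect_error(classify_element("up"), "direction")
})

test_that("mark concordance covers the full sign table", {
  grid <- expand.grid(mark = c("H3K27ac", "H3K27me3"),
                      lfc = c(-1, 1),
                      direction = c("RA_activated", "RA_repressed"),
                      stringsAsFactors = FALSE)
  got <- mark_concordance(grid$mark, grid$lfc, grid$direction)
  # concordant: activated genes lose H3K27ac / gain H3K27me3 in the KO;
  # repressed genes the reverse
  want <- with(grid,
    (direction == "RA_activated" & ((mark == "H3K27ac" & lfc < 0) |
                                      (mark == "H3K27me3" & lfc > 0))) |
    (direction == "RA_repressed" & ((mark == "H3K27ac" & lfc > 0) |
                                      (mark == "H3K27me3" & lfc < 0))))
  expect_identical(got, want)
  expect_equal(sum(got), 4)
  # worked examples
  expect_true(mark_concordance("H3K27me3", 1.02, "RA_activated"))
  expect_true(mark_concordance("H3K27ac", 0.53, "RA_repressed"))
  expect_false(mark_concordance("H3K27ac", 0.53, "RA_activated"))
})

test_that("every row of the packaged worked example is concordant", {
  fx <- load_table1_fixture()
  direction <- ifelse(fx$rna_log2fc < 0, "RA_activated", "RA_repressed")
  expect_true(all(mark_concordance(fx$mark, fx$mark_log2fc, direction)))
  silencer_genes <- unique(fx$gene_id[classify_element(direction) == "silencer"])
  expect_setequal(silencer_genes, c("Fgf8", "Fst", "Cdx2", "Spry4"))
  enhancer_genes <- unique(fx$gene_id[classify_element(direction) == "enhancer"])
  expect_false(any(enhancer_genes %in% silencer_genes))
})

test_that("candidates require both a significant peak link and a DE gene", {
  genes <- make_gene_tbl("chr1", c(1000, 30000, 60000),
                         c("Rarb", "noDE", "farDE"))
  # Rarb-like pattern: peaks for both marks near the same activated gene
  peaks <- dplyr::bind_rows(
    make_peak_tbl("chr1", 500, 1500, "H3K27ac", log2fc = -0.63),
    make_peak_tbl("chr1", 800, 1800, "H3K27me3", log2fc = 1.02),
    make_peak_tbl("chr1", 29500, 30500, "H3K27ac", log2fc = -2))
  de <- tibble::tibble(gene_id = c("Rarb", "farDE"),
                       direction = c("RA_activated", "RA_activated"))
  links <- nearest_gene(peaks, genes, quiet = TRUE)
  cand <- build_candidates(peaks, de, links)
  # one target gene with links for both marks
  expect_setequal(cand$gene_id, "Rarb")
  expect_setequal(cand$mark, c("H3K27ac", "H3K27me3"))
  expect_true(all(cand$concordant))
  # the noDE-linked peak contributes nothing; farDE has no linked peak
  expect_false("noDE" %in% cand$gene_id)
  expect_false("farDE" %in% cand$gene_id)
})

test_that("RAREs attach only when they overlap the linked peak", {
  genes <- make_gene_tbl("chr1", 1000, "g1")
  peaks <- make_peak_tbl("chr1", 500, 1500, log2fc = -1)
  de <- tibble::tibble(gene_id = "g1", direction = "RA_activated")
  links <- nearest_gene(peaks, genes, quiet = TRUE)
  rares <- tibble::tibble(
    peak_id = peaks$peak_id,
    chrom = "chr1",
    start = c(600L, 1494L, 2000L),
    end = c(614L, 1508L, 2014L),
    strand = "+", motif_type = "DR2", mismatches = 0L,
    sequence = "GGGTCAGGAGGTCA")
  cand <- build_candidates(peaks, de, links, rares)
  # inside and edge-overlapping attach; the far one does not
  expect_setequal(cand$rare_region[!is.na(cand$rare_region)],
                  c("chr1:601-614", "chr1:1495-1508"))
  expect_true(all(cand$element_class[!is.na(cand$rare_type)] == "enhancer"))

  strict <- build_candidates(peaks, de, links, rares,
                             pipeline_config(strict_containment = TRUE))
  expect_equal(strict$rare_region[!is.na(strict$rare_region)],
               "chr1:601-614")

  # attached RAREs always overlap a linked peak (invariant)
  with_rare <- cand[!is.na(cand$rare_region), ]
  rr <- parse_region(with_rare$rare_region)
  pr <- parse_region(with_rare$peak_region)
  expect_true(all(interval_overlap(rr, pr) > 0))
})

test_that("summary counts use set-union semantics over genes", {
  expect_equal(union_gene_count(c("a", "b"), c("c", "d", "e")), 5)
  expect_equal(union_gene_count(c("a", "b"), c("a", "b")), 2)
  expect_equal(union_gene_count(character(0), "a"), 1)

  genes <- make_gene_tbl("chr1", c(1000, 30000), c("g1", "g2"))
  peaks <- dplyr::bind_rows(
    make_peak_tbl("chr1", 500, 1500, "H3K27ac", log2fc = -1),
    make_peak_tbl("chr1", 29500, 30500, "H3K27me3", log2fc = 1))
  de <- tibble::tibble(gene_id = c("g1", "g2"), direction = "RA_activated")
  cand <- build_candidates(peaks, de,
                           nearest_gene(peaks, genes, quiet = TRUE))
  s <- summarize_candidates(cand)
  expect_equal(s$n_genes_k27ac, 1)
  expect_equal(s$n_genes_k27me3, 1)
  expect_equal(s$n_genes_union, 2)
  expect_equal(s$n_genes_with_rare, 0)
  # idempotent and order-invariant
  expect_identical(summarize_candidates(cand[sample(nrow(cand)), ]), s)
})
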