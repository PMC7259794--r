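test_that("nearest gene minimises midpoint-to-TSS distance with ties by id", {
  peak <- make_peak_tbl("chr1", 100, 200)
  genes <- make_gene_tbl("chr1", c(150, 400), c("gA", "gB"))
  link <- nearest_gene(peak, genes, quiet = TRUE)
  expect_equal(link$gene_id, "gA")
  expect_equal(link$distance, 1L)  # midpoint 149 vs TSS 150
  expect_equal(link$link_type, "nearest")

  tie <- make_gene_tbl("chr1", c(100, 198), c("zeta", "alpha"))
  expect_equal(nearest_gene(peak, tie, quiet = TRUE)$gene_id, "alpha")

  off <- make_gene_tbl("chr2", 100, "gC")
  expect_message(
    unassigned <- nearest_gene(peak, off),
    "unassigned")
  expect_true(is.na(unassigned$gene_id))
})

test_that("nearest gene equals the brute-force minimiser on random data", {
  set.seed(202)
  for (i in 1:50) {
    n_genes <- sample(2:30, 1)
    genes <- make_gene_tbl("chr1", sort(sample(0:100000, n_genes)),
                           sprintf("g%02d", sample(n_genes)))
    start <- sample(0:90000, 1)
    peak <- make_peak_tbl("chr1", start, start + sample(100:5000, 1))
    got <- nearest_gene(peak, genes, quiet = TRUE)
    mid <- interval_midpoint(peak$start, peak$end)
    d <- abs(mid - genes$tss)
    best <- genes$gene_id[d == min(d)]
    expect_equal(got$gene_id, sort(best)[1])
    expect_equal(got$distance, min(d))
    # permutation invariance
    got2 <- nearest_gene(peak, genes[sample(n_genes), ], quiet = TRUE)
    expect_identical(got2$gene_id, got$gene_id)
  }
})

test_that("TAD assignment uses midpoint containment with half-open bounds", {
  tads <- tibble::tibble(chrom = "chr1", start = c(0, 1000),
                         end = c(1000, 2000), tad_id = c("t1", "t2"))
  peak_in <- make_peak_tbl("chr1", 100, 200)      # midpoint 149
  expect_equal(assign_tad(peak_in, tads)$tad_id, "t1")
  # midpoint exactly at a TAD end belongs to the next TAD, not the first
  peak_edge <- make_peak_tbl("chr1", 951, 1052)   # midpoint 1001
  expect_equal(assign_tad(peak_edge, tads)$tad_id, "t2")
  peak_at_end <- make_peak_tbl("chr1", 1950, 2052) # midpoint 2000
  expect_true(is.na(assign_tad(peak_at_end, tads)$tad_id))
  peak_gap <- make_peak_tbl("chr2", 100, 200)
  expect_true(is.na(assign_tad(peak_gap, tads)$tad_id))
})

test_that("TAD links attach regulated genes and exclude the nearest gene", {
  tads <- tibble::tibble(chrom = "chr1", start = 0, end = 50000,
                         tad_id = "t1")
  genes <- make_gene_tbl("chr1", c(150, 10000, 20000, 30000, 60000),
                         c("Clstn1", "Lzic", "Nmnat1", "Kif1b", "outside"))
  peak <- make_peak_tbl("chr1", 100, 200)
  de <- tibble::tibble(
    gene_id = c("Clstn1", "Lzic", "Nmnat1", "Kif1b", "outside"),
    direction = "RA_activated")
  near <- nearest_gene(peak, genes, quiet = TRUE)
  tl <- tad_links(peak, tads, genes, de, nearest = near)
  expect_setequal(tl$gene_id, c("Lzic", "Nmnat1", "Kif1b"))
  expect_true(all(tl$link_type == "tad"))
  expect_true(all(tl$tad_id == "t1"))

  # TAD with no regulated genes -> no links
  tl2 <- tad_links(peak, tads, genes,
                   de[de$gene_id == "outside", ], nearest = near)
  expect_equal(nrow(tl2), 0)
  # only regulated gene is the nearest gene -> excluded
  tl3 <- tad_links(peak, tads, genes,
                   de[de$gene_id == "Clstn1", ], nearest = near)
  expect_equal(nrow(tl3), 0)
})

test_that("the nearest link is never farther than a same-TAD link to a TSS in the TAD", {
  set.seed(303)
  sim <- simulate_ra_inputs(simulation_params(n_genes = 120,
                                              n_true_targets = 20,
                                              n_null_peaks = 0, seed = 9))
  de <- filter_de_genes(sim$expr)
  peaks <- dplyr::bind_rows(
    filter_diff_peaks(sim$peaks_k27ac), filter_diff_peaks(sim$peaks_k27me3))
  links <- link_peaks_to_genes(peaks, sim$genes, de, sim$tads, quiet = TRUE)
  by_peak <- split(links, links$peak_id)
  for (lk in by_peak) {
    expect_lte(sum(lk$link_type == "nearest"), 1)
    if (any(lk$link_type == "nearest") && any(lk$link_type == "tad")) {
      expect_lte(min(lk$distance[lk$link_type == "nearest"]),
                 min(lk$distance[lk$link_type == "tad"]))
    }
  }
})
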