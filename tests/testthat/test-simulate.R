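small_params <- function(seed = 3, ...) {
  simulation_params(n_chroms = 2L, chrom_length = 3e5, n_genes = 60L,
                    n_tads_per_chrom = 8L, n_true_targets = 10L,
                    n_null_peaks = 30L, seed = seed, ...)
}

test_that("the generator is reproducible from the seed", {
  s1 <- simulate_ra_inputs(small_params())
  s2 <- simulate_ra_inputs(small_params())
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$truth$rares, s2$truth$rares)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulated_inputs(s1, d1)
  write_simulated_inputs(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  s3 <- simulate_ra_inputs(small_params(seed = 4))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("generated tables have the requested shape and structure", {
  sim <- simulate_ra_inputs(small_params())
  expect_equal(nrow(sim$genes), 60)
  expect_equal(nrow(sim$expr), 60)
  expect_equal(sum(sim$truth$genes$direction != "null"), 10)
  expect_equal(nrow(sim$tads), 16)
  # genes do not overlap within a chromosome
  for (ch in unique(sim$genes$chrom)) {
    g <- sim$genes[sim$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # true targets pass the expression filter by construction
  de <- filter_de_genes(sim$expr)
  true_ids <- sim$truth$genes$gene_id[sim$truth$genes$direction != "null"]
  expect_true(all(true_ids %in% de$gene_id))
  # written files round-trip through the package readers
  d <- withr::local_tempdir()
  write_simulated_inputs(sim, d)
  expect_equal(nrow(read_gene_bed(file.path(d, "genes.bed"))), 60)
  expect_equal(read_genome_fasta(file.path(d, "genome.fa")), sim$genome)
  pk <- read_diff_peaks(file.path(d, "peaks_H3K27ac.tsv"), "H3K27ac",
                        quiet = TRUE)
  expect_identical(pk$log2fc, sim$peaks_k27ac$log2fc)
})

test_that("every planted RARE is re-found at its exact coordinates", {
  sim <- simulate_ra_inputs(small_params(seed = 8))
  truth <- sim$truth$rares
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    peak <- sim$truth$peaks[sim$truth$peaks$gene_id == r$gene_id &
                              sim$truth$peaks$status == "true", ][1, ]
    hits <- scan_peaks(peak, sim$genome, tol = r$mismatches)
    planted <- hits[hits$start == r$start & hits$end == r$end &
                      hits$motif_type == r$motif_type, ]
    expect_gte(nrow(planted), 1)
    expect_true(any(planted$mismatches == r$mismatches))
  }
  # a RARE planted with 1 mismatch is invisible at tolerance 0
  one_mm <- truth[truth$mismatches == 1, ]
  if (nrow(one_mm) > 0) {
    r <- one_mm[1, ]
    peak <- sim$truth$peaks[sim$truth$peaks$gene_id == r$gene_id &
                              sim$truth$peaks$status == "true", ][1, ]
    hits0 <- scan_peaks(peak, sim$genome, tol = 0)
    expect_false(any(hits0$start == r$start & hits0$end == r$end &
                       hits0$motif_type == r$motif_type))
  }
})

test_that("a null-only simulation produces no candidate targets", {
  for (seed in 1:5) {
    sim <- simulate_ra_inputs(
      simulation_params(n_chroms = 2L, chrom_length = 2e5, n_genes = 40L,
                        n_tads_per_chrom = 6L, n_true_targets = 0L,
                        n_null_peaks = 60L, seed = seed))
    run <- run_ra_pipeline(sim$expr, sim$peaks_k27ac, sim$peaks_k27me3,
                           sim$genome, sim$genes, sim$tads, quiet = TRUE)
    expect_equal(nrow(run$candidates), 0)
    rep <- recovery_report(run, sim$truth)
    expect_equal(rep$gene_precision, 1)
    expect_true(rep$empty_prediction)
  }
})

test_that("recovery is perfect in the noiseless regime", {
  sim <- simulate_ra_inputs(small_params(seed = 12, null_sigma = 0.01))
  run <- run_ra_pipeline(sim$expr, sim$peaks_k27ac, sim$peaks_k27me3,
                         sim$genome, sim$genes, sim$tads,
                         sim$ortholog_windows, quiet = TRUE)
  rep <- recovery_report(run, sim$truth)
  expect_equal(rep$gene_recall, 1)
  expect_equal(rep$gene_precision, 1)
  expect_equal(rep$rare_recovery, 1)
  expect_equal(rep$class_accuracy, 1)
  expect_equal(sum(rep$class_confusion[, "missed"]), 0)
})
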