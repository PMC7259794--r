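test_that("conservation in a window means a same-type match within tolerance", {
  win <- paste0("ACGTAC", "GGTTCACCGAAAGTTCA", "TTACGT")
  expect_true(rare_conserved_in(win, "DR5", tol = 1))
  expect_false(rare_conserved_in(win, "DR2", tol = 1))
  expect_false(rare_conserved_in(strrep("A", 40), "DR5", tol = 1))
  expect_false(rare_conserved_in("----", "DR1", tol = 1))
  expect_false(rare_conserved_in(NA_character_, "DR1", tol = 1))
  # gaps are stripped before scanning
  expect_true(rare_conserved_in("GGTTCA--CCGAA--AGTTCA", "DR5", tol = 1))
  # a minus-strand occurrence counts
  expect_true(rare_conserved_in(oracle_revcomp(win), "DR5", tol = 1))
})

test_that("per-clade flags map windows to booleans", {
  rare <- "GGGTCAGGAGGTCA"
  windows <- list(rodent = paste0("TT", rare, "GG"),
                  human = paste0("CC", rare, "AA"),
                  bird = strrep("T", 30),
                  frog = paste0("AG", rare))
  flags <- conservation_flags("DR2", windows)
  expect_identical(
    flags,
    c(rodent = TRUE, human = TRUE, bird = FALSE, reptile = FALSE,
      frog = TRUE, fish = FALSE))
})

test_that("the tier is the most distal conserved clade", {
  f <- c(rodent = TRUE, human = TRUE, bird = TRUE, reptile = FALSE,
         frog = FALSE, fish = FALSE)
  expect_equal(conservation_tier(f), "bird")
  expect_equal(conservation_tier(stats::setNames(rep(FALSE, 6), names(f))),
               "none")
  gap <- c(rodent = FALSE, human = FALSE, bird = FALSE, reptile = FALSE,
           frog = FALSE, fish = TRUE)
  expect_equal(conservation_tier(gap), "fish")
  # vectorised over a data frame of flag columns
  df <- tibble::as_tibble(rbind(f, gap))
  expect_equal(conservation_tier(df), c("bird", "fish"))
})

test_that("the highly conserved filter keeps distal, low-mismatch RAREs", {
  cand <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g4"),
    rare_region = c("chr1:11-24", "chr1:101-114", "chr1:201-214",
                    "chr1:301-317", NA),
    rare_type = c("DR2", "DR2", "DR1", "DR5", NA),
    rare_mismatches = c(0L, 2L, 1L, 0L, NA),
    element_class = c("enhancer", "enhancer", "silencer", "enhancer", NA),
    conserved_to = c("fish", "fish", "bird", "human", NA))
  kept <- filter_highly_conserved(cand)
  # g2 fails the mismatch tolerance, g4 is conserved only to human
  expect_equal(kept$n_rares, 2)
  expect_setequal(kept$genes, c("g1", "g3"))
  # tolerance 2 keeps strictly more
  loose <- filter_highly_conserved(
    cand, pipeline_config(high_conf_mismatch_tol = 2))
  expect_true(all(kept$rares$rare_region %in% loose$rares$rare_region))
  expect_equal(loose$n_rares, 3)
})

test_that("synthetic nested conservation yields non-increasing distal counts", {
  sim <- simulate_ra_inputs(simulation_params(n_genes = 200,
                                              n_true_targets = 40,
                                              n_null_peaks = 0, seed = 21))
  run <- run_ra_pipeline(sim$expr, sim$peaks_k27ac, sim$peaks_k27me3,
                         sim$genome, sim$genes, sim$tads,
                         sim$ortholog_windows, quiet = TRUE)
  cfg <- pipeline_config()
  planted <- dplyr::inner_join(
    sim$truth$rares,
    dplyr::distinct(run$candidates[!is.na(run$candidates$rare_region),
                                   c("rare_region", "conserved_to")]),
    by = c(region = "rare_region"))
  # recovered tier equals the planted tier
  expect_equal(planted$conserved_to, planted$tier)
  # counts conserved at least to each clade are non-increasing distally
  ranks <- match(planted$conserved_to, cfg$clade_order, nomatch = 0L)
  at_least <- vapply(seq_along(cfg$clade_order),
                     function(k) sum(ranks >= k), integer(1))
  expect_true(all(diff(at_least) <= 0))
})
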