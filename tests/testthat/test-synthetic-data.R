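test_that("the degenerate empty study builds a genome with empty truth", {
  truth <- build_genome(1, 5e4, 0, 0, seed = 1,
                        config = list(n_transcripts = 0))
  expect_identical(names(truth$genome), "chr1")
  expect_identical(nchar(truth$genome[[1]]), 50000L)
  expect_identical(nrow(truth$hairpins), 0L)
  expect_identical(nrow(truth$annotation), 0L)
  expect_identical(nrow(truth$expression), 0L)
})

test_that("regeneration with the same seed is byte-identical", {
  t1 <- build_genome(1, 2e4, 3, 4, seed = 5,
                     config = list(library_size = 5e3))
  t2 <- build_genome(1, 2e4, 3, 4, seed = 5,
                     config = list(library_size = 5e3))
  expect_identical(serialize(t1, NULL, version = 2),
                   serialize(t2, NULL, version = 2))
  s1 <- simulate_reads(t1, "fetal")
  s2 <- simulate_reads(t2, "fetal")
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth_table, s2$truth_table)
})

test_that("every planted precursor passes the hairpin criteria when refolded", {
  truth <- small_truth()
  hp <- truth$hairpins
  for (i in seq_len(nrow(hp))) {
    fr <- fold(hp$precursor[i])
    ev <- mirpipe:::evaluate_hairpin(fr, hp$mature_start[i], hp$mature_end[i])
    expect_true(ev$verdict, label = hp$name[i])
    expect_lte(fr$mfe, -18)
    expect_gt(fr$mfei, 0.85)
    # mature and star are precursor subsequences on opposite arms
    expect_true(grepl(hp$mature[i], hp$precursor[i], fixed = TRUE))
    expect_true(grepl(hp$star[i], hp$precursor[i], fixed = TRUE))
  }
  expect_true(all(truth$expression$fc > 0 & is.finite(truth$expression$fc)))
})

test_that("an unknown library identifier is rejected", {
  expect_error(simulate_reads(small_truth(), "larva"), "unknown library")
})

test_that("realized mature counts are Poisson-consistent with the truth", {
  study <- small_study()
  truth <- study$truth
  tt <- study$sims$fetal$truth_table
  cnt <- table(tt$mature_name[tt$source == "mature"])
  means <- truth$expression$mean_fetal
  names(means) <- truth$expression$mature_name
  for (nm in names(cnt)) {
    lam <- means[[nm]]
    expect_lt(abs(cnt[[nm]] - lam), 5 * sqrt(lam) + 1)
  }
})

test_that("a single forced-exact mature yields only canonical inserts", {
  truth <- build_genome(1, 2e4, 1, 0, seed = 3, config = list(
    library_size = 100, exact_counts = TRUE, isomir_rate = 0, edit_rate = 0,
    star_frac = 0, decoy_frac = 0, unknown_frac = 0, frac_adaptor3_null = 0,
    frac_insert_null = 0, frac_adaptor5 = 0, frac_short = 0, frac_polya = 0,
    n_transcripts = 0))
  sim <- simulate_reads(truth, "fetal")
  cr <- clean_reads(unname(sim$reads), truth$adapter3, truth$adapter5)
  expect_identical(unique(cr$inserts), chartr("U", "T", truth$hairpins$mature))
  expect_identical(length(sim$reads),
                   as.integer(round(truth$expression$mean_fetal)))
})

test_that("the simulated insert length mode is 22 nt", {
  study <- small_study()
  lh <- length_histogram(study$tags)
  expect_identical(lh$length[which.max(lh$total)], 22L)
})

test_that("FASTQ and FASTA writers round-trip through Biostrings", {
  truth <- build_genome(1, 2e4, 2, 2, seed = 9,
                        config = list(library_size = 500, n_transcripts = 0))
  sim <- simulate_reads(truth, "adult")
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim, fq)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_identical(unname(as.character(back)), unname(sim$reads))
  expect_identical(names(back), names(sim$reads))
  fa <- tempfile(fileext = ".fa")
  write_genome(truth, fa)
  g <- Biostrings::readDNAStringSet(fa)
  expect_identical(stats::setNames(as.character(g), names(g)), truth$genome)
})
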