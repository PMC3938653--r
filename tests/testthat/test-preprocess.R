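A3 <- "TCGTATGCCGTCTTCTGCTTG"
A5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

test_that("a 22-nt insert followed by the adapter trims to a clean insert", {
  ins <- "ACGTACGTACGTACGTACGTAC"
  r <- clean_reads(paste0(ins, A3), A3, A5)
  expect_identical(r$inserts, ins)
  expect_identical(r$stats$clean_reads, 1L)
})

test_that("reads without a 3' adapter are counted and dropped", {
  r <- clean_reads("GGCATGCATCAGATTCAGCATGCAGCATCAGT", A3, A5)
  expect_identical(r$stats$adaptor3_null, 1L)
  expect_length(r$inserts, 0)
})

test_that("category precedence assigns each read to exactly one class", {
  reads <- c(
    paste0(strrep("A", 22), A3),                  # polyA
    paste0(substr(A5, 1, 10), "ACGTACGTATAC", A3), # 5' contaminant
    "GGCATGCATCAGATTCAGCATGCAGCATCAGT",           # no 3' adapter
    A3,                                           # empty insert
    paste0("ACGTACGTAC", A3),                     # 10 nt: too short
    paste0("ACGTACGTACGTACGTACGTAC", A3)          # clean
  )
  r <- clean_reads(reads, A3, A5)
  expect_identical(r$categories,
                   c("polya", "adaptor5_contaminants", "adaptor3_null",
                     "insert_null", "small_than_18nt", "clean"))
  s <- r$stats
  expect_identical(s$high_quality,
                   s$adaptor3_null + s$insert_null + s$adaptor5_contaminants +
                     s$small_than_18nt + s$polya + s$clean_reads)
})

test_that("empty input yields zero stats without error", {
  r <- clean_reads(character(0), A3, A5)
  expect_identical(r$stats$total_read, 0L)
  expect_length(r$inserts, 0)
})

test_that("the accounting identity holds on random reads (property)", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:80, 1)
    reads <- vapply(seq_len(n), function(i) {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(0:35, 1), TRUE),
                   collapse = "")
      if (runif(1) < 0.7) substr(paste0(ins, A3), 1, 36) else
        substr(paste0(ins, strrep("G", 36)), 1, 36)
    }, "")
    s <- clean_reads(reads, A3, A5)$stats
    expect_identical(s$total_read, n)
    expect_identical(s$high_quality,
                     s$adaptor3_null + s$insert_null +
                       s$adaptor5_contaminants + s$small_than_18nt +
                       s$polya + s$clean_reads)
  }
})

test_that("clean inserts contain no residual adapter (trimming idempotent)", {
  study <- small_study()
  ins <- study$cleaned[[1]]$inserts
  # re-trimming: every insert lacks an adapter match, so nothing changes
  r2 <- clean_reads(ins, study$truth$adapter3, study$truth$adapter5)
  expect_true(all(r2$categories == "adaptor3_null"))
})

test_that("simulated category counts equal the planted per-read truth", {
  study <- small_study()
  for (lb in study$truth$libraries) {
    planted <- table(study$sims[[lb]]$truth_table$category)
    got <- table(study$cleaned[[lb]]$categories)
    expect_identical(as.list(got), as.list(planted))
  }
})

test_that("planted polyA reads match their binomial expectation", {
  truth <- small_truth()
  n <- truth$library_size
  p <- truth$frac_polya
  got <- sum(small_study()$sims$fetal$truth_table$category == "polya")
  expect_lt(abs(got - n * p), 5 * sqrt(n * p * (1 - p)) + 1)
})

test_that("collapse preserves read counts and keys tags by sequence", {
  t1 <- collapse_tags(rep("ACGTACGTACGTACGTACGT", 2), "fetal")
  expect_identical(nrow(t1), 1L)
  expect_identical(t1$count_fetal, 2L)
  expect_identical(nrow(collapse_tags(character(0), "x")), 0L)
  set.seed(5)
  ins <- vapply(1:2000, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""), "")
  tt <- collapse_tags(ins, "x")
  expect_identical(sum(tt$count_x), 2000L)
})

test_that("length histogram totals are conserved with the expected mode", {
  one <- collapse_tags(rep("ACGTACGTACGTACGTACGTAC", 5), "x")
  lh1 <- length_histogram(one)
  expect_identical(lh1$length, 22L)
  expect_identical(lh1$total, 5)
  expect_identical(lh1$unique, 1)

  study <- small_study()
  lh <- length_histogram(study$tags)
  expect_identical(lh$length[which.max(lh$total)], 22L)
  expect_equal(sum(lh$total),
               sum(vapply(study$cleaned, function(x) x$stats$clean_reads, 1)))
})

test_that("library overlap fractions partition the tag union", {
  a <- collapse_tags(c("ACGTACGTACGTACGTACGT", "CCGTACGTACGTACGTACGT"), "a")
  b <- collapse_tags(c("ACGTACGTACGTACGTACGT", "GGGTACGTACGTACGTACGT"), "b")
  ov <- library_overlap(a, b)
  expect_identical(ov$unique, c(1L, 1L, 1L))
  expect_equal(sum(ov$unique_fraction), 1, tolerance = 1e-12)
  same <- library_overlap(a, a)
  expect_identical(same$unique[same$set != "common"], c(0L, 0L))
  expect_equal(same$unique_fraction[1], 1)
  disj <- library_overlap(a, collapse_tags("TTTTACGTACGTACGTACGT", "b"))
  expect_identical(disj$unique[disj$set == "common"], 0L)
})
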