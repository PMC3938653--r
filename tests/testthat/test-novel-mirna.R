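test_that("multi-hit tags are excluded from candidate windows", {
  g <- c(chr1 = paste(rep("ACGT", 2500), collapse = ""))
  hits <- data.frame(tag = "T1", chrom = "chr1", start = 500, end = 522,
                     strand = "+", hit_count = 12L, multi_hit = TRUE,
                     stringsAsFactors = FALSE)
  cw <- candidate_windows(hits, g)
  expect_identical(nrow(cw$windows), 0L)
})

test_that("windows are clipped at chromosome ends and merged when close", {
  g <- c(chr1 = paste(rep("ACGT", 500), collapse = "")) # 2 kb
  hits <- data.frame(tag = c("T1", "T2"), chrom = "chr1",
                     start = c(200L, 252L), end = c(222L, 274L),
                     strand = "+", hit_count = 1L, multi_hit = FALSE,
                     stringsAsFactors = FALSE)
  cw <- candidate_windows(hits, g)
  expect_identical(nrow(cw$windows), 1L) # 30 nt apart: merged
  expect_identical(cw$windows$start, 50L) # clipped flank: 200 - 150
  expect_identical(nrow(cw$members), 2L)
  # near the chromosome start the flank is truncated at 0
  h2 <- data.frame(tag = "T1", chrom = "chr1", start = 100L, end = 122L,
                   strand = "+", hit_count = 1L, multi_hit = FALSE,
                   stringsAsFactors = FALSE)
  expect_identical(candidate_windows(h2, g)$windows$start, 0L)
})

test_that("known ncRNA-class tags do not seed candidate windows", {
  g <- c(chr1 = paste(rep("ACGT", 2500), collapse = ""))
  hits <- data.frame(tag = c("T1", "T2"), chrom = "chr1",
                     start = c(500L, 5000L), end = c(522L, 5022L),
                     strand = "+", hit_count = 1L, multi_hit = FALSE,
                     stringsAsFactors = FALSE)
  classes <- data.frame(tag = c("T1", "T2"), class = c("rRNA", "Intron_sense"),
                        stringsAsFactors = FALSE)
  cw <- candidate_windows(hits, g, classes = classes)
  expect_identical(nrow(cw$windows), 1L)
  expect_identical(cw$members$tag, "T2")
})

test_that("planted hairpin windows pass every criterion with star support", {
  study <- small_study()
  truth <- study$truth
  cnt <- stats::setNames(rowSums(tag_counts(study$tags)),
                         study$tags$sequence)
  cw <- candidate_windows(study$mapped$hits, truth$genome,
                          tag_counts = cnt)
  hp <- truth$hairpins
  verdicts <- logical(nrow(hp))
  for (i in seq_len(nrow(hp))) {
    w <- which(cw$windows$chrom == hp$chrom[i] &
                 cw$windows$start < hp$end[i] &
                 cw$windows$end > hp$start[i] &
                 cw$windows$strand == hp$strand[i])
    if (length(w) == 0) next
    win <- cw$windows[w[1], ]
    mem <- cw$members[cw$members$window_id == win$window_id, ]
    cand <- evaluate_candidate(win, mem, truth$genome, tag_counts = cnt)
    verdicts[i] <- cand$verdict
    if (cand$verdict && cand$star_support > 0)
      expect_identical(cand$tier, "high")
  }
  expect_gte(mean(verdicts), 0.9)
})

test_that("a random-sequence window fails the energy criteria", {
  set.seed(77)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 1200, TRUE),
                      collapse = ""))
  win <- data.frame(window_id = 1L, chrom = "chr1", start = 300L, end = 700L,
                    strand = "+", stringsAsFactors = FALSE)
  mem <- data.frame(window_id = 1L, tag = substr(g[[1]], 490, 510),
                    rel_start = 190L, rel_end = 210L, stringsAsFactors = FALSE)
  cand <- evaluate_candidate(win, mem, g)
  expect_false(cand$verdict)
  expect_false(cand$flags[["mfei_gt_0_85"]])
})

test_that("a 25-nt mature fails the length criterion", {
  mature <- "ACGGAUGCUAGCUAGGCUAGCAGCA" # 25 nt
  prec <- paste0("GG", mature, "GCAAUAGCAAG", revcomp_rna(mature), "GG")
  ev <- mirpipe:::evaluate_hairpin(fold(prec), 3L, 27L)
  expect_false(ev$flags[["length_20_22"]])
})

test_that("member tags outside the window raise an error", {
  g <- c(chr1 = paste(rep("ACGT", 500), collapse = ""))
  win <- data.frame(window_id = 1L, chrom = "chr1", start = 0L, end = 100L,
                    strand = "+", stringsAsFactors = FALSE)
  mem <- data.frame(window_id = 1L, tag = "ACGT", rel_start = 150L,
                    rel_end = 170L, stringsAsFactors = FALSE)
  expect_error(evaluate_candidate(win, mem, g), "outside its window")
})

test_that("an empty unannotated pool yields an empty prediction table", {
  g <- c(chr1 = paste(rep("ACGT", 500), collapse = ""))
  tags <- data.frame(sequence = character(0), count_x = integer(0))
  hits <- data.frame(tag = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     strand = character(0), hit_count = integer(0),
                     multi_hit = logical(0), stringsAsFactors = FALSE)
  expect_identical(nrow(predict_novel(tags, hits, g)), 0L)
})

test_that("tightening thresholds never increases the prediction count", {
  study <- small_study()
  base_args <- list(tags = study$tags, hits = study$mapped$hits,
                    genome = study$truth$genome)
  n_base <- nrow(do.call(predict_novel, base_args))
  for (mfei_min in c(0.95, 1.1)) {
    n <- nrow(do.call(predict_novel, c(base_args, list(mfei_min = mfei_min))))
    expect_lte(n, n_base)
    n_base2 <- n
  }
  n_dg <- nrow(do.call(predict_novel, c(base_args, list(dg_max = -30))))
  expect_lte(n_dg, n_base)
  n_both <- nrow(do.call(predict_novel,
                         c(base_args, list(dg_max = -30, mfei_min = 1.1))))
  expect_lte(n_both, min(n_dg, n_base))
})

test_that("prediction is idempotent: accepted candidates re-verify", {
  study <- small_study()
  nv1 <- predict_novel(study$tags, study$mapped$hits, study$truth$genome)
  nv2 <- predict_novel(study$tags, study$mapped$hits, study$truth$genome)
  expect_identical(nv1, nv2)
  expect_true(all(nv1$mfei > 0.85))
  expect_true(all(nv1$mfe <= -18))
})
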