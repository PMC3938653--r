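test_that("first-nucleotide bias fractions sum to one per length", {
  allU <- c("UACGACGAGCAUGCAGAUCG", "UUCGACGAGCAUGCAGAUCGA")
  b <- first_nt_bias(allU)
  expect_true(all(b$U == 1))
  mix <- c("AACGACGAGCAUGCAGAUCG", "CACGACGAGCAUGCAGAUCG",
           "GACGACGAGCAUGCAGAUCG", "UACGACGAGCAUGCAGAUCG")
  bm <- first_nt_bias(mix)
  expect_true(all(abs(bm[, c("A", "C", "G", "U")] - 0.25) < 1e-12))
})

test_that("planted 5'-U enrichment shows U as the dominant first base", {
  truth <- small_truth()
  b <- first_nt_bias(truth$hairpins$mature)
  agg <- colSums(b[, c("A", "C", "G", "U")] *
                   table(factor(nchar(truth$hairpins$mature),
                                levels = b$length)))
  expect_identical(names(which.max(agg)), "U")
})

test_that("positional composition is exact on degenerate input", {
  pb <- position_bias(rep("GGGGGGGGGGGGGGGGGGGG", 3))
  expect_true(all(pb$G == 1))
  expect_identical(nrow(position_bias(character(0))), 0L)
  set.seed(21)
  tags <- vapply(1:4000, function(i)
    paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = ""), "")
  pb2 <- position_bias(tags)
  sd5 <- 5 * sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(as.matrix(pb2[, c("A", "C", "G", "U")]) - 0.25) < sd5))
  expect_true(all(abs(rowSums(pb2[, c("A", "C", "G", "U")]) - 1) < 1e-12))
})

ref1 <- load_mirna_reference(
  mature = c("syn-miR-1-5p" = "ACGGAUGCUAGCUAGGCUAGC"),
  precursor = c("syn-mir-1" =
                  "GGACGGAUGCUAGCUAGGCUAGCAAAAGCUAGCCUAGCUAGCAUCCGUCC"))

test_that("single substitutions are located and seed-flagged", {
  tags <- data.frame(sequence = c("ACGGTTGCTAGCTAGGCTAGC",  # pos 5 T
                                  "ACGGATGCTAGTTAGGCTAGC"), # pos 12 T
                     count_x = c(3L, 4L), stringsAsFactors = FALSE)
  ed <- detect_edits(tags, ref1)
  expect_identical(nrow(ed), 2L)
  p5 <- ed[ed$position == 5, ]
  expect_identical(p5$from, "A")
  expect_identical(p5$to, "U")
  expect_true(p5$in_seed)
  expect_false(ed$in_seed[ed$position == 12])
})

test_that("an edit colliding with two matures goes to the expressed one", {
  ref2 <- load_mirna_reference(
    mature = c("syn-miR-a" = "ACGGAUGCUAGCUAGGCUAGC",
               "syn-miR-b" = "ACGGAUGCUAGCUAGGCUUGC"),
    precursor = c("syn-miR-a" = "ACGGAUGCUAGCUAGGCUAGCAAAA",
                  "syn-miR-b" = "ACGGAUGCUAGCUAGGCUUGCAAAA"))
  # one substitution away from both references
  tags <- data.frame(sequence = "ACGGATGCTAGCTAGGCTGGC", count_x = 1L,
                     stringsAsFactors = FALSE)
  hi_b <- detect_edits(tags, ref2,
                       mature_expression = c("syn-miR-a" = 1, "syn-miR-b" = 50))
  expect_identical(hi_b$mature, "syn-miR-b")
  tie <- detect_edits(tags, ref2,
                      mature_expression = c("syn-miR-a" = 5, "syn-miR-b" = 5))
  expect_identical(tie$mature, "syn-miR-a") # lexicographic tie-break
})

test_that("zero-mismatch edit detection reduces to exact canonical matching", {
  tags <- data.frame(sequence = c("ACGGATGCTAGCTAGGCTAGC",
                                  "ACGGTTGCTAGCTAGGCTAGC"),
                     count_x = c(2L, 3L), stringsAsFactors = FALSE)
  ed0 <- detect_edits(tags, ref1, mismatches = 0)
  expect_identical(ed0$tag, "ACGGATGCTAGCTAGGCTAGC")
  kn <- match_known(tags, ref1)
  canonical <- kn$assignments[kn$assignments$offset5 == 0 &
                                kn$assignments$offset3 == 0, ]
  expect_identical(sort(ed0$tag), sort(canonical$tag))
})

test_that("known assignments and edit records are disjoint pools", {
  study <- small_study()
  ref <- truth_reference(study$truth)
  kn <- match_known(study$tags, ref)
  unann <- study$tags[!study$tags$sequence %in% kn$assignments$tag, ]
  ed <- detect_edits(unann, ref)
  expect_length(intersect(ed$tag, kn$assignments$tag), 0)
})

test_that("templated end variants are recovered with exact offsets", {
  ref <- load_mirna_reference(
    mature = c("syn-miR-1-5p" = "ACGGAUGCUAGCUAGGCUAGC"),
    precursor = c("syn-mir-1" =
                    "GGACGGAUGCUAGCUAGGCUAGCAAAAGCUAGCCUAGCUAGCAUCCGUCC"))
  tags <- data.frame(
    sequence = c("ACGGATGCTAGCTAGGCTAGC",   # canonical: (0, 0)
                 "ACGGATGCTAGCTAGGCTAGCA"), # one templated 3' nt: (0, +1)
    count_x = c(5L, 2L), stringsAsFactors = FALSE)
  kn <- match_known(tags, ref)
  ev <- end_variants(kn$assignments, tags)
  expect_identical(nrow(ev), 2L)
  expect_true(any(ev$offset5 == 0 & ev$offset3 == 0 & ev$total == 5))
  expect_true(any(ev$offset5 == 0 & ev$offset3 == 1 & ev$total == 2))
})

test_that("simulated isomiR offsets are recovered exactly", {
  study <- small_study()
  ref <- truth_reference(study$truth)
  kn <- match_known(study$tags, ref)
  ev <- end_variants(kn$assignments, study$tags)
  tt <- do.call(rbind, lapply(study$sims, `[[`, "truth_table"))
  iso <- tt[tt$variant %in% c("canonical", "isomir"), ]
  planted <- stats::aggregate(
    list(total = rep(1, nrow(iso))),
    by = list(mature = iso$mature_name, offset5 = iso$offset5,
              offset3 = iso$offset3), FUN = sum)
  got <- ev[, c("mature", "offset5", "offset3", "total")]
  key <- function(d) paste(d$mature, d$offset5, d$offset3)
  planted <- planted[order(key(planted)), ]
  got <- got[order(key(got)), ]
  expect_identical(key(got), key(planted))
  expect_equal(got$total, planted$total)
})

test_that("the recovered edited-read fraction matches the generator rate", {
  study <- small_study()
  ref <- truth_reference(study$truth)
  kn <- match_known(study$tags, ref)
  unann <- study$tags[!study$tags$sequence %in% kn$assignments$tag, ]
  ed <- detect_edits(unann, ref)
  tt <- do.call(rbind, lapply(study$sims, `[[`, "truth_table"))
  n_mature_reads <- sum(tt$source == "mature")
  e <- study$truth$edit_rate
  got_frac <- sum(rowSums(tag_counts(ed))) / n_mature_reads
  expect_lt(abs(got_frac - e), 5 * sqrt(e * (1 - e) / n_mature_reads))
})

test_that("families group paralogs and identify the dominant member", {
  rec <- data.frame(
    name = c("bta-let-7a", "bta-let-7b", "bta-miR-2284e", "bta-miR-2284x",
             "bta-miR-107"),
    family = parse_family(c("bta-let-7a", "bta-let-7b", "bta-miR-2284e",
                            "bta-miR-2284x", "bta-miR-107")),
    count_x = c(100, 40, 0, 57585, 7), stringsAsFactors = FALSE)
  fam <- assign_family(rec)
  l7 <- fam[fam$family == "let-7", ]
  expect_identical(l7$n_members, 2L)
  expect_identical(l7$dominant, "bta-let-7a")
  m2284 <- fam[fam$family == "miR-2284", ]
  expect_identical(m2284$dominant, "bta-miR-2284x")
  expect_identical(m2284$dominant_total, 57585)
  single <- fam[fam$family == "miR-107", ]
  expect_identical(single$dominant, "bta-miR-107")
})
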