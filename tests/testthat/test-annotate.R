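mk_hits <- function(tag, chrom, start, len, strand) {
  data.frame(tag = tag, chrom = chrom, start = start, end = start + len,
             strand = strand, hit_count = 1L, multi_hit = FALSE,
             stringsAsFactors = FALSE)
}

test_that("single-feature overlap assigns the feature's class", {
  ann <- data.frame(chrom = "chr1", start = 100, end = 220, strand = "+",
                    class = "rRNA", name = "r1")
  cl <- classify_tags(mk_hits("T1", "chr1", 150, 22, "+"), ann)
  expect_identical(cl$classes$class, "rRNA")
})

test_that("the highest-priority class wins on multi-feature overlap", {
  ann <- data.frame(chrom = "chr1", start = c(100, 100), end = c(220, 220),
                    strand = c("+", "+"), class = c("miRNA", "repeat"),
                    name = c("m", "r"))
  cl <- classify_tags(mk_hits("T1", "chr1", 150, 22, "+"), ann)
  expect_identical(cl$classes$class, "miRNA")
  # exhaustive two-class check: the earlier class in the priority always wins
  pr <- default_class_priority()
  for (i in seq_along(pr)) for (j in seq_along(pr)) {
    if (i == j) next
    ann2 <- data.frame(chrom = "chr1", start = c(100, 100), end = c(220, 220),
                       strand = "+", class = c(pr[i], pr[j]),
                       name = c("a", "b"))
    got <- classify_tags(mk_hits("T1", "chr1", 150, 22, "+"), ann2)$classes$class
    want <- pr[min(i, j)]
    if (want %in% c("exon", "intron"))
      want <- paste0(toupper(substr(want, 1, 1)),
                     substr(want, 2, nchar(want)), "_sense")
    expect_identical(got, want)
  }
})

test_that("antisense exon overlap is labelled Exon_antisense", {
  ann <- data.frame(chrom = "chr1", start = 100, end = 220, strand = "+",
                    class = "exon", name = "e1")
  cl <- classify_tags(mk_hits("T1", "chr1", 150, 22, "-"), ann)
  expect_identical(cl$classes$class, "Exon_antisense")
})

test_that("unknown labels error and unannotated tags fall through", {
  bad <- data.frame(chrom = "chr1", start = 1, end = 10, strand = "+",
                    class = "lincRNA", name = "x")
  expect_error(classify_tags(mk_hits("T", "chr1", 1, 20, "+"), bad),
               "unknown annotation class")
  ann <- data.frame(chrom = "chr1", start = 1000, end = 1100, strand = "+",
                    class = "rRNA", name = "r")
  cl <- classify_tags(mk_hits("T1", "chr1", 10, 22, "+"), ann)
  expect_identical(cl$classes$class, "unknown")
})

test_that("classification partitions mapped tags and conserves read totals", {
  study <- small_study()
  cl <- classify_tags(study$mapped$hits, full_annotation(study$truth),
                      tags = study$tags)
  expect_identical(nrow(cl$classes), length(unique(study$mapped$hits$tag)))
  sm <- cl$summary
  tot_row <- sm[sm$class == "Total", ]
  expect_identical(sum(sm$unique[sm$class != "Total"]), tot_row$unique)
  for (cc in grep("^total_", names(sm), value = TRUE))
    expect_equal(sum(sm[[cc]][sm$class != "Total"]), tot_row[[cc]])
})

test_that("raising a class in the priority never decreases its tag count", {
  study <- small_study()
  hits <- study$mapped$hits
  ann <- full_annotation(study$truth)
  pr <- default_class_priority()
  for (cls in c("repeat", "intron", "snoRNA")) {
    base <- classify_tags(hits, ann, priority = pr)$classes
    raised <- classify_tags(hits, ann,
                            priority = c(cls, setdiff(pr, cls)))$classes
    count_of <- function(df) {
      cap <- paste0(toupper(substr(cls, 1, 1)), substr(cls, 2, nchar(cls)))
      sum(df$class %in% c(cls, paste0(cap, "_sense"), paste0(cap, "_antisense")))
    }
    expect_gte(count_of(raised), count_of(base))
  }
})

test_that("tags are matched to known matures within the isomiR tolerance", {
  ref <- load_mirna_reference(
    mature = c("syn-miR-9-5p" = "ACGGAUGCUAGCUAGGCUAGC"),
    precursor = c("syn-mir-9" =
                    "GGACGGAUGCUAGCUAGGCUAGCAAAAGCUAGCCUAGCUAGCAUCCGUCC"))
  tags <- data.frame(
    sequence = c("ACGGATGCTAGCTAGGCTAGC",   # canonical
                 "GGATGCTAGCTAGGCTAGCAA",   # +2/+2 shift, templated
                 "TTTTTTTTTTTTTTTTTTTTT"),  # unrelated
    count_x = c(10L, 2L, 5L), stringsAsFactors = FALSE)
  res <- match_known(tags, ref)
  expect_identical(nrow(res$assignments), 2L)
  can <- res$assignments[res$assignments$offset5 == 0 &
                           res$assignments$offset3 == 0, ]
  expect_identical(can$mature, "syn-miR-9-5p")
  shifted <- res$assignments[res$assignments$offset5 == 2, ]
  expect_identical(shifted$offset3, 2L)
  expect_identical(res$records$count_x, 12)
})

test_that("a reference mature absent from its precursor errors at load", {
  expect_error(load_mirna_reference(
    mature = c("m-1" = "ACGUACGUACGUACGUACGU"),
    precursor = c("m-1" = "GGGGGGGGGGGGGGGGGGGGGGGGGGGGGG")),
    "absent from its precursor")
})

test_that("chromosome density divides loci by Mbp", {
  d <- chromosome_density(data.frame(chrom = rep("chrX", 38)),
                          c(chrX = 149e6))
  expect_equal(d$loci_per_mbp, 38 / 149, tolerance = 1e-12)
  d0 <- chromosome_density(data.frame(chrom = character(0)), c(chr1 = 1e6))
  expect_identical(d0$n_loci, 0L)
  expect_identical(d0$loci_per_mbp, 0)
  expect_error(chromosome_density(data.frame(chrom = "chr1"), c(chr1 = 0)),
               "positive")
})

test_that("planted locus densities match the generator truth", {
  truth <- small_truth()
  d <- chromosome_density(truth$hairpins, truth$chrom_lengths)
  for (ch in names(truth$chrom_lengths)) {
    expect_identical(d$n_loci[d$chrom == ch],
                     sum(truth$hairpins$chrom == ch))
  }
})
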