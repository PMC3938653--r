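MIRNA <- "ACGGAUGCUAGCUAGGCUAGC" # 21 nt
PERFECT <- revcomp_rna(MIRNA)

test_that("a perfect complementary site aligns with zero weighted mismatches", {
  aln <- align_site(MIRNA, PERFECT)
  expect_true(all(aln$status == "match"))
  expect_identical(aln$weighted_mismatches, 0)
  expect_equal(aln$mfe_ratio, 1, tolerance = 1e-9)
  expect_true(apply_rules(aln)[["overall"]])
})

test_that("G:U wobbles count half a mismatch each", {
  # flip four site bases so they wobble-pair the miRNA (A->G where miRNA U,
  # C->U where miRNA G)
  site <- strsplit(PERFECT, "")[[1]]
  m <- strsplit(MIRNA, "")[[1]]
  L <- length(m)
  flipped <- 0
  for (i in seq_len(L)) {
    j <- L - i + 1
    if (flipped < 4 && m[i] == "U" && site[j] == "A") {
      site[j] <- "G"
      flipped <- flipped + 1
    }
  }
  expect_identical(flipped, 4)
  aln <- align_site(MIRNA, paste(site, collapse = ""))
  expect_identical(sum(aln$status == "GU"), 4L)
  expect_identical(aln$weighted_mismatches, 2)
  expect_error(align_site(MIRNA, "ACGU"), "length")
})

test_that("weighted totals survive an independent per-position recount", {
  set.seed(31)
  for (i in 1:25) {
    site <- rand_rna(21)
    aln <- align_site(MIRNA, site, compute_mfe = FALSE)
    m <- strsplit(MIRNA, "")[[1]]
    s <- strsplit(site, "")[[1]]
    recount <- 0
    for (p in 1:21) {
      pr <- paste0(m[p], s[21 - p + 1])
      recount <- recount +
        if (pr %in% c("AU", "UA", "CG", "GC")) 0
      else if (pr %in% c("GU", "UG")) 0.5 else 1
    }
    expect_equal(aln$weighted_mismatches, recount)
  }
})

test_that("individual rules fail on their defining violations", {
  mk_site <- function(mm_pos) {
    s <- strsplit(PERFECT, "")[[1]]
    m <- strsplit(MIRNA, "")[[1]]
    L <- length(m)
    for (i in mm_pos) {
      j <- L - i + 1
      # replace with the miRNA base itself: never complementary, never G:U
      s[j] <- switch(m[i], A = "C", C = "A", G = "A", U = "C")
    }
    paste(s, collapse = "")
  }
  v5 <- apply_rules(align_site(MIRNA, mk_site(c(13, 15, 17, 19, 21))))
  expect_false(v5[["rule1"]])
  v10 <- apply_rules(align_site(MIRNA, mk_site(10)))
  expect_false(v10[["rule4"]])
  v3 <- apply_rules(align_site(MIRNA, mk_site(c(5, 6))))
  expect_false(v3[["rule3"]])
  vrun <- apply_rules(align_site(MIRNA, mk_site(c(14, 15, 16))))
  expect_false(vrun[["rule2"]])
})

test_that("rule verdicts agree with the brute-force oracle on edited sites", {
  set.seed(41)
  s0 <- strsplit(PERFECT, "")[[1]]
  for (rep in 1:300) {
    k <- sample(1:3, 1)
    at <- sample(21, k)
    s <- s0
    for (j in at) s[j] <- sample(setdiff(c("A", "C", "G", "U"), s[j]), 1)
    site <- paste(s, collapse = "")
    aln <- align_site(MIRNA, site)
    got <- apply_rules(aln)
    want <- rules_oracle(MIRNA, site, aln$mfe_ratio)
    expect_identical(unname(got[paste0("rule", 1:6)]), unname(want),
                     label = site)
  }
})

test_that("adding mismatches never flips a failing rule to passing", {
  set.seed(51)
  m <- strsplit(MIRNA, "")[[1]]
  mk_site <- function(mm_pos) {
    s <- strsplit(PERFECT, "")[[1]]
    for (i in mm_pos) s[21 - i + 1] <- switch(m[i], A = "C", C = "A",
                                              G = "A", U = "C")
    paste(s, collapse = "")
  }
  for (rep in 1:40) {
    base_pos <- sample(21, sample(1:3, 1))
    extra <- sample(setdiff(1:21, base_pos), 1)
    v_small <- apply_rules(align_site(MIRNA, mk_site(base_pos),
                                      compute_mfe = FALSE))
    v_big <- apply_rules(align_site(MIRNA, mk_site(c(base_pos, extra)),
                                    compute_mfe = FALSE))
    for (r in paste0("rule", 1:5))
      expect_true(v_small[[r]] || !v_big[[r]], label = r)
  }
})

test_that("scanning finds exactly the embedded perfect site", {
  set.seed(61)
  tx <- rand_rna(300)
  site <- chartr("U", "T", PERFECT)
  substr(tx, 101, 121) <- site
  res <- scan_targets(MIRNA, c(tx1 = tx))
  hit <- res[res$start == 101, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$end, 121L)
  expect_true(hit$overall)
})

test_that("planted transcript sites are recovered and shuffles lose them", {
  truth <- small_truth()
  tt <- truth$target_truth
  for (m in unique(tt$mature_name)) {
    seqs <- truth$hairpins$mature[truth$hairpins$mature_name == m]
    res <- scan_targets(seqs, truth$transcripts)
    planted <- tt[tt$mature_name == m, ]
    found <- merge(planted, res, by.x = c("transcript", "start"),
                   by.y = c("transcript", "start"))
    expect_identical(nrow(found), nrow(planted))
    # column-shuffled transcripts: far fewer passing sites
    set.seed(71)
    shuf <- vapply(truth$transcripts, function(s)
      paste(sample(strsplit(s, "")[[1]]), collapse = ""), "")
    res_shuf <- scan_targets(seqs, shuf)
    expect_lt(nrow(res_shuf), nrow(planted))
  }
})

test_that("transcripts shorter than the miRNA are skipped with a notice", {
  expect_message(res <- scan_targets(MIRNA, c(short = "ACGUACGU")),
                 "skipped")
  expect_identical(nrow(res), 0L)
})
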