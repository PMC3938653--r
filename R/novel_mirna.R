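# Hairpin-based novel miRNA prediction: candidate windows around unannotated
# mapped tags, folding, and the enumerated acceptance criteria.

# partner position of `pos` in the pair table, adjusted antiparallel when the
# exact position is unpaired (search up to 2 nt away)
partner_adj <- function(pt, pos) {
  for (d in c(0L, 1L, -1L, 2L, -2L)) {
    p <- pos + d
    if (p >= 1 && p <= length(pt) && pt[p] > 0) return(pt[p] + d)
  }
  NA_integer_
}

# Evaluate the hairpin criteria for a folded precursor with a known mature
# span (1-based). Returns the criterion flags, the inferred star (2-nt 3'
# overhang rule) and the verdict.
evaluate_hairpin <- function(fr, mstart, mend, max_bulge = 4L,
                             dg_max = -18, mfei_min = 0.85,
                             mature_len = c(20L, 22L), dg_duplex_max = -20) {
  pt <- fr$pairs
  n <- length(pt)
  k <- mend - mstart + 1L
  flags <- c(mature_in_one_arm = FALSE, star_overhang_2nt = FALSE,
             no_large_bulge = FALSE, dg_le_minus18 = FALSE,
             mfei_gt_0_85 = FALSE, length_20_22 = FALSE,
             dg_lt_minus20 = FALSE)
  res <- list(flags = flags, verdict = FALSE, star = NA_character_,
              star_start = NA_integer_, star_end = NA_integer_,
              mfe = fr$mfe, mfei = fr$mfei)
  if (mstart < 1 || mend > n) stop("mature span outside the folded sequence")
  mat_pos <- mstart:mend
  partners <- pt[mat_pos]
  paired <- which(partners > 0)
  if (length(paired) == 0) return(res)
  pp <- partners[paired]
  one_arm <- length(paired) >= 0.6 * k &&
    (all(pp > mend) || all(pp < mstart))
  flags["mature_in_one_arm"] <- one_arm
  if (!one_arm) {
    res$flags <- flags
    return(res)
  }
  # star by the 2-nt 3' overhang rule
  ss <- partner_adj(pt, mend - 2L)
  se <- partner_adj(pt, mstart)
  if (!is.na(se)) se <- se + 2L
  star_ok <- !is.na(ss) && !is.na(se) && ss >= 1 && se <= n && ss < se &&
    abs((se - ss + 1L) - k) <= 4L
  flags["star_overhang_2nt"] <- star_ok
  if (star_ok) {
    res$star <- substr(fr$sequence, ss, se)
    res$star_start <- ss
    res$star_end <- se
  }
  # bulge sizes within the mature:star duplex
  pb <- mat_pos[paired]
  gaps_ok <- TRUE
  if (length(pb) > 1) {
    for (idx in seq_len(length(pb) - 1L)) {
      p <- pb[idx]; q <- pb[idx + 1L]
      g_mat <- q - p - 1L
      g_star <- abs(pt[p] - pt[q]) - 1L
      if (g_mat > max_bulge || g_star > max_bulge) { gaps_ok <- FALSE; break }
    }
  }
  flags["no_large_bulge"] <- gaps_ok
  flags["dg_le_minus18"] <- fr$mfe <= dg_max
  flags["mfei_gt_0_85"] <- isTRUE(fr$mfei > mfei_min)
  flags["length_20_22"] <- k >= mature_len[1] && k <= mature_len[2]
  if (star_ok) {
    mat_seq <- substr(fr$sequence, mstart, mend)
    flags["dg_lt_minus20"] <- duplex(mat_seq, res$star)$mfe < dg_duplex_max
  }
  res$flags <- flags
  res$verdict <- all(flags)
  res
}

#' Candidate windows around unannotated mapped tags
#'
#' Takes genome-mapped tags, drops multi-hit tags (more than `max_hits`
#' genomic hits) and tags classified into a known ncRNA/repeat/sense-exon
#' class (tags from unannotated regions, introns and antisense exons remain),
#' and extracts `flank` nt of genomic context on both sides of each hit.
#' Overlapping windows on the same chromosome and strand are merged and
#' clipped at chromosome ends.
#'
#' @param hits Hit table from [map_tags()].
#' @param genome Named chromosome sequences or FASTA path.
#' @param classes Optional per-tag class table (`classes` element of
#'   [classify_tags()]); when `NULL` all tags are treated as unannotated.
#' @param flank Flank size in nt (default 150).
#' @param max_hits Genomic hit-count cutoff (default 10).
#' @param tag_counts Optional named total-count vector; when given, only tags
#'   with at least `min_reads` reads seed windows (sporadic singletons do not
#'   trigger folding), though all admissible tags are still reported as
#'   window members.
#' @param min_reads Minimum read support for a window-seeding tag.
#' @return A list with `windows` (data frame `window_id`, `chrom`, `start`,
#'   `end`, `strand`; 0-based half-open) and `members` (data frame mapping
#'   `window_id` to member `tag`, `rel_start`, `rel_end` on the window
#'   strand, 1-based).
#' @export
candidate_windows <- function(hits, genome, classes = NULL, flank = 150L,
                              max_hits = 10L, tag_counts = NULL,
                              min_reads = 3L) {
  if (length(genome) == 1 && is.null(names(genome)) && file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
    genome <- stats::setNames(as.character(gs), names(gs))
  }
  allowed <- c("unknown", "Intron_sense", "Intron_antisense", "Exon_antisense")
  keep <- hits$hit_count <= max_hits
  if (!is.null(classes)) {
    cls <- classes$class[match(hits$tag, classes$tag)]
    keep <- keep & (is.na(cls) | cls %in% allowed)
  }
  h <- hits[keep, , drop = FALSE]
  empty <- list(
    windows = data.frame(window_id = integer(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), stringsAsFactors = FALSE),
    members = data.frame(window_id = integer(0), tag = character(0),
                         rel_start = integer(0), rel_end = integer(0),
                         stringsAsFactors = FALSE))
  seed <- if (!is.null(tag_counts)) {
    cnt <- tag_counts[h$tag]
    !is.na(cnt) & cnt >= min_reads
  } else rep(TRUE, nrow(h))
  if (nrow(h) == 0 || !any(seed)) return(empty)
  chrlen <- stats::setNames(nchar(genome), names(genome))
  hs <- h[seed, , drop = FALSE]
  wstart <- pmax(0L, hs$start - flank)
  wend <- pmin(chrlen[hs$chrom], hs$end + flank)
  gr <- GenomicRanges::GRanges(hs$chrom,
                               IRanges::IRanges(wstart + 1L, wend),
                               strand = hs$strand)
  red <- GenomicRanges::reduce(gr)
  windows <- data.frame(
    window_id = seq_along(red),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    strand = as.character(GenomicRanges::strand(red)),
    stringsAsFactors = FALSE)
  # members: every admissible hit fully inside a window, window-strand coords
  hg <- GenomicRanges::GRanges(h$chrom,
                               IRanges::IRanges(h$start + 1L, h$end),
                               strand = h$strand)
  ov <- GenomicRanges::findOverlaps(hg, red, type = "within")
  qh <- S4Vectors::queryHits(ov)
  win_of <- S4Vectors::subjectHits(ov)
  ws <- windows$start[win_of]
  we <- windows$end[win_of]
  plus <- windows$strand[win_of] == "+"
  rel_start <- ifelse(plus, h$start[qh] - ws + 1L, we - h$end[qh] + 1L)
  rel_end <- ifelse(plus, h$end[qh] - ws, we - h$start[qh])
  members <- data.frame(window_id = win_of, tag = h$tag[qh],
                        rel_start = as.integer(rel_start),
                        rel_end = as.integer(rel_end),
                        stringsAsFactors = FALSE)
  list(windows = windows, members = members)
}

window_sequence <- function(window, genome) {
  s <- substr(genome[[window$chrom]], window$start + 1L, window$end)
  if (window$strand == "-") s <- revcomp_dna(s)
  chartr("T", "U", s)
}

#' Evaluate one candidate window as a miRNA hairpin
#'
#' The most abundant member tag is taken as the mature candidate. A grid of
#' candidate precursor extents is folded with the tag as the 5' or 3' stem
#' arm, each fold is trimmed to its paired span (plus 2 nt for the star
#' overhang), and the criterion flags are evaluated on the trimmed precursor:
#' mature contained in one arm; star inferred by the 2-nt 3' overhang rule;
#' no bulge or internal loop larger than `max_bulge` within the mature:star
#' duplex; precursor MFE at most `dg_max` kcal/mol; MFEI above `mfei_min`;
#' mature length within `mature_len`; and mature:star hybridisation below
#' `dg_duplex_max` kcal/mol. The best extent (most criteria passed, then
#' highest MFEI) is reported; its verdict is the conjunction of all flags,
#' and star-supporting reads raise the confidence tier to "high".
#'
#' @param window One row of the `windows` table of [candidate_windows()].
#' @param members Member tags of this window (rows of the `members` table).
#' @param genome Named chromosome sequences.
#' @param tag_counts Optional named total-count vector used to rank member
#'   tags (default: all equal, ties to the lexicographically first tag).
#' @param max_bulge,dg_max,mfei_min,mature_len,dg_duplex_max Criterion
#'   thresholds (see above).
#' @param spans Candidate precursor extents (nt beyond the anchoring tag
#'   end), covering the usual loop + star arm range.
#' @param side_pad Extra nt kept on the tag's outer side before trimming.
#' @return A `hairpin_candidate` list: `flags`, `verdict`, `tier`, `mature`
#'   tag and its window span, `star`, `star_support` (read count at the star
#'   position), `precursor` sequence and window span, `mfe`, `mfei`.
#' @export
evaluate_candidate <- function(window, members, genome, tag_counts = NULL,
                               max_bulge = 4L, dg_max = -18, mfei_min = 0.85,
                               mature_len = c(20L, 22L), dg_duplex_max = -20,
                               spans = c(30L, 35L, 40L, 45L, 50L, 60L, 70L,
                                         85L),
                               side_pad = 6L) {
  wseq <- window_sequence(window, genome)
  wlen <- nchar(wseq)
  if (any(members$rel_start < 1 | members$rel_end > wlen))
    stop("member tag outside its window")
  cnt <- if (is.null(tag_counts)) stats::setNames(rep(1, nrow(members)),
                                                  members$tag) else tag_counts
  ord <- order(-cnt[members$tag], members$tag)
  mt <- members[ord[1], ]
  k <- mt$rel_end - mt$rel_start + 1L
  best <- list(flags = stats::setNames(rep(FALSE, 7),
                                       c("mature_in_one_arm",
                                         "star_overhang_2nt",
                                         "no_large_bulge", "dg_le_minus18",
                                         "mfei_gt_0_85", "length_20_22",
                                         "dg_lt_minus20")),
               verdict = FALSE, tier = NA_character_,
               mature = mt$tag, mature_rel = c(mt$rel_start, mt$rel_end),
               star = NA_character_, star_support = 0,
               precursor = NA_character_, prec_rel = c(NA, NA),
               mfe = NA_real_, mfei = NA_real_)
  class(best) <- "hairpin_candidate"
  best_score <- -1

  for (arm in c("5p", "3p")) {
    for (L in spans) {
      if (arm == "5p") {
        a <- mt$rel_start - side_pad
        b <- mt$rel_start + k - 1L + L
      } else {
        a <- mt$rel_end - k + 1L - L
        b <- mt$rel_end + side_pad
      }
      a <- max(1L, a)
      b <- min(wlen, b)
      if (b - a + 1L < k + 25L) next
      prec <- substr(wseq, a, b)
      fr <- fold(prec)
      # trim to the paired span (+2 nt so the star 3' overhang stays inside),
      # iterating to a fixed point: refolding can free further terminal bases
      ok <- TRUE
      for (it in 1:3) {
        paired <- which(fr$pairs > 0)
        if (length(paired) == 0) { ok <- FALSE; break }
        mlo <- mt$rel_start - a + 1L
        mhi <- mt$rel_end - a + 1L
        t1 <- max(1L, min(min(paired), mlo) - 2L)
        t2 <- min(nchar(prec), max(max(paired), mhi) + 2L)
        if (t1 == 1L && t2 == nchar(prec)) break
        b <- a + t2 - 1L
        a <- a + t1 - 1L
        prec <- substr(wseq, a, b)
        fr <- fold(prec)
      }
      if (!ok) next
      ev <- evaluate_hairpin(fr, mt$rel_start - a + 1L, mt$rel_end - a + 1L,
                             max_bulge = max_bulge, dg_max = dg_max,
                             mfei_min = mfei_min, mature_len = mature_len,
                             dg_duplex_max = dg_duplex_max)
      score <- sum(ev$flags) + ifelse(ev$verdict, 100, 0) +
        min(ifelse(is.na(fr$mfei), 0, fr$mfei), 0.99)
      if (score > best_score) {
        best_score <- score
        star_support <- 0
        if (!is.na(ev$star_start)) {
          sst <- ev$star_start + a - 1L
          sen <- ev$star_end + a - 1L
          at_star <- abs(members$rel_start - sst) <= 2 &
            abs(members$rel_end - sen) <= 2
          star_support <- sum(cnt[members$tag[at_star]])
        }
        best <- list(flags = ev$flags, verdict = ev$verdict,
                     tier = if (!ev$verdict) NA_character_ else
                       if (star_support > 0) "high" else "candidate",
                     mature = mt$tag,
                     mature_rel = c(mt$rel_start, mt$rel_end),
                     star = ev$star, star_support = star_support,
                     precursor = fr$sequence, prec_rel = c(a, b),
                     mfe = fr$mfe, mfei = fr$mfei)
        class(best) <- "hairpin_candidate"
      }
    }
  }
  best
}

#' Predict novel miRNA loci from unannotated mapped tags
#'
#' End-to-end prediction: candidate windows ([candidate_windows()]) around
#' unannotated, non-multi-hit tags are each evaluated as a hairpin
#' ([evaluate_candidate()]); windows whose candidate passes every criterion
#' are reported with genomic precursor coordinates.
#'
#' @param tags Tag table with per-library counts (used to pick the most
#'   abundant member tag and report expression).
#' @param hits Hit table from [map_tags()].
#' @param genome Named chromosome sequences or FASTA path.
#' @param classes Optional per-tag class table (see [candidate_windows()]).
#' @param flank,max_hits,min_reads Window construction parameters (see
#'   [candidate_windows()]).
#' @param ... Criterion thresholds passed to [evaluate_candidate()].
#' @return Data frame of accepted candidates: `name`, `chrom`, `start`,
#'   `end`, `strand` (precursor locus, 0-based half-open), `mature`, `star`,
#'   `tier`, `mfe`, `mfei`, `star_support` and the mature tag's per-library
#'   counts.
#' @export
predict_novel <- function(tags, hits, genome, classes = NULL, flank = 150L,
                          max_hits = 10L, min_reads = 3L, ...) {
  if (length(genome) == 1 && is.null(names(genome)) && file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
    genome <- stats::setNames(as.character(gs), names(gs))
  }
  cols <- grep("^count_", names(tags), value = TRUE)
  cnt <- stats::setNames(rowSums(tags[, cols, drop = FALSE]), tags$sequence)
  cw <- candidate_windows(hits, genome, classes = classes, flank = flank,
                          max_hits = max_hits, tag_counts = cnt,
                          min_reads = min_reads)
  out <- list()
  for (w in seq_len(nrow(cw$windows))) {
    win <- cw$windows[w, ]
    mem <- cw$members[cw$members$window_id == win$window_id, , drop = FALSE]
    cand <- evaluate_candidate(win, mem, genome, tag_counts = cnt, ...)
    if (!isTRUE(cand$verdict)) next
    # precursor window coordinates back to genomic
    if (win$strand == "+") {
      gstart <- win$start + cand$prec_rel[1] - 1L
      gend <- win$start + cand$prec_rel[2]
    } else {
      gstart <- win$end - cand$prec_rel[2]
      gend <- win$end - cand$prec_rel[1] + 1L
    }
    rec <- data.frame(
      name = NA_character_, chrom = win$chrom, start = gstart, end = gend,
      strand = win$strand, mature = chartr("T", "U", cand$mature),
      star = cand$star, tier = cand$tier, mfe = cand$mfe, mfei = cand$mfei,
      star_support = cand$star_support, stringsAsFactors = FALSE)
    for (cc in cols)
      rec[[cc]] <- tags[[cc]][match(cand$mature, tags$sequence)]
    out[[length(out) + 1L]] <- rec
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mature = character(0),
                      star = character(0), tier = character(0),
                      mfe = numeric(0), mfei = numeric(0),
                      star_support = numeric(0), stringsAsFactors = FALSE)
    for (cc in cols) res[[cc]] <- numeric(0)
    return(res)
  }
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$name <- sprintf("novel-%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}
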