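#' Align a miRNA against a candidate target site
#'
#' Ungapped antiparallel alignment: miRNA position i (1-based from the miRNA
#' 5' end) faces site position L - i + 1. Each position is scored `match`
#' (Watson-Crick), `GU` (G:U wobble) or `mismatch`; the weighted mismatch
#' total counts G:U as 0.5. The duplex MFE and the MFE of the miRNA bound to
#' its perfect Watson-Crick complement give `mfe_ratio` (1 for a perfect
#' site).
#'
#' @param mirna miRNA sequence, 5' to 3' (RNA or DNA alphabet).
#' @param site Target site sequence of the same length, 5' to 3'.
#' @param compute_mfe Compute duplex energies (set `FALSE` to skip the
#'   folding engine when only the mismatch rules are needed).
#' @return An object of class `duplex_alignment`: `mirna`, `site`, `status`
#'   (per miRNA position), `weighted_mismatches`, `duplex_mfe`,
#'   `perfect_mfe`, `mfe_ratio`.
#' @export
align_site <- function(mirna, site, compute_mfe = TRUE) {
  mirna <- toupper(chartr("tT", "UU", mirna))
  site <- toupper(chartr("tT", "UU", site))
  L <- nchar(mirna)
  if (nchar(site) != L)
    stop("site window length (", nchar(site), ") must equal miRNA length (",
         L, ")")
  m <- strsplit(mirna, "")[[1]]
  s <- rev(strsplit(site, "")[[1]]) # antiparallel: position i faces L - i + 1
  pair <- paste0(m, s)
  status <- ifelse(pair %in% c("AU", "UA", "CG", "GC"), "match",
                   ifelse(pair %in% c("GU", "UG"), "GU", "mismatch"))
  wt <- sum(status == "mismatch") + 0.5 * sum(status == "GU")
  dmfe <- pmfe <- ratio <- NA_real_
  if (compute_mfe) {
    dmfe <- duplex(mirna, site)$mfe
    pmfe <- duplex(mirna, revcomp_rna(mirna))$mfe
    ratio <- if (pmfe < 0) dmfe / pmfe else NA_real_
  }
  structure(list(mirna = mirna, site = site, status = status,
                 weighted_mismatches = wt, duplex_mfe = dmfe,
                 perfect_mfe = pmfe, mfe_ratio = ratio),
            class = "duplex_alignment")
}

#' Apply the six target-prediction rules to an aligned site
#'
#' The rules, with positions numbered from the miRNA 5' end and G:U wobbles
#' weighted 0.5 in the totals but treated as non-mismatches for adjacency and
#' position rules:
#' 1. weighted mismatch total at most 4;
#' 2. no more than two adjacent mismatches;
#' 3. no adjacent mismatches in positions 2-12;
#' 4. no mismatch at positions 10-11;
#' 5. weighted mismatch total over positions 1-12 at most 2.5;
#' 6. duplex MFE at least 75% of the perfect-complement MFE.
#'
#' @param aln A [align_site()] result.
#' @param mfe_ratio_min Rule-6 threshold (default 0.75).
#' @return Named logical vector `rule1`..`rule6` plus `overall`.
#' @export
apply_rules <- function(aln, mfe_ratio_min = 0.75) {
  stopifnot(inherits(aln, "duplex_alignment"))
  st <- aln$status
  L <- length(st)
  mm <- st == "mismatch"
  runs <- rle(mm)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  r2_12 <- mm[2:min(12, L)]
  adj_2_12 <- any(r2_12[-length(r2_12)] & r2_12[-1])
  upto12 <- seq_len(min(12, L))
  wt12 <- sum(st[upto12] == "mismatch") + 0.5 * sum(st[upto12] == "GU")
  rules <- c(
    rule1 = aln$weighted_mismatches <= 4,
    rule2 = max_run <= 2,
    rule3 = !adj_2_12,
    rule4 = !(mm[10] || mm[11]),
    rule5 = wt12 <= 2.5,
    rule6 = isTRUE(aln$mfe_ratio >= mfe_ratio_min)
  )
  c(rules, overall = all(rules))
}

#' Scan transcripts for miRNA target sites
#'
#' Evaluates every window of miRNA length across each transcript with the
#' six target-prediction rules and reports the windows passing all of them.
#' The cheap mismatch rules (1-5) are applied first; the duplex energies for
#' rule 6 are computed only for surviving windows. Transcripts shorter than
#' the miRNA are skipped with a message.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param transcripts Named character vector of transcript sequences or a
#'   FASTA path.
#' @param mfe_ratio_min Rule-6 threshold.
#' @param report_all Report every window (with verdicts) instead of only the
#'   passing ones.
#' @return Data frame `transcript`, `start`, `end` (1-based inclusive site
#'   coordinates), `site`, `weighted_mismatches`, `mfe_ratio`, the per-rule
#'   verdicts and `overall`.
#' @export
scan_targets <- function(mirna, transcripts, mfe_ratio_min = 0.75,
                         report_all = FALSE) {
  if (length(transcripts) == 1 && is.null(names(transcripts)) &&
      file.exists(transcripts)) {
    ss <- Biostrings::readBStringSet(transcripts)
    transcripts <- stats::setNames(as.character(ss),
                                   sub("\\s.*$", "", names(ss)))
  }
  mirna <- toupper(chartr("tT", "UU", mirna))
  L <- nchar(mirna)
  mvec <- strsplit(mirna, "")[[1]]
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  gu <- list(G = "U", U = "G")
  out <- list()
  for (tx in names(transcripts)) {
    s <- toupper(chartr("tT", "UU", transcripts[[tx]]))
    n <- nchar(s)
    if (n < L) {
      message("transcript ", tx, " shorter than miRNA; skipped")
      next
    }
    sv <- strsplit(s, "")[[1]]
    # windows as a (n - L + 1) x L matrix of site bases facing each miRNA
    # position: window w covers sv[w..w+L-1]; miRNA position i faces the
    # site base at w + L - i
    nw <- n - L + 1L
    stat <- matrix("mismatch", nrow = nw, ncol = L)
    for (i in seq_len(L)) {
      b <- sv[seq_len(nw) + L - i]
      stat[, i][b == wc[[mvec[i]]]] <- "match"
      if (mvec[i] %in% names(gu)) stat[, i][b == gu[[mvec[i]]]] <- "GU"
    }
    is_mm <- stat == "mismatch"
    is_gu <- stat == "GU"
    wt <- rowSums(is_mm) + 0.5 * rowSums(is_gu)
    wt12 <- rowSums(is_mm[, 1:min(12, L), drop = FALSE]) +
      0.5 * rowSums(is_gu[, 1:min(12, L), drop = FALSE])
    r1 <- wt <= 4
    r4 <- !(is_mm[, 10] | is_mm[, 11])
    r5 <- wt12 <= 2.5
    cand <- which(if (report_all) rep(TRUE, nw) else (r1 & r4 & r5))
    for (w in cand) {
      site <- substr(s, w, w + L - 1L)
      aln <- align_site(mirna, site, compute_mfe = TRUE)
      v <- apply_rules(aln, mfe_ratio_min = mfe_ratio_min)
      if (report_all || v[["overall"]]) {
        out[[length(out) + 1L]] <- data.frame(
          transcript = tx, start = w, end = w + L - 1L, site = site,
          weighted_mismatches = aln$weighted_mismatches,
          mfe_ratio = aln$mfe_ratio,
          rule1 = v[["rule1"]], rule2 = v[["rule2"]], rule3 = v[["rule3"]],
          rule4 = v[["rule4"]], rule5 = v[["rule5"]], rule6 = v[["rule6"]],
          overall = v[["overall"]], stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), site = character(0),
                      weighted_mismatches = numeric(0), mfe_ratio = numeric(0),
                      rule1 = logical(0), rule2 = logical(0),
                      rule3 = logical(0), rule4 = logical(0),
                      rule5 = logical(0), rule6 = logical(0),
                      overall = logical(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
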