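#' First-nucleotide bias per tag length
#'
#' @param tags Tag table or character vector of sequences (read counts are
#'   ignored: bias is computed over unique tags, the convention for
#'   first-nucleotide summaries of miRNA candidates).
#' @return Data frame `length`, `A`, `C`, `G`, `U` (fractions summing to 1
#'   per length).
#' @export
first_nt_bias <- function(tags) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  if (length(seqs) == 0)
    return(data.frame(length = integer(0), A = numeric(0), C = numeric(0),
                      G = numeric(0), U = numeric(0)))
  seqs <- toupper(chartr("tT", "UU", seqs))
  first <- substr(seqs, 1, 1)
  len <- nchar(seqs)
  tb <- table(factor(len), factor(first, levels = c("A", "C", "G", "U")))
  fr <- prop.table(tb, margin = 1)
  out <- data.frame(length = as.integer(rownames(tb)),
                    A = fr[, "A"], C = fr[, "C"], G = fr[, "G"], U = fr[, "U"],
                    row.names = NULL)
  out[order(out$length), , drop = FALSE]
}

#' Per-position nucleotide composition
#'
#' @param tags Tag table or character vector.
#' @return Data frame `position`, `A`, `C`, `G`, `U`, `n` (tags long enough
#'   to cover the position); fractions sum to 1 per position.
#' @export
position_bias <- function(tags) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  if (length(seqs) == 0)
    return(data.frame(position = integer(0), A = numeric(0), C = numeric(0),
                      G = numeric(0), U = numeric(0), n = integer(0)))
  seqs <- toupper(chartr("tT", "UU", seqs))
  maxlen <- max(nchar(seqs))
  out <- lapply(seq_len(maxlen), function(p) {
    b <- substr(seqs[nchar(seqs) >= p], p, p)
    tb <- table(factor(b, levels = c("A", "C", "G", "U")))
    data.frame(position = p, A = tb[["A"]], C = tb[["C"]], G = tb[["G"]],
               U = tb[["U"]], n = length(b))
  })
  out <- do.call(rbind, out)
  out[, c("A", "C", "G", "U")] <- out[, c("A", "C", "G", "U")] / out$n
  out
}

#' Detect single-base edits against known matures
#'
#' Aligns unannotated tags to reference matures of the same length and emits
#' an edit record for every tag with exactly one substitution. The edit
#' position is 1-based from the mature 5' end; positions 2-8 are flagged as
#' seed edits. A tag one-mismatch-matching several matures is assigned to the
#' most expressed mature (ties: lexicographically first name).
#'
#' @param tags Tag table of unannotated tags (not already assigned to a known
#'   miRNA) with per-library counts.
#' @param reference A [load_mirna_reference()] object.
#' @param mature_expression Optional named vector of per-mature expression
#'   used for the tie-break (default: all zero, so ties break by name).
#' @param mismatches Exact number of substitutions to report (default 1).
#'   With 0, the operation degenerates to exact canonical matching.
#' @return Data frame `tag`, `mature`, `position`, `from`, `to`, `in_seed`
#'   plus the tag's per-library counts. With `mismatches = 0`, `position`,
#'   `from` and `to` are `NA`.
#' @export
detect_edits <- function(tags, reference, mature_expression = NULL,
                         mismatches = 1L) {
  stopifnot(inherits(reference, "mirna_reference"))
  cols <- grep("^count_", names(tags), value = TRUE)
  mt <- reference$mature
  if (is.null(mature_expression))
    mature_expression <- stats::setNames(rep(0, nrow(mt)), mt$name)
  seqs <- tags$sequence
  out <- vector("list", length(seqs))
  mat_by_len <- split(seq_len(nrow(mt)), nchar(mt$sequence))
  split_cache <- new.env(parent = emptyenv())
  chars_of <- function(s) {
    v <- split_cache[[s]]
    if (is.null(v)) {
      v <- strsplit(s, "")[[1]]
      split_cache[[s]] <- v
    }
    v
  }
  for (i in seq_along(seqs)) {
    len <- as.character(nchar(seqs[i]))
    rows <- mat_by_len[[len]]
    if (is.null(rows)) next
    tg <- chars_of(seqs[i])
    cand <- NULL
    for (r in rows) {
      mm <- which(tg != chars_of(mt$sequence[r]))
      if (length(mm) == mismatches) {
        pos1 <- if (mismatches >= 1) mm[1] else NA_integer_
        cand <- rbind(cand, data.frame(
          row = r, position = pos1,
          from = if (is.na(pos1)) NA_character_ else
            chartr("T", "U", chars_of(mt$sequence[r])[pos1]),
          to = if (is.na(pos1)) NA_character_ else chartr("T", "U", tg[pos1]),
          stringsAsFactors = FALSE))
      }
    }
    if (is.null(cand)) next
    if (nrow(cand) > 1) {
      e <- mature_expression[mt$name[cand$row]]
      cand <- cand[order(-e, mt$name[cand$row]), , drop = FALSE]
    }
    out[[i]] <- data.frame(
      tag = seqs[i], mature = mt$name[cand$row[1]],
      position = cand$position[1], from = cand$from[1], to = cand$to[1],
      in_seed = isTRUE(cand$position[1] >= 2 && cand$position[1] <= 8),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(tag = character(0), mature = character(0),
                      position = integer(0), from = character(0),
                      to = character(0), in_seed = logical(0),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  for (cc in cols) res[[cc]] <- tags[[cc]][match(res$tag, tags$sequence)]
  res
}

#' IsomiR end variants of known-miRNA assignments
#'
#' Summarises the 5'/3' end offsets of tags assigned to known matures (from
#' [match_known()], which admits only templated variants: the tag must occur
#' exactly within the precursor). Offsets are signed: positive 3' offsets are
#' templated extensions, (0, 0) is the canonical sequence.
#'
#' @param assignments Assignment table from [match_known()].
#' @param tags Tag table with per-library counts.
#' @return Data frame `mature`, `offset5`, `offset3`, per-library counts and
#'   `total`, one row per observed (mature, offset pair).
#' @export
end_variants <- function(assignments, tags) {
  cols <- grep("^count_", names(tags), value = TRUE)
  if (nrow(assignments) == 0)
    return(data.frame(mature = character(0), offset5 = integer(0),
                      offset3 = integer(0), total = numeric(0)))
  cnt <- tags[match(assignments$tag, tags$sequence), cols, drop = FALSE]
  key <- interaction(assignments$mature, assignments$offset5,
                     assignments$offset3, drop = TRUE)
  agg <- stats::aggregate(cnt, by = list(key = key), FUN = sum)
  first <- assignments[match(agg$key, key), c("mature", "offset5", "offset3")]
  out <- cbind(first, agg[, cols, drop = FALSE])
  out$total <- rowSums(out[, cols, drop = FALSE])
  out <- out[order(out$mature, out$offset5, out$offset3), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Family table with member counts and the dominant member
#'
#' @param records Per-mature record table from [match_known()] (needs `name`,
#'   `family` and `count_` columns).
#' @return Data frame `family`, `n_members`, `total`, `dominant` (the
#'   highest-count member) and `dominant_total`.
#' @export
assign_family <- function(records) {
  cols <- grep("^count_", names(records), value = TRUE)
  tot <- rowSums(records[, cols, drop = FALSE])
  sp <- split(seq_len(nrow(records)), records$family)
  out <- lapply(names(sp), function(f) {
    rows <- sp[[f]]
    dom <- rows[order(-tot[rows], records$name[rows])][1]
    data.frame(family = f, n_members = length(rows), total = sum(tot[rows]),
               dominant = records$name[dom], dominant_total = tot[dom],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(-out$total, out$family), , drop = FALSE]
}
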