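#' Clean raw small-RNA reads and account for every read
#'
#' Trims the 3' adapter, removes contaminants and length-filtered reads, and
#' tallies each read into exactly one accounting category, mirroring the
#' standard sequencing summary: `Total_read`, `High_quality`, `Adaptor3_null`,
#' `Insert_null`, `Adaptor5_contaminants`, `Small_than_18 nt`, `PolyA`,
#' `Clean_reads`.
#'
#' The 3' adapter is located at the leftmost position where its prefix matches
#' the read with at least `min_overlap` nt of overlap and at most `max_mm`
#' mismatches. Categories are assigned with a fixed precedence so that they
#' are disjoint: polyA (insert at least `polya_frac` A after trimming), then
#' 5'-adapter contaminant (insert begins with the first `adapter5_prefix` nt
#' of the 5' adapter), then missing 3' adapter, then empty insert, then
#' too-short insert, then clean. No quality model is applied: every read
#' counts as high quality. A trimmed insert longer than `max_len` is treated
#' as lacking an admissible 3' adapter.
#'
#' @param reads Character vector of read sequences, or a path to a FASTQ file
#'   (read with Biostrings). U and T are both accepted; sequences are stored
#'   in the DNA alphabet.
#' @param adapter3,adapter5 Adapter sequences (non-empty).
#' @param min_len,max_len Clean-insert length bounds (default 18-30 nt).
#' @param min_overlap,max_mm Adapter-match parameters.
#' @param polya_frac Minimum A fraction for the polyA category.
#' @param adapter5_prefix Number of leading 5'-adapter nt checked for the
#'   contaminant category.
#' @return A list with `inserts` (clean insert sequences), `stats` (a
#'   `clean_stats` object), and `categories` (per-read category labels).
#' @examples
#' r <- clean_reads(paste0("ACGTACGTACGTACGTACGTAC", "TCGTATGCCGTCTT"),
#'                  adapter3 = "TCGTATGCCGTCTTCTGCTTG",
#'                  adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC")
#' r$inserts
#' @export
clean_reads <- function(reads, adapter3, adapter5, min_len = 18L, max_len = 30L,
                        min_overlap = 6L, max_mm = 1L, polya_frac = 0.9,
                        adapter5_prefix = 8L) {
  stopifnot(nchar(adapter3) > 0, nchar(adapter5) > 0)
  if (length(reads) == 1 && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  reads <- toupper(chartr("uU", "TT", reads))
  n <- length(reads)
  stats_names <- c("total_read", "high_quality", "adaptor3_null", "insert_null",
                   "adaptor5_contaminants", "small_than_18nt", "polya",
                   "clean_reads")
  if (n == 0) {
    stats <- as.list(stats::setNames(rep(0L, length(stats_names)), stats_names))
    class(stats) <- "clean_stats"
    return(list(inserts = character(0), stats = stats, categories = character(0)))
  }
  adapter3 <- toupper(chartr("uU", "TT", adapter3))
  adapter5 <- toupper(chartr("uU", "TT", adapter5))
  pos <- locate_adapter_cpp(reads, adapter3, as.integer(min_overlap),
                            as.integer(max_mm))
  has_adapter <- pos > 0L
  insert <- ifelse(has_adapter, substr(reads, 1L, pos - 1L), reads)
  ilen <- nchar(insert)
  a_frac <- ifelse(ilen > 0,
                   nchar(gsub("[^A]", "", insert)) / ilen, 0)
  p5 <- substr(adapter5, 1L, adapter5_prefix)
  contam <- ilen >= adapter5_prefix & startsWith(insert, p5)

  category <- rep("clean", n)
  category[ilen < min_len] <- "small_than_18nt"
  category[ilen == 0L] <- "insert_null"
  category[!has_adapter | ilen > max_len] <- "adaptor3_null"
  category[contam] <- "adaptor5_contaminants"
  category[a_frac >= polya_frac & ilen > 0L] <- "polya"

  stats <- list(
    total_read            = n,
    high_quality          = n,
    adaptor3_null         = sum(category == "adaptor3_null"),
    insert_null           = sum(category == "insert_null"),
    adaptor5_contaminants = sum(category == "adaptor5_contaminants"),
    small_than_18nt       = sum(category == "small_than_18nt"),
    polya                 = sum(category == "polya"),
    clean_reads           = sum(category == "clean")
  )
  class(stats) <- "clean_stats"
  list(inserts = unname(insert[category == "clean"]), stats = stats,
       categories = category)
}

#' @export
#' @method as.data.frame clean_stats
as.data.frame.clean_stats <- function(x, ...) {
  data.frame(
    Type = c("Total_read", "High_quality", "Adaptor3_null", "Insert_null",
             "Adaptor5_contaminants", "Small_than_18 nt", "PolyA",
             "Clean_reads"),
    Count = c(x$total_read, x$high_quality, x$adaptor3_null, x$insert_null,
              x$adaptor5_contaminants, x$small_than_18nt, x$polya,
              x$clean_reads),
    stringsAsFactors = FALSE
  )
}

#' @export
print.clean_stats <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Collapse inserts into unique tags with counts
#'
#' @param inserts Character vector of clean insert sequences.
#' @param library Library identifier used to name the count column.
#' @return A data frame (`sequence`, `count_<library>`) sorted by sequence.
#' @examples
#' collapse_tags(c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT"), "fetal")
#' @export
collapse_tags <- function(inserts, library = "lib1") {
  if (length(inserts) == 0) {
    out <- data.frame(sequence = character(0), count = integer(0))
    names(out)[2] <- paste0("count_", library)
    return(out)
  }
  tb <- table(inserts)
  out <- data.frame(sequence = names(tb), count = as.integer(tb),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  names(out)[2] <- paste0("count_", library)
  out
}

#' Merge per-library tag tables into one table of unique tags
#'
#' @param tag_tables Named list of [collapse_tags()] outputs (one per library).
#' @return A data frame with `sequence` and one `count_<library>` column per
#'   library (0 where a tag is absent from a library).
#' @export
merge_tag_tables <- function(tag_tables) {
  stopifnot(length(tag_tables) >= 1)
  out <- Reduce(function(a, b) merge(a, b, by = "sequence", all = TRUE),
                tag_tables)
  cnt <- grep("^count_", names(out))
  for (k in cnt) out[[k]][is.na(out[[k]])] <- 0L
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count matrix of a tag or record table
#'
#' @param tags Data frame with one or more `count_<library>` columns.
#' @return Numeric matrix of the count columns.
#' @export
tag_counts <- function(tags) {
  cols <- grep("^count_", names(tags), value = TRUE)
  if (length(cols) == 0) stop("tag table has no count_ columns")
  as.matrix(tags[, cols, drop = FALSE])
}

#' Length distribution of unique tags
#'
#' @param tags A tag table ([collapse_tags()] or [merge_tag_tables()] output).
#' @return A data frame with `length`, `total` (summed read counts over all
#'   libraries) and `unique` (number of distinct tags) per length.
#' @export
length_histogram <- function(tags) {
  if (nrow(tags) == 0)
    return(data.frame(length = integer(0), total = integer(0),
                      unique = integer(0)))
  len <- nchar(tags$sequence)
  tot <- rowSums(tag_counts(tags))
  agg <- stats::aggregate(cbind(total = tot, unique = 1L),
                          by = list(length = len), FUN = sum)
  agg[order(agg$length), , drop = FALSE]
}

#' Common and library-specific tags of two libraries
#'
#' Summarises the overlap structure of two tag sets: how many unique
#' sequences (and how many reads) are shared and how many are specific to
#' each library.
#'
#' @param tags_a,tags_b Single-library tag tables.
#' @return A data frame with rows `common`, `a_specific`, `b_specific` and
#'   columns for unique counts/fractions and total read counts/fractions.
#' @export
library_overlap <- function(tags_a, tags_b) {
  ca <- tag_counts(tags_a)[, 1]
  cb <- tag_counts(tags_b)[, 1]
  common <- intersect(tags_a$sequence, tags_b$sequence)
  a_only <- setdiff(tags_a$sequence, tags_b$sequence)
  b_only <- setdiff(tags_b$sequence, tags_a$sequence)
  names(ca) <- tags_a$sequence
  names(cb) <- tags_b$sequence
  uniq <- c(common = length(common), a_specific = length(a_only),
            b_specific = length(b_only))
  tot <- c(common = sum(ca[common]) + sum(cb[common]),
           a_specific = sum(ca[a_only]), b_specific = sum(cb[b_only]))
  data.frame(
    set = names(uniq),
    unique = as.integer(uniq),
    unique_fraction = if (sum(uniq) > 0) uniq / sum(uniq) else rep(0, 3),
    total = as.numeric(tot),
    total_fraction = if (sum(tot) > 0) tot / sum(tot) else rep(0, 3),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
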