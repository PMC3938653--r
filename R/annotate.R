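#' RNA class vocabulary and default classification priority
#'
#' Order in which overlapping annotation classes win when a mapped tag touches
#' more than one feature. Exon and intron classes are split into sense and
#' antisense at classification time.
#'
#' @return Character vector of class labels, highest priority first.
#' @export
default_class_priority <- function() {
  c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "srpRNA",
    "repeat", "exon", "intron")
}

#' Read or validate a BED-like annotation table
#'
#' @param annotation A data frame (`chrom`, `start`, `end`, `strand`, `class`,
#'   optional `name`; 0-based half-open coordinates) or a path to a TSV file
#'   with those columns.
#' @return The validated annotation data frame.
#' @export
read_annotation <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1) {
    annotation <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  }
  need <- c("chrom", "start", "end", "strand", "class")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(annotation$class), default_class_priority())
  if (length(bad) > 0)
    stop("unknown annotation class label(s): ", paste(bad, collapse = ", "))
  if (any(annotation$end <= annotation$start))
    stop("annotation intervals must be non-empty (0-based half-open)")
  annotation
}

annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand,
    class = annotation$class
  )
}

#' Classify genome-mapped tags into RNA classes
#'
#' Each mapped tag receives exactly one class: the highest-priority class
#' among annotation features overlapping any of its hit loci by at least one
#' nucleotide. Non-coding RNA and repeat classes require strand agreement;
#' exon and intron overlaps are split into `Exon_sense`/`Exon_antisense` and
#' `Intron_sense`/`Intron_antisense` by strand agreement. Tags overlapping
#' nothing are `unknown`.
#'
#' @param hits Hit table from [map_tags()].
#' @param annotation Annotation data frame or TSV path (see
#'   [read_annotation()]).
#' @param tags Optional tag table with per-library counts, used for the
#'   summary totals.
#' @param priority Class priority, highest first.
#' @return A list with `classes` (data frame `tag`, `class`) and `summary`
#'   (per-class unique tag and total read counts per library, a distribution
#'   table of the genome-mapped reads).
#' @export
classify_tags <- function(hits, annotation, tags = NULL,
                          priority = default_class_priority()) {
  annotation <- read_annotation(annotation)
  stopifnot(all(annotation$class %in% priority))
  tag_seqs <- unique(hits$tag)
  cls <- rep("unknown", length(tag_seqs))
  names(cls) <- tag_seqs
  if (nrow(hits) > 0 && nrow(annotation) > 0) {
    hg <- GenomicRanges::GRanges(
      seqnames = hits$chrom,
      ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
      strand = hits$strand
    )
    ag <- annotation_granges(annotation)
    ov <- GenomicRanges::findOverlaps(hg, ag, minoverlap = 1L,
                                      ignore.strand = TRUE)
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      feat_class <- annotation$class[sh]
      sense <- hits$strand[qh] == annotation$strand[sh]
      stranded <- !(feat_class %in% c("exon", "intron"))
      keep <- !stranded | sense
      qh <- qh[keep]; sh <- sh[keep]
      feat_class <- feat_class[keep]; sense <- sense[keep]
      if (length(qh) > 0) {
        rank <- match(feat_class, priority)
        # per (tag, class) pick the best-ranked class; remember sense-ness
        df <- data.frame(tag = hits$tag[qh], rank = rank, sense = sense,
                         stringsAsFactors = FALSE)
        # antisense ranks just below sense within the same class so a sense
        # overlap wins over an antisense overlap of the same class
        df$score <- df$rank * 2L + as.integer(!df$sense)
        best <- stats::aggregate(score ~ tag, data = df, FUN = min)
        cl <- priority[best$score %/% 2L]
        anti <- best$score %% 2L == 1L
        split_cls <- cl %in% c("exon", "intron")
        cl[split_cls] <- paste0(
          toupper(substr(cl[split_cls], 1, 1)),
          substr(cl[split_cls], 2, nchar(cl[split_cls])),
          ifelse(anti[split_cls], "_antisense", "_sense")
        )
        cls[best$tag] <- cl
      }
    }
  }
  classes <- data.frame(tag = tag_seqs, class = unname(cls),
                        stringsAsFactors = FALSE)
  summary <- class_summary(classes, tags, priority)
  list(classes = classes, summary = summary)
}

class_summary <- function(classes, tags = NULL,
                          priority = default_class_priority()) {
  lab <- setdiff(priority, c("exon", "intron"))
  row_order <- c("Total", sort(c(
    lab, "Exon_sense", "Exon_antisense", "Intron_sense", "Intron_antisense"
  ), method = "radix"), "unknown")
  row_order <- unique(row_order)
  out <- data.frame(class = row_order, unique = 0L, stringsAsFactors = FALSE)
  ucount <- table(classes$class)
  out$unique[match(names(ucount), out$class)] <- as.integer(ucount)
  out$unique[out$class == "Total"] <- nrow(classes)
  if (!is.null(tags)) {
    cols <- grep("^count_", names(tags), value = TRUE)
    cnt <- tags[match(classes$tag, tags$sequence), cols, drop = FALSE]
    cnt[is.na(cnt)] <- 0L
    for (cc in cols) {
      colname <- sub("^count_", "total_", cc)
      tot <- tapply(cnt[[cc]], classes$class, sum)
      out[[colname]] <- 0
      out[[colname]][match(names(tot), out$class)] <- as.numeric(tot)
      out[[colname]][out$class == "Total"] <- sum(cnt[[cc]])
    }
  }
  out
}

#' Load a miRBase-style mature + precursor reference
#'
#' Mature and precursor sequences are linked by name: each mature is matched
#' to the precursor whose name is a prefix of the mature name (case
#' insensitive), and must occur within its precursor sequence.
#'
#' @param mature FASTA path or named character vector of mature sequences.
#' @param precursor FASTA path or named character vector of precursors.
#' @param family Optional named character vector mapping mature names to
#'   family names; missing families are parsed from the name stem.
#' @return An object of class `mirna_reference`: data frame `mature` with
#'   columns `name`, `sequence`, `precursor`, `start`, `end` (1-based position
#'   of the mature within the precursor), `family`, plus `precursors` (named
#'   vector).
#' @export
load_mirna_reference <- function(mature, precursor, family = NULL) {
  read_fa <- function(x) {
    if (length(x) == 1 && is.null(names(x)) && file.exists(x)) {
      ss <- Biostrings::readBStringSet(x)
      x <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    }
    stats::setNames(toupper(chartr("uU", "TT", x)), names(x))
  }
  mat <- read_fa(mature)
  pre <- read_fa(precursor)
  pre_for <- function(nm) {
    hit <- names(pre)[startsWith(tolower(nm), tolower(names(pre)))]
    if (length(hit) == 0) return(NA_character_)
    hit[which.max(nchar(hit))]
  }
  prec_name <- vapply(names(mat), pre_for, "")
  if (anyNA(prec_name))
    stop("no precursor found for mature(s): ",
         paste(names(mat)[is.na(prec_name)], collapse = ", "))
  pos <- mapply(function(m, p) as.integer(regexpr(m, pre[[p]], fixed = TRUE)),
                mat, prec_name)
  if (any(pos < 1))
    stop("mature sequence absent from its precursor: ",
         paste(names(mat)[pos < 1], collapse = ", "))
  fam <- if (is.null(family)) parse_family(names(mat)) else
    ifelse(is.na(family[names(mat)]), parse_family(names(mat)),
           family[names(mat)])
  out <- list(
    mature = data.frame(
      name = names(mat), sequence = unname(mat),
      precursor = unname(prec_name), start = unname(pos),
      end = unname(pos + nchar(mat) - 1L), family = unname(fam),
      stringsAsFactors = FALSE
    ),
    precursors = pre
  )
  class(out) <- "mirna_reference"
  out
}

# family from the name stem: strip species prefix, arm suffix, paralog letters
parse_family <- function(names) {
  x <- sub("^[A-Za-z]{2,4}-", "", names)       # species prefix e.g. bta-
  x <- sub("-(5p|3p)$", "", x)
  hit <- regexpr("^(let|miR|mir)-?[0-9]+", x, ignore.case = TRUE)
  out <- x
  out[hit > 0] <- regmatches(x, hit)
  out
}

#' Assign tags to known miRNAs
#'
#' A tag is assigned to a reference mature miRNA when it occurs exactly
#' (substring match) within the mature's precursor and its position overlaps
#' the annotated mature span within `tolerance` nucleotides at each end, so
#' templated isomiRs are captured. When a tag satisfies this for several
#' matures, the mature with the higher total expression wins; remaining ties
#' break to the lexicographically first name.
#'
#' @param tags Tag table with per-library counts.
#' @param reference A [load_mirna_reference()] object.
#' @param tolerance Maximum |5' offset| and |3' offset| (default 4 nt).
#' @return A list with `assignments` (data frame `tag`, `mature`, `offset5`,
#'   `offset3`) and `records` (per-mature counts per library, a
#'   `mirna_record` table with `name`, `family`, `precursor`, counts).
#' @export
match_known <- function(tags, reference, tolerance = 4L) {
  stopifnot(inherits(reference, "mirna_reference"))
  cols <- grep("^count_", names(tags), value = TRUE)
  seqs <- tags$sequence
  pre <- reference$precursors
  mt <- reference$mature
  asg <- vector("list", length(seqs))
  # locate each tag in each precursor (exact substring)
  for (p in names(pre)) {
    hit <- which(vapply(seqs, function(s) grepl(s, pre[[p]], fixed = TRUE),
                        TRUE, USE.NAMES = FALSE))
    if (length(hit) == 0) next
    mrows <- which(mt$precursor == p)
    for (i in hit) {
      st <- as.integer(regexpr(seqs[i], pre[[p]], fixed = TRUE))
      en <- st + nchar(seqs[i]) - 1L
      for (r in mrows) {
        o5 <- st - mt$start[r]
        o3 <- en - mt$end[r]
        if (abs(o5) <= tolerance && abs(o3) <= tolerance) {
          asg[[i]] <- rbind(asg[[i]],
                            data.frame(tag = seqs[i], mature = mt$name[r],
                                       offset5 = o5, offset3 = o3,
                                       stringsAsFactors = FALSE))
        }
      }
    }
  }
  # resolve multi-mature tags: expression then name
  expr0 <- rowSums(tags[, cols, drop = FALSE])
  names(expr0) <- tags$sequence
  mat_expr <- stats::setNames(rep(0, nrow(mt)), mt$name)
  for (a in asg) if (!is.null(a) && nrow(a) == 1)
    mat_expr[a$mature] <- mat_expr[a$mature] + expr0[a$tag[1]]
  resolved <- lapply(asg, function(a) {
    if (is.null(a)) return(NULL)
    if (nrow(a) == 1) return(a)
    e <- mat_expr[a$mature]
    a <- a[order(-e, a$mature), , drop = FALSE]
    a[1, , drop = FALSE]
  })
  assignments <- do.call(rbind, resolved[!vapply(resolved, is.null, TRUE)])
  if (is.null(assignments))
    assignments <- data.frame(tag = character(0), mature = character(0),
                              offset5 = integer(0), offset3 = integer(0),
                              stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  records <- mt[, c("name", "family", "precursor", "sequence")]
  for (cc in cols) {
    tot <- tapply(tags[[cc]][match(assignments$tag, tags$sequence)],
                  assignments$mature, sum)
    records[[cc]] <- 0
    records[[cc]][match(names(tot), records$name)] <- as.numeric(tot)
  }
  list(assignments = assignments, records = records)
}

#' Per-chromosome miRNA locus density
#'
#' @param loci Data frame with a `chrom` column (one row per miRNA locus).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @return Data frame `chrom`, `n_loci`, `length_mbp`, `loci_per_mbp`.
#' @examples
#' chromosome_density(data.frame(chrom = rep("chrX", 38)),
#'                    c(chrX = 149e6))
#' @export
chromosome_density <- function(loci, chrom_lengths) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  n <- table(factor(loci$chrom, levels = names(chrom_lengths)))
  data.frame(
    chrom = names(chrom_lengths),
    n_loci = as.integer(n),
    length_mbp = as.numeric(chrom_lengths) / 1e6,
    loci_per_mbp = as.integer(n) / (as.numeric(chrom_lengths) / 1e6),
    stringsAsFactors = FALSE
  )
}
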