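#' Build a k-mer index of a genome
#'
#' Indexes every length-`k` substring of each chromosome (forward strand) in a
#' hash environment, enabling exact full-length lookup of small RNA tags on
#' both strands. Positions containing non-ACGT characters are excluded.
#'
#' @param genome Named character vector of chromosome sequences (DNA
#'   alphabet), or a path to a genome FASTA file.
#' @param k K-mer size; must not exceed the shortest tag to be mapped.
#' @return An object of class `genome_index`.
#' @export
build_index <- function(genome, k = 12L) {
  if (length(genome) == 1 && is.null(names(genome)) && file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
    genome <- stats::setNames(as.character(gs), names(gs))
  }
  stopifnot(!is.null(names(genome)), k >= 4L)
  genome <- toupper(genome)
  # positions across chromosomes encoded as chrom_index * offset_base + start
  offset_base <- max(nchar(genome)) + 1
  kml <- list()
  posl <- list()
  for (ci in seq_along(genome)) {
    s <- genome[[ci]]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    keep <- !grepl("[^ACGT]", kmers)
    kml[[ci]] <- kmers[keep]
    posl[[ci]] <- ci * offset_base + as.double(starts[keep])
  }
  sp <- split(unlist(posl, use.names = FALSE),
              unlist(kml, use.names = FALSE))
  idx <- list2env(sp, hash = TRUE, size = 2L * length(sp),
                  envir = new.env(parent = emptyenv()))
  structure(list(index = idx, genome = genome, k = as.integer(k),
                 chroms = names(genome), offset_base = offset_base),
            class = "genome_index")
}

# exact forward-strand hits of one tag; returns data.frame(chrom, start)
lookup_tag <- function(index, tag) {
  k <- index$k
  if (nchar(tag) < k) stop("tag shorter than index k-mer size")
  seed <- substr(tag, 1L, k)
  cand <- index$index[[seed]]
  if (is.null(cand)) return(NULL)
  ci <- as.integer(cand %/% index$offset_base)
  st <- as.integer(cand %% index$offset_base)
  len <- nchar(tag)
  ok <- substring(index$genome[ci], st, st + len - 1L) == tag
  if (!any(ok)) return(NULL)
  data.frame(chrom = index$chroms[ci[ok]], start = st[ok] - 1L,
             stringsAsFactors = FALSE)
}

#' Map tags to the genome by exact full-length match
#'
#' Every tag is searched on both strands (reverse-complement hits are reported
#' on the minus strand with forward-strand coordinates). Tags with more hits
#' than `max_hits` are retained and flagged (`multi_hit`), so downstream
#' novel-miRNA prediction can exclude them; counts are never split across
#' loci.
#'
#' @param tags A tag table (see [collapse_tags()]) or character vector of tag
#'   sequences.
#' @param index A [build_index()] result.
#' @param max_hits Multi-hit flag threshold (default 10).
#' @return A list with `hits` (data frame: `tag`, `chrom`, `start`, `end`,
#'   `strand`, `hit_count`, `multi_hit`; coordinates 0-based half-open) and
#'   `unmapped` (character vector of unmapped tag sequences).
#' @export
map_tags <- function(tags, index, max_hits = 10L) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  seqs <- unique(toupper(chartr("uU", "TT", seqs)))
  res <- vector("list", length(seqs))
  unmapped <- character(0)
  for (i in seq_along(seqs)) {
    tg <- seqs[i]
    fw <- lookup_tag(index, tg)
    rc <- lookup_tag(index, revcomp_dna(tg))
    len <- nchar(tg)
    hit <- NULL
    if (!is.null(fw))
      hit <- data.frame(tag = tg, chrom = fw$chrom, start = fw$start,
                        end = fw$start + len, strand = "+",
                        stringsAsFactors = FALSE)
    if (!is.null(rc))
      hit <- rbind(hit, data.frame(tag = tg, chrom = rc$chrom, start = rc$start,
                                   end = rc$start + len, strand = "-",
                                   stringsAsFactors = FALSE))
    if (is.null(hit)) unmapped <- c(unmapped, tg) else res[[i]] <- hit
  }
  hits <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(hits))
    hits <- data.frame(tag = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), stringsAsFactors = FALSE)
  nh <- table(hits$tag)
  hits$hit_count <- as.integer(nh[hits$tag])
  hits$multi_hit <- hits$hit_count > max_hits
  rownames(hits) <- NULL
  list(hits = hits, unmapped = unmapped)
}
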