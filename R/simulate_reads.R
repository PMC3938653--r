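# Read simulation for one library: per-read category/variant ground truth,
# with every read validated through the package's own trimmer so planted
# category counts are recovered exactly by clean_reads().

# validated variant caches avoid re-checking the same (mature, offset/edit)
variant_ok <- function(tag, own_prec, all_prec, all_mat) {
  n_own <- lengths(regmatches(own_prec, gregexpr(tag, own_prec, fixed = TRUE)))
  if (n_own != 1) return(FALSE)
  others <- setdiff(all_prec, own_prec)
  if (any(vapply(others, grepl, TRUE, pattern = tag, fixed = TRUE)))
    return(FALSE)
  !(tag %in% all_mat)
}

edit_ok <- function(tag, own, all_prec, all_mat) {
  if (any(vapply(all_prec, grepl, TRUE, pattern = tag, fixed = TRUE)))
    return(FALSE)
  same_len <- all_mat[nchar(all_mat) == nchar(tag) & all_mat != own]
  if (length(same_len) > 0) {
    tg <- strsplit(tag, "")[[1]]
    for (m in same_len) {
      if (sum(tg != strsplit(m, "")[[1]]) <= 1) return(FALSE)
    }
  }
  TRUE
}

# insert-level read checks shared by the generators: trims back to itself,
# contains no internal adapter-like match (so trimming is idempotent), not a
# 5'-contaminant, not polyA
insert_clean_ok <- function(tags, a3, a5p) {
  n <- nchar(tags)
  pos <- locate_adapter_cpp(paste0(tags, a3), a3, 6L, 1L)
  bare <- locate_adapter_cpp(tags, a3, 6L, 1L)
  afrac <- nchar(gsub("[^A]", "", tags)) / pmax(n, 1L)
  pos == n + 1L & bare == 0L & !startsWith(tags, a5p) & afrac < 0.9 &
    !grepl("[^ACGT]", tags)
}

blank_meta <- function(n) {
  data.frame(category = character(n), source = character(n),
             mature_name = rep(NA_character_, n),
             variant = rep(NA_character_, n), offset5 = rep(NA_integer_, n),
             offset3 = rep(NA_integer_, n), edit_pos = rep(NA_integer_, n),
             edit_from = rep(NA_character_, n),
             edit_to = rep(NA_character_, n), stringsAsFactors = FALSE)
}

#' Simulate an adapter-ligated small RNA read library
#'
#' Draws per-mature read counts (Poisson around the planted expression
#' means), splits them into canonical, templated-isomiR and single-edit
#' reads, adds star-arm reads, decoy-locus reads, reads from unannotated
#' genome regions, and the junk categories exercised by [clean_reads()]
#' (adapterless, empty-insert, 5'-contaminant, too-short and polyA reads).
#' Inserts are ligated to the 3' adapter and truncated to the read length;
#' insert lengths peak at 22 nt (the canonical mature length mode). Every
#' read is validated through the package's trimmer so its realised cleaning
#' category equals the planted one; random reads are resampled until they
#' validate. The same truth and library always produce identical output.
#'
#' @param truth A [build_genome()] object.
#' @param library One of `truth$libraries`.
#' @return A list with `reads` (named character vector), `truth_table`
#'   (per-read data frame: `name`, `category`, `source`, `mature_name`,
#'   `variant`, `offset5`, `offset3`, `edit_pos`, `edit_from`, `edit_to`)
#'   and `library`.
#' @export
simulate_reads <- function(truth, library) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!library %in% truth$libraries)
    stop("unknown library identifier: ", library,
         " (expected one of: ", paste(truth$libraries, collapse = ", "), ")")
  lib_i <- match(library, truth$libraries)
  with_seed((truth$seed %% 100000L) * 101L + lib_i, {
    cfg <- truth
    hp <- truth$hairpins
    all_prec <- chartr("U", "T", hp$precursor)
    all_mat <- chartr("U", "T", hp$mature)
    a3 <- cfg$adapter3
    a5p <- substr(chartr("U", "T", cfg$adapter5), 1, 8)

    blocks <- list()
    push <- function(tags, meta) {
      stopifnot(length(tags) == nrow(meta))
      if (length(tags) == 0) return(invisible())
      blocks[[length(blocks) + 1L]] <<- list(tags = tags, meta = meta)
      invisible()
    }

    # --- mature-arm reads -------------------------------------------------
    iso_cache <- new.env(parent = emptyenv())
    edit_cache <- new.env(parent = emptyenv())
    w5 <- c(0.05, 0.15, 0.60, 0.15, 0.05) # 5' offsets -2..2
    w3 <- c(0.10, 0.20, 0.25, 0.30, 0.15) # 3' offsets -2..2
    if (nrow(hp) > 0) {
      means <- truth$expression[[paste0("mean_", library)]]
      for (m in seq_len(nrow(hp))) {
        cnt <- if (cfg$exact_counts) round(means[m]) else
          stats::rpois(1, means[m])
        if (cnt == 0) next
        mat_dna <- all_mat[m]
        prec_dna <- all_prec[m]
        k <- nchar(mat_dna)
        u <- stats::runif(cnt)
        n_edit <- sum(u < cfg$edit_rate)
        n_iso <- sum(u >= cfg$edit_rate & u < cfg$edit_rate + cfg$isomir_rate)
        n_can <- cnt - n_edit - n_iso

        # isomiRs: vectorised rejection sampling of valid templated offsets
        iso_tag <- character(0); iso_o5 <- iso_o3 <- integer(0)
        todo <- n_iso
        for (iter in 1:60) {
          if (todo == 0) break
          o5 <- sample(-2:2, todo, replace = TRUE, prob = w5)
          o3 <- sample(-2:2, todo, replace = TRUE, prob = w3)
          len <- k - o5 + o3
          cand <- !(o5 == 0 & o3 == 0) & len >= 18 & len <= 30
          keys <- paste(o5, o3)
          for (ky in unique(keys[cand])) {
            if (is.null(iso_cache[[paste(m, ky)]])) {
              oo <- as.integer(strsplit(ky, " ")[[1]])
              tg <- substr(prec_dna, hp$mature_start[m] + oo[1],
                           hp$mature_end[m] + oo[2])
              ok <- variant_ok(tg, prec_dna, all_prec, all_mat) &&
                insert_clean_ok(tg, a3, a5p)
              iso_cache[[paste(m, ky)]] <- if (ok) tg else NA_character_
            }
          }
          tags <- rep(NA_character_, todo)
          tags[cand] <- vapply(keys[cand], function(ky)
            iso_cache[[paste(m, ky)]], "")
          okv <- !is.na(tags)
          iso_tag <- c(iso_tag, tags[okv])
          iso_o5 <- c(iso_o5, o5[okv])
          iso_o3 <- c(iso_o3, o3[okv])
          todo <- todo - sum(okv)
        }
        n_can <- n_can + todo # unresolvable isomiRs fall back to canonical

        # single-base edits: vectorised rejection over (position, to-base)
        ed_tag <- character(0); ed_pos <- integer(0)
        ed_from <- ed_to <- character(0)
        todo <- n_edit
        mat_chars <- strsplit(mat_dna, "")[[1]]
        for (iter in 1:60) {
          if (todo == 0) break
          pos <- sample.int(k, todo, replace = TRUE)
          to <- vapply(pos, function(p)
            sample(setdiff(c("A", "C", "G", "T"), mat_chars[p]), 1), "")
          keys <- paste(pos, to)
          for (ky in unique(keys)) {
            if (is.null(edit_cache[[paste(m, ky)]])) {
              parts <- strsplit(ky, " ")[[1]]
              p <- as.integer(parts[1])
              tg <- mat_dna
              substr(tg, p, p) <- parts[2]
              ok <- edit_ok(tg, mat_dna, all_prec, all_mat) &&
                insert_clean_ok(tg, a3, a5p)
              edit_cache[[paste(m, ky)]] <- if (ok) tg else NA_character_
            }
          }
          tags <- vapply(keys, function(ky) edit_cache[[paste(m, ky)]], "")
          okv <- !is.na(tags)
          ed_tag <- c(ed_tag, tags[okv])
          ed_pos <- c(ed_pos, pos[okv])
          ed_from <- c(ed_from, mat_chars[pos[okv]])
          ed_to <- c(ed_to, to[okv])
          todo <- todo - sum(okv)
        }
        n_can <- n_can + todo

        n_star <- stats::rpois(1, cfg$star_frac * means[m])
        mname <- hp$mature_name[m]
        mm <- blank_meta(n_can + length(iso_tag) + length(ed_tag) + n_star)
        mm$category <- "clean"
        mm$source <- c(rep("mature", n_can + length(iso_tag) + length(ed_tag)),
                       rep("star", n_star))
        mm$mature_name <- mname
        mm$variant <- c(rep("canonical", n_can),
                        rep("isomir", length(iso_tag)),
                        rep("edit", length(ed_tag)), rep("star", n_star))
        mm$offset5 <- c(rep(0L, n_can), iso_o5,
                        rep(0L, length(ed_tag)), rep(NA_integer_, n_star))
        mm$offset3 <- c(rep(0L, n_can), iso_o3,
                        rep(0L, length(ed_tag)), rep(NA_integer_, n_star))
        mm$edit_pos <- c(rep(NA_integer_, n_can + length(iso_tag)), ed_pos,
                         rep(NA_integer_, n_star))
        mm$edit_from <- c(rep(NA_character_, n_can + length(iso_tag)),
                          chartr("T", "U", ed_from), rep(NA_character_, n_star))
        mm$edit_to <- c(rep(NA_character_, n_can + length(iso_tag)),
                        chartr("T", "U", ed_to), rep(NA_character_, n_star))
        push(c(rep(mat_dna, n_can), iso_tag, ed_tag,
               rep(chartr("U", "T", hp$star[m]), n_star)), mm)
      }
    }

    # --- decoy reads ------------------------------------------------------
    ann <- truth$annotation
    if (nrow(ann) > 0 && cfg$decoy_frac > 0) {
      n_dec <- stats::rbinom(1, cfg$library_size, cfg$decoy_frac)
      tags <- rep(NA_character_, n_dec)
      src <- rep(NA_character_, n_dec)
      var <- rep(NA_character_, n_dec)
      todo <- seq_len(n_dec)
      for (iter in 1:60) {
        if (length(todo) == 0) break
        d <- sample(nrow(ann), length(todo), replace = TRUE,
                    prob = truth$decoy_weights)
        len <- sample(18:28, length(todo), replace = TRUE,
                      prob = c(2, 3, 5, 8, 10, 8, 6, 4, 3, 2, 1))
        len <- pmin(len, ann$end[d] - ann$start[d])
        lo <- ann$start[d] + 1L
        hi <- ann$end[d] - len + 1L
        st <- lo + floor(stats::runif(length(todo)) * (hi - lo + 1L))
        tg <- substring(unname(truth$genome[ann$chrom[d]]), st, st + len - 1L)
        antisense <- ann$class[d] %in% c("exon", "intron") &
          stats::runif(length(todo)) < 0.25
        flip <- xor(ann$strand[d] == "-", antisense)
        tg[flip] <- revcomp_dna(tg[flip])
        ok <- insert_clean_ok(tg, a3, a5p)
        tags[todo[ok]] <- tg[ok]
        src[todo[ok]] <- ann$name[d][ok]
        var[todo[ok]] <- ifelse(antisense[ok], "antisense", "sense")
        todo <- todo[!ok]
      }
      keep <- !is.na(tags)
      mm <- blank_meta(sum(keep))
      mm$category <- "clean"
      mm$source <- "decoy"
      mm$mature_name <- src[keep]
      mm$variant <- var[keep]
      push(tags[keep], mm)
    }

    # --- reads from unannotated regions (mapped but unclassified) ---------
    fr <- truth$free_regions
    if (!is.null(fr) && nrow(fr) > 0 && cfg$unknown_frac > 0) {
      n_unk <- stats::rbinom(1, cfg$library_size, cfg$unknown_frac)
      tags <- rep(NA_character_, n_unk)
      todo <- seq_len(n_unk)
      for (iter in 1:60) {
        if (length(todo) == 0) break
        reg <- sample(nrow(fr), length(todo), replace = TRUE)
        len <- sample(20:24, length(todo), replace = TRUE)
        lo <- fr$start[reg] + 1L
        hi <- fr$end[reg] - len
        st <- lo + floor(stats::runif(length(todo)) * (hi - lo + 1L))
        tg <- substring(unname(truth$genome[fr$chrom[reg]]), st, st + len - 1L)
        flip <- stats::runif(length(todo)) < 0.5
        tg[flip] <- revcomp_dna(tg[flip])
        ok <- insert_clean_ok(tg, a3, a5p)
        tags[todo[ok]] <- tg[ok]
        todo <- todo[!ok]
      }
      keep <- !is.na(tags)
      mm <- blank_meta(sum(keep))
      mm$category <- "clean"
      mm$source <- "unknown_region"
      push(tags[keep], mm)
    }

    # --- clean reads: ligate adapter, truncate, final validation ----------
    ins <- unlist(lapply(blocks, `[[`, "tags"), use.names = FALSE)
    meta_df <- do.call(rbind, lapply(blocks, `[[`, "meta"))
    if (is.null(meta_df)) meta_df <- blank_meta(0)
    clean_full <- substr(paste0(ins, a3, strrep("A", cfg$read_length)), 1,
                         cfg$read_length)
    if (length(ins) > 0) {
      chk <- clean_reads(clean_full, a3, cfg$adapter5)
      if (any(chk$categories != "clean") ||
          !identical(chk$inserts, ins))
        stop("internal error: planted clean reads failed trimming validation")
    }

    # --- junk categories --------------------------------------------------
    junk_reads <- character(0)
    junk_cat <- character(0)
    add_junk <- function(n, category, gen) {
      if (n == 0) return(invisible())
      reads <- rep(NA_character_, n)
      todo <- n
      for (iter in 1:100) {
        if (todo == 0) break
        cand <- vapply(seq_len(todo), function(i) gen(), "")
        cr <- clean_reads(cand, a3, cfg$adapter5)
        ok <- cr$categories == category
        reads[which(is.na(reads))[seq_len(sum(ok))]] <- cand[ok]
        todo <- todo - sum(ok)
      }
      reads <- reads[!is.na(reads)]
      junk_reads <<- c(junk_reads, reads)
      junk_cat <<- c(junk_cat, rep(category, length(reads)))
      invisible()
    }
    draw <- function(frac) stats::rbinom(1, cfg$library_size, frac)
    rl <- cfg$read_length
    add_junk(draw(cfg$frac_adaptor3_null), "adaptor3_null",
             function() rand_dna(rl))
    add_junk(draw(cfg$frac_insert_null), "insert_null",
             function() substr(paste0(a3, strrep("A", rl)), 1, rl))
    add_junk(draw(cfg$frac_adaptor5), "adaptor5_contaminants", function()
      substr(paste0(a5p, rand_dna(sample(10:14, 1)), a3, strrep("A", rl)),
             1, rl))
    add_junk(draw(cfg$frac_short), "small_than_18nt", function()
      substr(paste0(rand_dna(sample(8:17, 1)), a3, strrep("A", rl)), 1, rl))
    add_junk(draw(cfg$frac_polya), "polya", function() {
      x <- strsplit(strrep("A", 22), "")[[1]]
      if (stats::runif(1) < 0.3) x[sample(22, 1)] <- sample(c("C", "G"), 1)
      substr(paste0(paste(x, collapse = ""), a3, strrep("A", rl)), 1, rl)
    })

    # --- shuffle and name -------------------------------------------------
    reads <- c(clean_full, junk_reads)
    tt <- rbind(meta_df, {
      jm <- blank_meta(length(junk_cat))
      jm$category <- junk_cat
      jm$source <- rep("junk", length(junk_cat))
      jm
    })
    ord <- sample(length(reads))
    reads <- reads[ord]
    tt <- tt[ord, , drop = FALSE]
    nm <- sprintf("%s_%06d", library, seq_along(reads))
    names(reads) <- nm
    tt <- cbind(data.frame(name = nm, stringsAsFactors = FALSE), tt)
    rownames(tt) <- NULL
    list(reads = reads, truth_table = tt, library = library)
  })
}

#' Write simulated reads as FASTQ
#'
#' @param sim A [simulate_reads()] result.
#' @param path Output FASTQ path.
#' @return `path`, invisibly. Qualities are constant high quality (no quality
#'   model is simulated).
#' @export
write_fastq <- function(sim, path) {
  dss <- Biostrings::DNAStringSet(sim$reads)
  qual <- Biostrings::PhredQuality(
    Biostrings::BStringSet(strrep("I", nchar(sim$reads))))
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(dss, qual), path)
  invisible(path)
}

#' Write the genome of a synthetic truth object as FASTA
#'
#' @param truth A [build_genome()] object.
#' @param path Output FASTA path.
#' @export
write_genome <- function(truth, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(truth$genome), path)
  invisible(path)
}
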