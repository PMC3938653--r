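# Synthetic small RNA-seq study generator: a genome with planted miRNA
# hairpins and decoy ncRNA loci, a miRBase-style reference, transcripts with
# planted target sites, and two adapter-ligated read libraries with per-read
# ground truth (category, isomiR offsets, single-base edits, fold changes).

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rand_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

#' Default configuration of the synthetic study generator
#'
#' Values emulate the structure of a two-library (fetal vs adult) small
#' RNA-seq experiment: insert lengths peaking at 22 nt, strong mature-arm
#' read stacks with a minority of star reads, mostly-3' isomiR end offsets,
#' rare single-base edits, a small complement of adapter/contaminant/short/
#' polyA junk reads, and planted four-fold expression changes for a subset of
#' miRNAs.
#'
#' @return Named list of generator parameters.
#' @export
synthetic_defaults <- function() {
  list(
    libraries = c("fetal", "adult"),
    library_size = 1e5,
    read_length = 36L,
    adapter3 = "TCGTATGCCGTCTTCTGCTTG",
    adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
    isomir_rate = 0.15,
    edit_rate = 0.03,
    star_frac = 0.08,
    de_frac = 0.3,
    de_fold = 4,
    known_frac = 0.7,
    first_nt_u_prob = 0.6,
    decoy_frac = 0.15,
    unknown_frac = 0.03,
    frac_adaptor3_null = 0.004,
    frac_insert_null = 0.002,
    frac_adaptor5 = 0.003,
    frac_short = 0.004,
    frac_polya = 0.002,
    n_repeat_loci = 0L,
    n_transcripts = 12L,
    transcript_len = c(400L, 800L),
    target_mirnas = 3L,
    sites_per_mirna = 3L,
    exact_counts = FALSE
  )
}

# one admissible planted hairpin, rejection-sampled against the novel-miRNA
# criteria under the package's own folding engine
sample_hairpin <- function(cfg, reject_mature = character(0),
                           reject_precursors = character(0), max_try = 400L) {
  for (try in seq_len(max_try)) {
    k <- sample(20:22, 1, prob = c(0.15, 0.25, 0.60))
    first <- if (stats::runif(1) < cfg$first_nt_u_prob) "U" else
      sample(c("A", "C", "G"), 1)
    rest <- sample(c("A", "C", "G", "U"), k - 1, replace = TRUE,
                   prob = c(0.22, 0.28, 0.28, 0.22))
    mature <- paste(c(first, rest), collapse = "")
    loop <- paste(sample(c("A", "C", "G", "U"), sample(10:14, 1),
                         replace = TRUE), collapse = "")
    arm <- strsplit(revcomp_rna(mature), "")[[1]]
    # 1-3 arm mutations: real precursor duplexes are imperfect, and a perfect
    # palindrome would make the mature map to both genome strands
    n_mut <- sample(1:3, 1)
    at <- sample(4:(k - 3), n_mut)
    for (p in at) arm[p] <- sample(setdiff(c("A", "C", "G", "U"), arm[p]), 1)
    arm <- paste(arm, collapse = "")
    arm_choice <- sample(c("5p", "3p"), 1)
    pad5 <- paste(sample(c("A", "C", "G", "U"), 2, TRUE), collapse = "")
    pad3 <- paste(sample(c("A", "C", "G", "U"), 2, TRUE), collapse = "")
    if (arm_choice == "5p") {
      prec <- paste0(pad5, mature, loop, arm, pad3)
      mstart <- 3L
    } else {
      prec <- paste0(pad5, arm, loop, mature, pad3)
      mstart <- 2L + nchar(arm) + nchar(loop) + 1L
    }
    mend <- mstart + k - 1L
    mature_dna <- chartr("U", "T", mature)
    prec_dna <- chartr("U", "T", prec)
    # structural acceptance: all novel-miRNA criteria on the naked precursor
    fr <- fold(prec)
    ev <- evaluate_hairpin(fr, mstart, mend)
    if (!ev$verdict) next
    # read-level sanity: mature/star inserts must trim cleanly and avoid the
    # contaminant/polyA categories
    star_dna <- chartr("U", "T", ev$star)
    a5p <- substr(chartr("U", "T", cfg$adapter5), 1, 8)
    if (!all(insert_clean_ok(c(mature_dna, star_dna), cfg$adapter3, a5p)))
      next
    if (mature_dna %in% reject_mature) next
    if (length(reject_precursors) > 0 &&
        (any(vapply(reject_precursors, grepl, TRUE, pattern = mature_dna,
                    fixed = TRUE)) ||
         any(vapply(reject_mature, grepl, TRUE, x = prec_dna,
                    fixed = TRUE))))
      next
    return(list(precursor = prec, mature = mature, arm = arm_choice,
                mature_start = mstart, mature_end = mend, star = ev$star,
                star_start = ev$star_start, star_end = ev$star_end,
                mfe = fr$mfe, mfei = fr$mfei))
  }
  stop("failed to sample an admissible hairpin after ", max_try, " attempts")
}

place_locus <- function(occupied, chrom_lens, len, margin, gap_hairpin,
                        gap_other, is_hairpin, max_try = 500L) {
  for (try in seq_len(max_try)) {
    chrom <- sample(names(chrom_lens), 1)
    lo <- margin
    hi <- chrom_lens[[chrom]] - len - margin
    if (hi <= lo) next
    start <- sample(lo:hi, 1)
    end <- start + len
    occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
    ok <- TRUE
    if (nrow(occ) > 0) {
      gap <- ifelse(occ$is_hairpin | is_hairpin, gap_hairpin, gap_other)
      ok <- all(start >= occ$end + gap | end <= occ$start - gap)
    }
    if (ok) return(list(chrom = chrom, start = start, end = end))
  }
  NULL
}

#' Build a synthetic genome with planted miRNA hairpins and decoy loci
#'
#' Generates `n_chrom` random chromosomes and embeds (i) `n_hairpins`
#' miRNA precursors, each rejection-sampled until it passes every
#' novel-miRNA criterion under the package's folding engine (MFE <= -18
#' kcal/mol, MFEI > 0.85, mature in one arm, 2-nt 3' overhang star, no
#' bulge > 4 nt in the mature:star duplex, mature 20-22 nt, mature:star
#' hybridisation < -20 kcal/mol), with at least 150 nt of flank inside the
#' chromosome; and (ii) `n_decoys` decoy ncRNA/repeat/exon/intron loci.
#' Everything downstream of the genome (reference, expression table,
#' transcripts with target sites) is generated here too, so a single seed
#' reproduces the whole study.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length (nt), scalar or per-chromosome vector.
#' @param n_hairpins Number of planted hairpin loci.
#' @param n_decoys Number of decoy loci.
#' @param seed Integer RNG seed; the same seed reproduces the object
#'   byte-for-byte.
#' @param config Generator parameters, see [synthetic_defaults()]; partial
#'   lists override the defaults element-wise.
#' @return An object of class `synthetic_truth`. Key elements: `genome`
#'   (named chromosome sequences), `hairpins` (planted precursor table),
#'   `annotation` (decoy loci, BED-like 0-based half-open), `mirna_annotation`
#'   (precursor loci), `expression` (per-mature expected counts per library
#'   and true fold change), `transcripts` and `target_truth`, plus all
#'   generator parameters.
#' @export
build_genome <- function(n_chrom = 2L, chrom_len = 1e5, n_hairpins = 30L,
                         n_decoys = 20L, seed = 1L, config = list()) {
  cfg <- utils::modifyList(synthetic_defaults(), config)
  with_seed(seed, {
    chrom_lens <- stats::setNames(rep_len(as.integer(chrom_len), n_chrom),
                                  paste0("chr", seq_len(n_chrom)))
    genome <- vapply(chrom_lens, rand_dna, "")

    # --- hairpins ---------------------------------------------------------
    hp <- list()
    if (n_hairpins > 0) {
      for (h in seq_len(n_hairpins)) {
        hp[[h]] <- sample_hairpin(
          cfg,
          reject_mature = vapply(hp, function(x) chartr("U", "T", x$mature), ""),
          reject_precursors = vapply(hp, function(x)
            chartr("U", "T", x$precursor), "")
        )
      }
    }
    # family structure: occasional multi-member families (shared name stem)
    fam_of <- integer(0)
    if (n_hairpins > 0) {
      fam <- 0L
      while (length(fam_of) < n_hairpins) {
        fam <- fam + 1L
        size <- sample(c(1L, 1L, 1L, 1L, 2L, 3L), 1)
        fam_of <- c(fam_of, rep(fam, size))
      }
      fam_of <- fam_of[seq_len(n_hairpins)]
      suffix <- unlist(lapply(split(seq_along(fam_of), fam_of), function(ix) {
        if (length(ix) == 1) "" else letters[seq_along(ix)]
      }), use.names = FALSE)
      prec_names <- sprintf("syn-mir-%03d%s", fam_of, suffix)
    } else prec_names <- character(0)

    # --- placement --------------------------------------------------------
    occupied <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), is_hairpin = logical(0),
                           stringsAsFactors = FALSE)
    hp_loci <- list()
    for (h in seq_along(hp)) {
      len <- nchar(hp[[h]]$precursor)
      loc <- place_locus(occupied, chrom_lens, len, margin = 200L,
                         gap_hairpin = 400L, gap_other = 50L,
                         is_hairpin = TRUE)
      if (is.null(loc))
        stop("placement failure for hairpin locus ", prec_names[h])
      strand <- sample(c("+", "-"), 1)
      prec_dna <- chartr("U", "T", hp[[h]]$precursor)
      ins <- if (strand == "+") prec_dna else revcomp_dna(prec_dna)
      substr(genome[[loc$chrom]], loc$start + 1L, loc$end) <- ins
      occupied <- rbind(occupied, data.frame(
        chrom = loc$chrom, start = loc$start, end = loc$end,
        is_hairpin = TRUE, stringsAsFactors = FALSE))
      hp_loci[[h]] <- data.frame(chrom = loc$chrom, start = loc$start,
                                 end = loc$end, strand = strand,
                                 stringsAsFactors = FALSE)
    }

    decoy_classes <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "srpRNA",
                       "repeat", "exon", "intron")
    decoy_len <- c(rRNA = 120L, tRNA = 75L, snRNA = 100L, snoRNA = 90L,
                   scRNA = 110L, srpRNA = 130L, `repeat` = 160L, exon = 200L,
                   intron = 240L)
    dec <- list()
    if (n_decoys > 0) {
      cls <- sample(decoy_classes, n_decoys, replace = TRUE)
      if (n_decoys >= 2) { cls[1] <- "exon"; cls[2] <- "intron" }
      for (d in seq_len(n_decoys)) {
        len <- decoy_len[[cls[d]]]
        loc <- place_locus(occupied, chrom_lens, len, margin = 20L,
                           gap_hairpin = 400L, gap_other = 50L,
                           is_hairpin = FALSE)
        if (is.null(loc))
          stop("placement failure for decoy locus dec-", d)
        occupied <- rbind(occupied, data.frame(
          chrom = loc$chrom, start = loc$start, end = loc$end,
          is_hairpin = FALSE, stringsAsFactors = FALSE))
        dec[[d]] <- data.frame(
          name = sprintf("dec-%03d", d), class = cls[d], chrom = loc$chrom,
          start = loc$start, end = loc$end,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      }
    }
    annotation <- if (length(dec) > 0) do.call(rbind, dec) else
      data.frame(name = character(0), class = character(0),
                 chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)

    repeat_tag <- NULL
    if (cfg$n_repeat_loci > 0) {
      rt <- rand_dna(22)
      rt_loci <- list()
      for (r in seq_len(cfg$n_repeat_loci)) {
        loc <- place_locus(occupied, chrom_lens, 22L, margin = 20L,
                           gap_hairpin = 400L, gap_other = 50L,
                           is_hairpin = FALSE)
        if (is.null(loc)) stop("placement failure for repeat copy ", r)
        substr(genome[[loc$chrom]], loc$start + 1L, loc$end) <- rt
        occupied <- rbind(occupied, data.frame(
          chrom = loc$chrom, start = loc$start, end = loc$end,
          is_hairpin = FALSE, stringsAsFactors = FALSE))
        rt_loci[[r]] <- data.frame(chrom = loc$chrom, start = loc$start,
                                   end = loc$end, stringsAsFactors = FALSE)
      }
      repeat_tag <- list(sequence = rt, loci = do.call(rbind, rt_loci))
    }

    # --- hairpin table ----------------------------------------------------
    hairpins <- if (n_hairpins > 0) {
      cbind(
        data.frame(
          name = prec_names,
          mature_name = sprintf("syn-miR-%s-%s",
                                sub("^syn-mir-", "", prec_names),
                                vapply(hp, `[[`, "", "arm")),
          family = parse_family(prec_names), stringsAsFactors = FALSE),
        do.call(rbind, lapply(hp_loci, identity)),
        data.frame(
          arm = vapply(hp, `[[`, "", "arm"),
          precursor = vapply(hp, `[[`, "", "precursor"),
          mature = vapply(hp, `[[`, "", "mature"),
          mature_start = vapply(hp, `[[`, 1L, "mature_start"),
          mature_end = vapply(hp, `[[`, 1L, "mature_end"),
          star = vapply(hp, `[[`, "", "star"),
          star_start = vapply(hp, `[[`, 1L, "star_start"),
          star_end = vapply(hp, `[[`, 1L, "star_end"),
          mfe = vapply(hp, `[[`, 1.0, "mfe"),
          mfei = vapply(hp, `[[`, 1.0, "mfei"), stringsAsFactors = FALSE)
      )
    } else {
      data.frame(name = character(0), mature_name = character(0),
                 family = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 arm = character(0), precursor = character(0),
                 mature = character(0), mature_start = integer(0),
                 mature_end = integer(0), star = character(0),
                 star_start = integer(0), star_end = integer(0),
                 mfe = numeric(0), mfei = numeric(0), stringsAsFactors = FALSE)
    }
    if (nrow(hairpins) > 0) {
      n_known <- round(cfg$known_frac * nrow(hairpins))
      hairpins$known <- seq_len(nrow(hairpins)) %in%
        sample(nrow(hairpins), n_known)
    } else hairpins$known <- logical(0)
    mirna_annotation <- hairpins[, c("name", "chrom", "start", "end",
                                     "strand", "known"), drop = FALSE]
    if (nrow(mirna_annotation) > 0) mirna_annotation$class <- "miRNA"
    else mirna_annotation$class <- character(0)

    # --- expression table with planted fold changes -----------------------
    expression <- NULL
    if (n_hairpins > 0) {
      lam <- 10^stats::runif(n_hairpins, log10(5), log10(2500))
      n_de <- round(cfg$de_frac * n_hairpins)
      de_idx <- if (n_de > 0) sample(n_hairpins, n_de) else integer(0)
      up <- de_idx[seq_len(floor(n_de / 2))]
      down <- setdiff(de_idx, up)
      mf <- ma <- lam
      mf[up] <- lam[up] * cfg$de_fold
      ma[down] <- lam[down] * cfg$de_fold
      junk <- cfg$frac_adaptor3_null + cfg$frac_insert_null +
        cfg$frac_adaptor5 + cfg$frac_short + cfg$frac_polya
      budget <- cfg$library_size *
        (1 - junk - cfg$decoy_frac - cfg$unknown_frac) /
        (1 + cfg$star_frac)
      sc <- budget / mean(c(sum(mf), sum(ma)))
      mf <- pmax(1, mf * sc)
      ma <- pmax(1, ma * sc)
      expression <- data.frame(
        mature_name = hairpins$mature_name,
        mean_fetal = mf, mean_adult = ma, fc = mf / ma,
        is_de = seq_len(n_hairpins) %in% de_idx, stringsAsFactors = FALSE)
      names(expression)[2:3] <- paste0("mean_", cfg$libraries)
    } else {
      expression <- data.frame(mature_name = character(0),
                               mean_fetal = numeric(0),
                               mean_adult = numeric(0), fc = numeric(0),
                               is_de = logical(0), stringsAsFactors = FALSE)
      names(expression)[2:3] <- paste0("mean_", cfg$libraries)
    }
    decoy_weights <- if (n_decoys > 0) 10^stats::runif(n_decoys, 0, 2) else
      numeric(0)

    # --- free regions for "unknown"-class reads ---------------------------
    free_regions <- do.call(rbind, lapply(names(chrom_lens), function(ch) {
      occ <- occupied[occupied$chrom == ch, , drop = FALSE]
      occ <- occ[order(occ$start), , drop = FALSE]
      bounds <- c(200L, rbind(occ$start - 200L, occ$end + 200L),
                  chrom_lens[[ch]] - 200L)
      st <- bounds[seq(1, length(bounds), 2)]
      en <- bounds[seq(2, length(bounds), 2)]
      keep <- en - st > 60
      data.frame(chrom = ch, start = st[keep], end = en[keep],
                 stringsAsFactors = FALSE)
    }))

    # --- transcripts with planted perfect target sites --------------------
    transcripts <- character(0)
    target_truth <- data.frame(transcript = character(0),
                               mature_name = character(0), start = integer(0),
                               end = integer(0), stringsAsFactors = FALSE)
    if (cfg$n_transcripts > 0) {
      tl <- sample(cfg$transcript_len[1]:cfg$transcript_len[2],
                   cfg$n_transcripts, replace = TRUE)
      transcripts <- stats::setNames(vapply(tl, rand_dna, ""),
                                     sprintf("tx-%03d", seq_len(cfg$n_transcripts)))
      n_tm <- min(cfg$target_mirnas, n_hairpins)
      if (n_tm > 0) {
        used <- lapply(transcripts, function(x) integer(0))
        tt <- list()
        for (m in seq_len(n_tm)) {
          site <- revcomp_dna(chartr("U", "T", hairpins$mature[m]))
          L <- nchar(site)
          for (s in seq_len(cfg$sites_per_mirna)) {
            for (try in 1:200) {
              tx <- sample(names(transcripts), 1)
              pos <- sample(seq_len(nchar(transcripts[[tx]]) - L + 1L), 1)
              span <- pos:(pos + L - 1L)
              if (length(intersect(span, used[[tx]])) > 0) next
              substr(transcripts[[tx]], pos, pos + L - 1L) <- site
              used[[tx]] <- c(used[[tx]], span)
              tt[[length(tt) + 1L]] <- data.frame(
                transcript = tx, mature_name = hairpins$mature_name[m],
                start = pos, end = pos + L - 1L, stringsAsFactors = FALSE)
              break
            }
          }
        }
        if (length(tt) > 0) target_truth <- do.call(rbind, tt)
      }
    }

    out <- c(list(
      genome = genome, chrom_lengths = chrom_lens, hairpins = hairpins,
      annotation = annotation, mirna_annotation = mirna_annotation,
      expression = expression, decoy_weights = decoy_weights,
      free_regions = free_regions, repeat_tag = repeat_tag,
      transcripts = transcripts, target_truth = target_truth,
      seed = as.integer(seed)), cfg)
    class(out) <- "synthetic_truth"
    out
  })
}

#' miRBase-style reference of the planted miRNAs
#'
#' @param truth A [build_genome()] object.
#' @param known_only Restrict the reference to the `known` subset of planted
#'   hairpins (the remainder emulate undiscovered miRNAs for novel-locus
#'   prediction).
#' @return A [load_mirna_reference()] object for the planted matures and
#'   precursors.
#' @export
truth_reference <- function(truth, known_only = FALSE) {
  hp <- truth$hairpins
  if (known_only) hp <- hp[hp$known, , drop = FALSE]
  if (nrow(hp) == 0) stop("truth contains no planted hairpins")
  load_mirna_reference(
    mature = stats::setNames(hp$mature, hp$mature_name),
    precursor = stats::setNames(hp$precursor, hp$name)
  )
}
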