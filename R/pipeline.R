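# Pipeline orchestration: run every stage in order on a config, write
# stage artifacts to an output directory, and record a deterministic
# manifest. The configuration can come from a YAML file or an R list; when
# no read files are given the synthetic generator produces the study.

#' Default pipeline configuration
#'
#' @return Named list understood by [run_pipeline()]. Paths may be `NULL`,
#'   in which case the synthetic generator (seeded by `seed`) provides the
#'   genome, annotation, reference and reads.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    n_chrom = 2L, chrom_len = 1e5, n_hairpins = 30L, n_decoys = 20L,
    synthetic = list(),
    reads = NULL,            # named list/vector: one FASTQ per library
    genome = NULL, annotation = NULL,
    mature = NULL, precursor = NULL, transcripts = NULL,
    flank = 150L, max_hits = 10L, mfei_min = 0.85, dg_max = -18,
    dg_duplex_max = -20, max_bulge = 4L,
    p_threshold = 0.01, fc_bounds = c(0.5, 2),
    mfe_ratio_min = 0.75, target_mirnas = 2L,
    min_len = 18L, max_len = 30L
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  utils::modifyList(pipeline_defaults(), config)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full small RNA-seq analysis pipeline
#'
#' Stages, in order: simulate (when no reads are configured), clean, map,
#' annotate, profile (known miRNAs, isomiRs, edits, families), predict-novel,
#' de, targets. Each stage writes its tables under `outdir`, and a manifest
#' records the package version, seed, configuration checksum and the MD5 of
#' every output file, so two runs with identical config and seed produce
#' byte-identical manifests.
#'
#' @param config A configuration list or YAML path (see
#'   [pipeline_defaults()]).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results and
#'   `manifest` (data frame).
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("mirpipe_run_")) {
  cfg <- read_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  files <- character(0)
  state <- list()

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  # --- inputs / simulate --------------------------------------------------
  truth <- NULL
  if (is.null(cfg$reads)) {
    truth <- run_stage("simulate", function() {
      build_genome(cfg$n_chrom, cfg$chrom_len, cfg$n_hairpins, cfg$n_decoys,
                   seed = cfg$seed, config = cfg$synthetic)
    })
    state$truth <- truth
    genome <- truth$genome
    known_loci <- truth$mirna_annotation[truth$mirna_annotation$known, ,
                                         drop = FALSE]
    annotation <- rbind(
      truth$annotation[, c("chrom", "start", "end", "strand", "class", "name")],
      known_loci[, c("chrom", "start", "end", "strand", "class", "name")])
    reference <- if (any(truth$hairpins$known))
      truth_reference(truth, known_only = TRUE) else NULL
    transcripts <- truth$transcripts
    sims <- lapply(truth$libraries, function(lb) simulate_reads(truth, lb))
    names(sims) <- truth$libraries
    read_sets <- lapply(sims, function(s) unname(s$reads))
    libs <- truth$libraries
    files <- c(files, write_tsv(truth$hairpins[, c("name", "mature_name",
                                                   "chrom", "start", "end",
                                                   "strand", "arm")],
                                file.path(outdir, "planted_hairpins.tsv")))
  } else {
    genome <- cfg$genome
    if (length(genome) == 1 && is.null(names(genome))) {
      gs <- Biostrings::readDNAStringSet(genome)
      genome <- stats::setNames(as.character(gs), names(gs))
    }
    annotation <- read_annotation(cfg$annotation)
    reference <- if (!is.null(cfg$mature))
      load_mirna_reference(cfg$mature, cfg$precursor) else NULL
    transcripts <- cfg$transcripts
    libs <- names(cfg$reads)
    if (is.null(libs)) stop("configuration error: reads must be named by library")
    read_sets <- lapply(cfg$reads, function(p) {
      if (!file.exists(p)) stop("configuration error: missing reads file ", p)
      as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
    })
  }
  if (is.null(genome)) stop("configuration error: no genome available")

  a3 <- if (!is.null(truth)) truth$adapter3 else synthetic_defaults()$adapter3
  a5 <- if (!is.null(truth)) truth$adapter5 else synthetic_defaults()$adapter5

  # --- clean --------------------------------------------------------------
  cleaned <- run_stage("clean", function() {
    lapply(stats::setNames(libs, libs), function(lb)
      clean_reads(read_sets[[lb]], a3, a5, min_len = cfg$min_len,
                  max_len = cfg$max_len))
  })
  state$clean_stats <- lapply(cleaned, `[[`, "stats")
  per_lib_tags <- lapply(libs, function(lb)
    collapse_tags(cleaned[[lb]]$inserts, lb))
  names(per_lib_tags) <- libs
  tags <- merge_tag_tables(per_lib_tags)
  state$tags <- tags
  for (lb in libs)
    files <- c(files, write_tsv(as.data.frame(cleaned[[lb]]$stats),
                                file.path(outdir, paste0("clean_stats_", lb,
                                                         ".tsv"))))
  files <- c(files, write_tsv(tags, file.path(outdir, "tags.tsv")),
             write_tsv(length_histogram(tags),
                       file.path(outdir, "length_histogram.tsv")))
  if (length(libs) == 2)
    files <- c(files, write_tsv(library_overlap(per_lib_tags[[1]],
                                                per_lib_tags[[2]]),
                                file.path(outdir, "library_overlap.tsv")))

  # --- map ----------------------------------------------------------------
  mapped <- run_stage("map", function() {
    idx <- build_index(genome, k = 12L)
    map_tags(tags, idx, max_hits = cfg$max_hits)
  })
  state$hits <- mapped$hits
  state$unmapped <- mapped$unmapped
  files <- c(files, write_tsv(mapped$hits, file.path(outdir, "hits.tsv")))

  # --- annotate -----------------------------------------------------------
  classified <- run_stage("annotate", function()
    classify_tags(mapped$hits, annotation, tags = tags))
  state$classes <- classified$classes
  state$class_summary <- classified$summary
  files <- c(files, write_tsv(classified$summary,
                              file.path(outdir, "class_distribution.tsv")))

  # --- profile: known miRNAs, variants, edits, families -------------------
  profiled <- run_stage("profile", function() {
    if (is.null(reference)) return(NULL)
    known <- match_known(tags, reference)
    assigned <- known$assignments$tag
    unann <- tags[!tags$sequence %in% assigned, , drop = FALSE]
    expr <- stats::setNames(rowSums(tag_counts(known$records)),
                            known$records$name)
    list(known = known,
         edits = detect_edits(unann, reference, mature_expression = expr),
         variants = end_variants(known$assignments, tags),
         families = assign_family(known$records),
         bias = first_nt_bias(tags))
  })
  state$profile <- profiled
  if (!is.null(profiled)) {
    files <- c(files,
               write_tsv(profiled$known$records,
                         file.path(outdir, "known_mirnas.tsv")),
               write_tsv(profiled$edits, file.path(outdir, "edits.tsv")),
               write_tsv(profiled$variants,
                         file.path(outdir, "end_variants.tsv")),
               write_tsv(profiled$families, file.path(outdir, "families.tsv")),
               write_tsv(profiled$bias, file.path(outdir, "first_nt_bias.tsv")))
  }

  # --- predict-novel ------------------------------------------------------
  novel <- run_stage("predict-novel", function() {
    known_tags <- if (!is.null(profiled)) profiled$known$assignments$tag else
      character(0)
    unann_hits <- mapped$hits[!mapped$hits$tag %in% known_tags, , drop = FALSE]
    predict_novel(tags, unann_hits, genome, classes = classified$classes,
                  flank = cfg$flank, max_hits = cfg$max_hits,
                  mfei_min = cfg$mfei_min, dg_max = cfg$dg_max,
                  dg_duplex_max = cfg$dg_duplex_max,
                  max_bulge = cfg$max_bulge)
  })
  state$novel <- novel
  files <- c(files, write_tsv(novel, file.path(outdir, "novel_mirnas.tsv")),
             write_gff3(novel, file.path(outdir, "novel_mirnas.gff3")))

  # --- differential expression --------------------------------------------
  de <- run_stage("de", function() {
    if (is.null(profiled) || length(libs) != 2) return(NULL)
    counts <- profiled$known$records
    names(counts)[names(counts) == "name"] <- "name"
    totals <- vapply(libs, function(lb) cleaned[[lb]]$stats$clean_reads, 1)
    differential_expression(counts, total_clean = totals,
                            p_threshold = cfg$p_threshold,
                            fc_bounds = cfg$fc_bounds)
  })
  state$de <- de
  if (!is.null(de))
    files <- c(files, write_tsv(de, file.path(outdir, "diff_expr.tsv")))

  # --- targets ------------------------------------------------------------
  targets <- run_stage("targets", function() {
    if (is.null(transcripts) || length(transcripts) == 0 || is.null(reference))
      return(NULL)
    n_tm <- min(cfg$target_mirnas, nrow(reference$mature))
    res <- lapply(seq_len(n_tm), function(m) {
      tb <- scan_targets(reference$mature$sequence[m], transcripts,
                         mfe_ratio_min = cfg$mfe_ratio_min)
      if (nrow(tb) > 0) cbind(mirna = reference$mature$name[m], tb) else NULL
    })
    res <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
    if (is.null(res)) data.frame() else res
  })
  state$targets <- targets
  if (!is.null(targets) && nrow(targets) > 0)
    files <- c(files, write_tsv(targets, file.path(outdir, "targets.tsv")))

  # --- manifest -----------------------------------------------------------
  manifest <- data.frame(
    key = c("package_version", "seed", "config_md5", "stages",
            basename(files)),
    value = c(as.character(utils::packageVersion("mirpipe")),
              as.character(cfg$seed),
              digest_object(cfg),
              paste(stages, collapse = ","),
              unname(tools::md5sum(files))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  state$manifest <- manifest
  state$outdir <- outdir
  invisible(state)
}

# stable checksum of an R object via its serialization (version 2, so the
# hash is identical across sessions)
digest_object <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(raw, tf)
  unname(tools::md5sum(tf))
}

write_gff3 <- function(novel, path) {
  lines <- "##gff-version 3"
  if (nrow(novel) > 0) {
    lines <- c(lines, sprintf(
      "%s\tmirpipe\tpre_miRNA\t%d\t%d\t.\t%s\t.\tID=%s;mfei=%.3f;tier=%s",
      novel$chrom, novel$start + 1L, novel$end, novel$strand, novel$name,
      novel$mfei, novel$tier))
  }
  writeLines(lines, path)
  path
}

#' Publication-style summary tables of a pipeline run
#'
#' @param state A [run_pipeline()] result.
#' @return A list of data frames: `clean_stats` (per-library read
#'   accounting), `class_distribution` (per-class unique/total counts),
#'   `known_summary` (per-library known-miRNA tallies), `families`,
#'   `chromosome_density`.
#' @export
summary_tables <- function(state) {
  cs <- NULL
  if (!is.null(state$clean_stats)) {
    cs <- Reduce(function(a, b) merge(a, b, by = "Type", sort = FALSE),
                 lapply(names(state$clean_stats), function(lb) {
                   d <- as.data.frame(state$clean_stats[[lb]])
                   names(d)[2] <- paste0("Count_", lb)
                   d
                 }))
  }
  known <- NULL
  if (!is.null(state$profile)) {
    rec <- state$profile$known$records
    cols <- grep("^count_", names(rec), value = TRUE)
    known <- data.frame(
      library = sub("^count_", "", cols),
      matures_detected = vapply(cols, function(cc) sum(rec[[cc]] > 0), 1L),
      reads_matched = vapply(cols, function(cc) sum(rec[[cc]]), 1),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  dens <- NULL
  if (!is.null(state$truth) && nrow(state$truth$hairpins) > 0) {
    dens <- chromosome_density(state$truth$hairpins,
                               state$truth$chrom_lengths)
  }
  list(clean_stats = cs,
       class_distribution = state$class_summary,
       known_summary = known,
       families = if (!is.null(state$profile)) state$profile$families,
       chromosome_density = dens)
}

#' Dinucleotide shuffle of a genome
#'
#' Shuffles each chromosome preserving its exact dinucleotide composition by
#' the Altschul-Erickson method: a random "last edge" arborescence toward the
#' final base guarantees a valid Eulerian walk over the dinucleotide graph,
#' and the remaining successor edges are permuted uniformly. This is the
#' standard null genome for hairpin-prediction false-positive checks.
#'
#' @param genome Named chromosome sequences.
#' @param seed RNG seed.
#' @return Named shuffled chromosome sequences.
#' @export
dinucleotide_shuffle <- function(genome, seed = 1L) {
  with_seed(seed, vapply(genome, dinuc_shuffle_one, ""))
}

dinuc_shuffle_one <- function(s) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  if (n < 3) return(s)
  succ <- split(v[-1], v[-n]) # outgoing edges per vertex
  verts <- names(succ)
  f <- v[n]
  # random last-edge choice per vertex forming an arborescence toward f
  repeat {
    last <- vapply(verts, function(a) sample(succ[[a]], 1), "")
    ok <- TRUE
    for (a in verts) {
      if (a == f) next
      cur <- a
      seen <- character(0)
      while (cur %in% verts && cur != f && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- last[[cur]]
      }
      if (!identical(cur, f)) { ok <- FALSE; break }
    }
    if (ok) break
  }
  ordered <- stats::setNames(lapply(verts, function(a) {
    e <- succ[[a]]
    if (a == f) return(sample(e)) # the walk's end vertex needs no reservation
    i <- match(last[[a]], e)
    c(sample(e[-i]), last[[a]])
  }), verts)
  idx <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- v[1]
  cur <- v[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][idx[[cur]]]
    idx[[cur]] <- idx[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
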