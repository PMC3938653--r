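# shared small-scale synthetic study used by several test files; built once
# per test run (a few seconds) and memoised in the test environment

small_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- mirpipe::build_genome(
        n_chrom = 2, chrom_len = 3e4, n_hairpins = 8, n_decoys = 10,
        seed = 7, config = list(library_size = 2e4))
    cache
  }
})

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- small_truth()
      sims <- lapply(truth$libraries, function(lb)
        mirpipe::simulate_reads(truth, lb))
      names(sims) <- truth$libraries
      cleaned <- lapply(sims, function(s)
        mirpipe::clean_reads(unname(s$reads), truth$adapter3, truth$adapter5))
      tags <- mirpipe::merge_tag_tables(lapply(truth$libraries, function(lb)
        mirpipe::collapse_tags(cleaned[[lb]]$inserts, lb)))
      idx <- mirpipe::build_index(truth$genome, 12)
      mapped <- mirpipe::map_tags(tags, idx)
      cache <<- list(truth = truth, sims = sims, cleaned = cleaned,
                     tags = tags, index = idx, mapped = mapped)
    }
    cache
  }
})

decoy_annotation <- function(truth) {
  truth$annotation[, c("chrom", "start", "end", "strand", "class", "name")]
}

full_annotation <- function(truth) {
  rbind(decoy_annotation(truth),
        truth$mirna_annotation[, c("chrom", "start", "end", "strand",
                                   "class", "name")])
}
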