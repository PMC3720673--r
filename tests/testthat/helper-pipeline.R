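# Shared end-to-end run on the standard fixture design (10 families at copy
# numbers 1..10 plus 10 decoys of each class), evaluated with the default
# criteria (MFEI report-only). Cached per seed within a test file.

run_standard_bundle <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 101L) {
    key <- as.character(seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fx <- generate_fixture(fixture_spec(seed = seed))
    hits <- find_hits(fx$matures, fx$reads, search_config())
    cand <- classify_hits(hits, fx$reads, criteria = criteria_config())
    merged <- dplyr::left_join(fx$ground_truth, cand,
                               by = c("read_id", "mirna_name"))
    cache[[key]] <- list(fx = fx, hits = hits, cand = cand,
                         merged = merged)
    cache[[key]]
  }
})

# reduced design for fast property checks
run_small_bundle <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 103L) {
    key <- as.character(seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    spec <- fixture_spec(seed = seed,
                         implants = default_implants(4L, c(1L, 2L, 2L, 1L)),
                         decoys = default_decoys(2L),
                         n_background = 3L,
                         read_length_mean = 220, read_length_sd = 30)
    fx <- generate_fixture(spec)
    hits <- find_hits(fx$matures, fx$reads, search_config())
    cand <- classify_hits(hits, fx$reads,
                          criteria = criteria_config(enforce_mfei = TRUE))
    cache[[key]] <- list(fx = fx, hits = hits, cand = cand)
    cache[[key]]
  }
})

# a small designed read: background + embedded precursor, plus coordinates
embed_in_read <- function(pre_rna, left = 40L, right = 40L, strand = "+",
                          gc = 0.4) {
  pre <- rna_to_dna(pre_rna)
  insert <- if (strand == "-") reverse_complement(pre) else pre
  seqn <- paste0(random_dna_seq(left, gc), insert, random_dna_seq(right, gc))
  list(sequence = seqn, start = left + 1L,
       end = left + nchar(pre), strand = strand)
}
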