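test_that("count_mismatches is Hamming distance with N never matching", {
  expect_equal(count_mismatches("ACGU", "ACGU"), 0L)
  expect_equal(count_mismatches("ACGU", "AGGU"), 1L)
  expect_equal(count_mismatches("ACGN", "ACGA"), 1L)
  expect_equal(count_mismatches("NNNN", "NNNN"), 4L)
  expect_error(count_mismatches("ACG", "ACGU"), "length")
})

test_that("word index covers every exact occurrence once", {
  reads <- tibble::tibble(id = "r1", sequence = "ACGTACG")
  fwd <- build_word_index(reads, 7L, strands = "forward")
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$word, "ACGTACG")
  expect_equal(fwd$start, 1L)
  short <- build_word_index(tibble::tibble(id = "r", sequence = "ACGT"),
                            7L, strands = "forward")
  expect_equal(nrow(short), 0L)
  # posting count equals sum(len - w + 1) per scanned strand (N-free reads)
  withr::with_seed(8, {
    rds <- tibble::tibble(id = paste0("r", 1:5),
                          sequence = vapply(sample(20:120, 5),
                                            random_dna_seq, character(1)))
    w <- 7L
    expected <- sum(nchar(rds$sequence) - w + 1L)
    expect_equal(nrow(build_word_index(rds, w, strands = "forward")),
                 expected)
    expect_equal(nrow(build_word_index(rds, w, strands = "both")),
                 2L * expected)
  })
})

make_query <- function(seq, name = "sim-miR9001") {
  tibble::tibble(name = name, family = mirna_family(name), sequence = seq)
}

test_that("find_hits recovers implants within the mismatch budget", {
  withr::with_seed(21, {
    mature <- random_rna_seq(21)
    emb <- embed_in_read(mature, left = 30, right = 30)
    reads <- tibble::tibble(id = "r1", sequence = emb$sequence)
    hits <- find_hits(make_query(mature), reads, search_config())
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$mismatches, 0L)
    expect_equal(hits$read_start, 31L)
    expect_equal(hits$read_end, 51L)
    expect_equal(hits$matched_subsequence, rna_to_dna(mature))

    # 3 substitutions still found; 4 exceed the default budget
    mutate_at <- function(seq, pos) {
      ch <- strsplit(seq, "")[[1]]
      for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
      paste(ch, collapse = "")
    }
    dna <- rna_to_dna(mature)
    r3 <- tibble::tibble(id = "r3", sequence = paste0(
      random_dna_seq(25), mutate_at(dna, c(3, 10, 17)), random_dna_seq(25)))
    h3 <- find_hits(make_query(mature), r3, search_config())
    expect_equal(nrow(h3), 1L)
    expect_equal(h3$mismatches, 3L)
    r4 <- tibble::tibble(id = "r4", sequence = paste0(
      random_dna_seq(25), mutate_at(dna, c(3, 8, 13, 18)),
      random_dna_seq(25)))
    expect_equal(nrow(find_hits(make_query(mature), r4, search_config())),
                 0L)
  })
})

test_that("minus-strand hits mirror plus-strand coordinates", {
  withr::with_seed(22, {
    mature <- random_rna_seq(21)
    emb <- embed_in_read(mature, left = 40, right = 25, strand = "-")
    reads <- tibble::tibble(id = "r1", sequence = emb$sequence)
    hits <- find_hits(make_query(mature), reads, search_config())
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$strand, "-")
    expect_equal(hits$read_start, emb$start)
    expect_equal(hits$read_end, emb$end)
    expect_equal(hits$matched_subsequence, rna_to_dna(mature))
  })
})

test_that("find_hits equals the brute-force scan on random instances", {
  withr::with_seed(30, {
    for (k in 0:3) {
      matures <- tibble::tibble(
        name = paste0("sim-miR", 9000 + 1:4),
        family = paste0("miR", 9000 + 1:4),
        sequence = vapply(sample(18:26, 4, replace = TRUE),
                          random_rna_seq, character(1)))
      reads <- tibble::tibble(
        id = paste0("r", 1:3),
        sequence = vapply(sample(100:400, 3), random_dna_seq, character(1)))
      # implant mutated copies so the comparison is not vacuous
      for (qi in 1:4) {
        dna <- rna_to_dna(matures$sequence[qi])
        ch <- strsplit(dna, "")[[1]]
        nmut <- sample(0:4, 1)
        for (p in sample(seq_along(ch), nmut)) {
          ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[sample.int(3, 1)]
        }
        ins <- paste(ch, collapse = "")
        if (sample(c(TRUE, FALSE), 1)) ins <- reverse_complement(ins)
        ri <- sample(1:3, 1)
        s <- reads$sequence[ri]
        pos <- sample.int(nchar(s) - nchar(ins), 1)
        substr(s, pos, pos + nchar(ins) - 1L) <- ins
        reads$sequence[ri] <- s
      }
      mine <- find_hits(matures, reads,
                        search_config(max_mismatches = k))
      ref <- oracle_hits(matures, reads, k)
      expect_setequal(hit_key(mine), hit_key(ref))
    }
  })
})

test_that("search is strand-symmetric and monotone in the mismatch cap", {
  withr::with_seed(31, {
    mature <- random_rna_seq(22)
    emb <- embed_in_read(mature, left = 50, right = 50)
    reads <- tibble::tibble(id = "r1", sequence = emb$sequence)
    rc_reads <- tibble::tibble(id = "r1",
                               sequence = reverse_complement(emb$sequence))
    q <- make_query(mature)
    h <- find_hits(q, reads, search_config())
    h_rc <- find_hits(q, rc_reads, search_config())
    expect_equal(nrow(h), nrow(h_rc))
    n <- nchar(emb$sequence)
    expect_equal(sort(h_rc$read_start), sort(n - h$read_end + 1L))
    expect_setequal(h_rc$strand, ifelse(h$strand == "+", "-", "+"))

    # monotonicity: the hit set can only grow with the budget
    prev <- character(0)
    for (k in 0:3) {
      hk <- find_hits(q, reads, search_config(max_mismatches = k))
      expect_true(all(prev %in% hit_key(hk)))
      prev <- hit_key(hk)
    }
  })
})

test_that("zero-mismatch mode reports exact occurrences only", {
  withr::with_seed(32, {
    mature <- random_rna_seq(21)
    dna <- rna_to_dna(mature)
    near <- sub("A", "G", dna)  # one substitution somewhere
    reads <- tibble::tibble(id = "r1",
                            sequence = paste0(random_dna_seq(30), dna,
                                              random_dna_seq(10), near,
                                              random_dna_seq(30)))
    h0 <- find_hits(make_query(mature), reads,
                    search_config(max_mismatches = 0L))
    expect_true(all(h0$mismatches == 0L))
    expect_equal(nrow(h0), 1L)
  })
})

test_that("queries shorter than the word size are skipped with a warning", {
  q <- make_query("ACGUA", name = "sim-miRtiny")
  reads <- tibble::tibble(id = "r1", sequence = "ACGTAACGTA")
  expect_warning(h <- find_hits(q, reads, search_config()), "skipped")
  expect_equal(nrow(h), 0L)
})
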