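`%+%` <- function(a, b) paste0(a, b)

make_hit <- function(emb, name = "sim-miR9001") {
  tibble::tibble(mirna_name = name, family = mirna_family(name),
                 read_id = "r1", strand = emb$strand,
                 read_start = emb$start, read_end = emb$end,
                 mismatches = 0L)
}

test_that("fold_hit_region folds the whole read in mature-sense orientation", {
  withr::with_seed(41, {
    mature <- random_rna_seq(21)
    pre <- make_precursor(mature)
    emb <- embed_in_read(pre$sequence, left = 60, right = 55)
    m_start <- emb$start + pre$mature_start - 1L
    hit <- make_hit(list(strand = "+", start = m_start,
                         end = m_start + 20L))
    reg <- fold_hit_region(emb$sequence, hit)
    expect_equal(reg$status, "ok")
    expect_equal(nchar(reg$fold$sequence), nchar(emb$sequence))
    expect_equal(substr(reg$fold$sequence, reg$mature_start,
                        reg$mature_end), mature)

    # minus strand: folded sequence is the reverse complement, mature
    # coordinates mirror
    embm <- embed_in_read(pre$sequence, left = 60, right = 55,
                          strand = "-")
    # mature interval mapped onto the forward read through the rc embedding
    m_start_fwd <- embm$start + (nchar(pre$sequence) - pre$mature_end)
    hitm <- make_hit(list(strand = "-", start = m_start_fwd,
                          end = m_start_fwd + 20L))
    regm <- fold_hit_region(embm$sequence, hitm)
    expect_equal(regm$status, "ok")
    expect_equal(regm$fold$sequence,
                 dna_to_rna(reverse_complement(embm$sequence)))
    expect_equal(substr(regm$fold$sequence, regm$mature_start,
                        regm$mature_end), mature)
  })
})

test_that("hits flush against a read end are rejected for missing flank", {
  withr::with_seed(42, {
    mature <- random_rna_seq(21)
    pre <- make_precursor(mature)
    emb <- embed_in_read(pre$sequence, left = 3, right = 60)
    m_start <- emb$start + pre$mature_start - 1L
    hit <- make_hit(list(strand = "+", start = m_start,
                         end = m_start + 20L))
    reg <- fold_hit_region(emb$sequence, hit)
    expect_equal(reg$status, "insufficient_flank")
    cand <- evaluate_candidate(emb$sequence, hit)
    expect_false(cand$accepted)
    expect_equal(cand$reject_reason, "insufficient_flank")
  })
})

test_that("locate_star reports duplex coordinates, arm and mismatches", {
  withr::with_seed(43, {
    mature <- random_rna_seq(21)
    pre <- make_precursor(mature, star_mismatches = 0L, arm = "5p")
    f <- fold(pre$sequence)
    ls <- locate_star(f, pre$mature_start, pre$mature_end)
    expect_equal(ls$status, "ok")
    expect_equal(ls$star_mismatches, 0L)
    expect_equal(ls$arm, "5p")
    expect_false(ls$multibranch_in_duplex)
    expect_equal(ls$mature_loop_overlap, 0L)
    expect_gte(ls$star_start, pre$star_start)
    expect_lte(ls$star_end, pre$star_end)

    pre3 <- make_precursor(mature, arm = "3p")
    f3 <- fold(pre3$sequence)
    ls3 <- locate_star(f3, pre3$mature_start, pre3$mature_end)
    expect_equal(ls3$arm, "3p")

    pre7 <- make_precursor(mature, star_mismatches = 7L)
    f7 <- fold(pre7$sequence)
    ls7 <- locate_star(f7, pre7$mature_start, pre7$mature_end)
    expect_gte(ls7$star_mismatches, 7L)
  })
})

test_that("a mature lying across the terminal loop is flagged", {
  # hand-built structure: stem of 6, loop of 6; mature covers the loop
  f <- structure(list(sequence = strrep("G", 6) %+% strrep("A", 6) %+%
                        strrep("C", 6),
                      structure = "((((((......))))))", mfe = -12,
                      engine = "stub"), class = "mir_fold")
  ls <- locate_star(f, 3, 12)
  expect_equal(ls$status, "ok")
  expect_gt(ls$mature_loop_overlap, 0)
})

test_that("a fully unpaired mature has no duplex", {
  f <- structure(list(sequence = strrep("A", 30),
                      structure = strrep(".", 30), mfe = 0,
                      engine = "stub"), class = "mir_fold")
  ls <- locate_star(f, 5, 25)
  expect_equal(ls$status, "no_duplex")
})

test_that("trim_to_hairpin extracts the duplex-bearing stem", {
  withr::with_seed(44, {
    mature <- random_rna_seq(21)
    pre <- make_precursor(mature)
    emb <- embed_in_read(pre$sequence, left = 30, right = 30)
    f <- fold(dna_to_rna(emb$sequence))
    ms <- emb$start + pre$mature_start - 1L
    iv <- trim_to_hairpin(f, ms, ms + 20L)
    # designed stem (tails excluded) must be inside the precursor interval
    expect_lte(iv$start, emb$start + pre$stem_start - 1L)
    expect_gte(iv$end, emb$start + pre$stem_end - 1L)
    # and the precursor must not swallow the whole read
    expect_gt(iv$start, 5L)
    expect_lt(iv$end, nchar(emb$sequence) - 5L)

    # a read that is exactly one hairpin trims to (almost) itself
    f2 <- fold(pre$sequence)
    iv2 <- trim_to_hairpin(f2, pre$mature_start, pre$mature_end)
    expect_equal(iv2$start, pre$stem_start)
    expect_equal(iv2$end, pre$stem_end)

    # under the additive model a subsequence cannot fold lower than the
    # full read
    sub <- substr(f$sequence, iv$start, iv$end)
    expect_gte(fold(sub)$mfe, f$mfe)
  })
})

test_that("evaluate_candidate accepts designed hairpins and explains rejections", {
  withr::with_seed(45, {
    mature <- random_rna_seq(21)

    good <- embed_in_read(make_precursor(mature)$sequence, 50, 50)
    pre <- make_precursor(mature)
    emb <- embed_in_read(pre$sequence, 50, 50)
    ms <- emb$start + pre$mature_start - 1L
    cand <- evaluate_candidate(emb$sequence,
                               make_hit(list(strand = "+", start = ms,
                                             end = ms + 20L)))
    expect_true(cand$accepted)
    expect_false(cand$flag_multibranch)
    expect_false(cand$flag_mature_spans_loop)
    expect_equal(cand$star_mismatches, 0L)
    expect_gt(cand$mfei, 0.67)
    expect_equal(substr(cand$precursor_sequence, cand$mature_start,
                        cand$mature_end), mature)

    # seven designed star mismatches exceed the duplex cap
    pre7 <- make_precursor(mature, star_mismatches = 7L)
    emb7 <- embed_in_read(pre7$sequence, 50, 50)
    ms7 <- emb7$start + pre7$mature_start - 1L
    cand7 <- evaluate_candidate(emb7$sequence,
                                make_hit(list(strand = "+", start = ms7,
                                              end = ms7 + 20L)))
    expect_false(cand7$accepted)
    expect_equal(cand7$reject_reason, "star_mismatches")
    expect_gt(cand7$star_mismatches, 6L)

    # two stems between mature and star: multibranch in the duplex
    hp <- function() {
      s <- random_rna_seq(8, gc = 0.8)
      paste0(s, "ACAC", chartr("ACGU", "UGCA",
                               paste(rev(strsplit(s, "")[[1]]),
                                     collapse = "")))
    }
    mb_pre <- paste0("AACCAA", mature, hp(), "CA", hp(),
                     chartr("ACGU", "UGCA",
                            paste(rev(strsplit(mature, "")[[1]]),
                                  collapse = "")), "AACCAA")
    embb <- embed_in_read(mb_pre, 50, 50)
    msb <- embb$start + 6L
    candb <- evaluate_candidate(embb$sequence,
                                make_hit(list(strand = "+", start = msb,
                                              end = msb + 20L)))
    expect_false(candb$accepted)
    expect_equal(candb$reject_reason, "multibranch_in_duplex")
  })
})

test_that("acceptance is monotone in the criteria thresholds", {
  run <- run_small_bundle(103L)
  strict <- classify_hits(run$hits, run$fx$reads,
                          criteria = criteria_config(
                            max_star_mismatches = 3L, enforce_mfei = TRUE,
                            min_mfei = 0.9))
  loose <- classify_hits(run$hits, run$fx$reads,
                         criteria = criteria_config(
                           max_star_mismatches = 6L, enforce_mfei = TRUE,
                           min_mfei = 0.67))
  key <- function(x) paste(x$read_id, x$mirna_name)
  expect_true(all(key(strict[strict$accepted, ]) %in%
                    key(loose[loose$accepted, ])))
})

test_that("classification is deterministic", {
  run <- run_small_bundle(103L)
  again <- classify_hits(run$hits, run$fx$reads,
                         criteria = criteria_config(enforce_mfei = TRUE))
  expect_identical(tibble::as_tibble(run$cand), tibble::as_tibble(again))
})

test_that("classify_hits rejects hits on unknown reads", {
  hits <- tibble::tibble(mirna_name = "m", family = "m", read_id = "ghost",
                         strand = "+", read_start = 1L, read_end = 21L,
                         mismatches = 0L, matched_subsequence = "A")
  expect_error(classify_hits(hits, tibble::tibble(id = "r1",
                                                  sequence = "ACGT")),
               "unknown read")
})
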