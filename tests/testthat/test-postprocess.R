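cand_row <- function(family, set, pre, read = "r1", accepted = TRUE) {
  tibble::tibble(family = family, set = set, precursor_sequence = pre,
                 read_id = read, accepted = accepted)
}

test_that("representation collapses identical loci and labels specificity", {
  cand <- dplyr::bind_rows(
    cand_row("miR169", "A", "ACGUACGU", read = "r1"),
    cand_row("miR169", "A", "ACGUACGU", read = "r2"),  # identical precursor
    cand_row("miR169", "A", "GGGGCCCC", read = "r3"),
    cand_row("miR169", "B", "ACGUACGU", read = "r4"),
    cand_row("miR2118", "A", "AAAACCCC", read = "r5"),
    cand_row("miR444", "B", "UUUUGGGG", read = "r6"),
    cand_row("miR444", "B", "CCCCGGGG", read = "r7", accepted = FALSE))
  rep <- representation(cand)
  expect_equal(rep$family, c("miR169", "miR2118", "miR444"))
  expect_equal(rep$A, c(2L, 1L, 0L))
  expect_equal(rep$B, c(1L, 0L, 1L))
  expect_equal(rep$total, c(3L, 1L, 1L))
  expect_equal(rep$specificity, c("shared", "A-specific", "B-specific"))
  # under the read key, the two r1/r2 loci stay distinct
  rep_read <- representation(cand, dedup = "identical_read")
  expect_equal(rep_read$A[rep_read$family == "miR169"], 3L)
})

test_that("representation is permutation-invariant and partitions families", {
  withr::with_seed(61, {
    cand <- dplyr::bind_rows(purrr::map(1:40, function(i) {
      cand_row(sample(paste0("miR", 1:6), 1), sample(c("A", "B"), 1),
               random_rna_seq(30), read = paste0("r", i))
    }))
    rep1 <- representation(cand)
    rep2 <- representation(cand[sample.int(nrow(cand)), ])
    expect_equal(rep1, rep2)
    n_shared <- sum(rep1$specificity == "shared")
    n_specific <- sum(rep1$specificity != "shared")
    expect_equal(n_shared + n_specific, nrow(rep1))
    expect_true(all(rep1$total >= 1L))
  })
})

test_that("describe_stats uses sample sd and midpoint medians", {
  d <- describe_stats(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$median, 2)
  expect_equal(d$min, 1)
  expect_equal(d$max, 3)
  expect_false(d$degenerate)
  expect_equal(describe_stats(c(1, 2, 3, 4))$median, 2.5)
  d1 <- describe_stats(5)
  expect_equal(d1$sd, 0)
  expect_true(d1$degenerate)
  expect_error(describe_stats(numeric(0)), "no values")
  withr::with_seed(62, {
    d1000 <- describe_stats(rnorm(1000))
    expect_lt(abs(d1000$mean), 0.1)
    expect_lt(abs(d1000$sd - 1), 0.1)
  })
})

test_that("repeat overlap flags any >= 1 nt intersection with fractions", {
  cand <- tibble::tibble(read_id = c("r1", "r1", "r2"),
                         family = "miR1", accepted = TRUE,
                         precursor_start = c(100L, 300L, 10L),
                         precursor_end = c(199L, 350L, 60L))
  ann <- tibble::tibble(score = 800, read_id = c("r1", "r3"),
                        start = c(150L, 1L), end = c(159L, 50L),
                        strand = "+", repeat_name = "MITE_x",
                        class_family = "DNA/TcMar-Stowaway",
                        repeat_class = "Class II DNA transposon",
                        superfamily = "TcMar-Stowaway")
  expect_warning(res <- repeat_overlap(cand, ann), "skipped")
  out <- res$candidates
  expect_equal(out$repeat_associated, c(TRUE, FALSE, FALSE))
  expect_equal(out$repeat_overlap_nt[1], 10L)
  expect_equal(out$repeat_overlap_fraction[1], 0.1)
  expect_equal(out$repeat_class[1], "Class II DNA transposon")
  expect_equal(res$percent_masked, 100 / 3)
  expect_equal(res$summary$percent, 100 / 3)
})

test_that("RepeatMasker-out tables survive a write/read round trip", {
  ann <- tibble::tibble(score = c(1500, 800), read_id = c("r1", "r2"),
                        start = c(10L, 40L), end = c(60L, 95L),
                        strand = c("+", "-"),
                        repeat_name = c("MITE_a", "CACTA_b"),
                        class_family = c("DNA/TcMar-Stowaway",
                                         "DNA/CACTA"))
  path <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(ann, path)
  back <- read_repeatmasker_out(path)
  expect_equal(back[, names(ann)], ann)
  expect_equal(back$repeat_class, rep("Class II DNA transposon", 2))
  expect_equal(back$superfamily, c("TcMar-Stowaway", "CACTA"))
})

test_that("EST evidence thresholds are inclusive and protein hits eliminate", {
  est <- tibble::tibble(
    family = paste0("miR", 1:6),
    est_id = paste0("EST", 1:6),
    query_coverage = c(100, 99, 98.9, 99.5, 100, 99),
    identity = c(100, 98, 99, 97.9, 98, 98))
  prot <- tibble::tibble(est_id = c("EST5", "EST6"),
                         e_value = c(1e-5, 1e-2))
  kept <- est_evidence(est, prot)
  # EST1 clean, EST2 exactly on both boundaries, EST3 coverage below,
  # EST4 identity below, EST5 protein-coding, EST6 protein e-value above
  # the elimination threshold so retained
  expect_equal(kept$est_id, c("EST1", "EST2", "EST6"))
  expect_equal(est_evidence(est, NULL)$est_id,
               c("EST1", "EST2", "EST5", "EST6"))
})
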