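#' Configuration for the mature-miRNA homology search
#'
#' Defaults mirror a short-query nucleotide search: a 7-nt exact word seed
#' and a cap of 3 mismatches over the full mature length. Matching is
#' ungapped and full-length: every reported hit covers the whole mature
#' query, so the mismatch cap is an exact Hamming-distance filter.
#'
#' @param word_size Exact-seed word length (>= 4). Seeds shorter than
#'   `word_size` are used automatically when the mismatch budget requires it
#'   (pigeonhole: with `k` mismatches allowed, one of `k + 1` disjoint blocks
#'   of length `floor(L / (k + 1))` must be exact).
#' @param max_mismatches Maximum Hamming distance to a mature query
#'   (0 gives the strict mode used for cross-species synteny scans).
#' @param strands `"both"` or `"forward"`.
#' @param require_full_length Must be `TRUE`; partial-length placements are
#'   outside the matching contract.
#' @return A list of class `mir_search_config`.
#' @export
search_config <- function(word_size = 7L, max_mismatches = 3L,
                          strands = c("both", "forward"),
                          require_full_length = TRUE) {
  strands <- match.arg(strands)
  word_size <- as.integer(word_size)
  max_mismatches <- as.integer(max_mismatches)
  stopifnot(word_size >= 4L, max_mismatches >= 0L)
  if (!isTRUE(require_full_length)) {
    stop("partial-length matching is not supported; ",
         "require_full_length must be TRUE")
  }
  structure(list(word_size = word_size, max_mismatches = max_mismatches,
                 strands = strands, require_full_length = TRUE),
            class = "mir_search_config")
}

#' Hamming distance with N counting as a mismatch
#'
#' Positions where either sequence carries `N` never match, which is the
#' conservative choice for survey-quality reads.
#'
#' @param a,b Equal-length sequence strings.
#' @return Integer mismatch count.
#' @export
count_mismatches <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")")
  }
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- charToRaw("N")
  sum(ra != rb | ra == n | rb == n)
}

#' Index every exact word occurrence in a set of reads
#'
#' For `strands = "both"` the reverse complement of each read is scanned as
#' well, with coordinates mapped back onto the forward read (1-based,
#' inclusive start of the word's footprint). Words containing `N` are not
#' indexed: `N` never participates in an exact match.
#'
#' @param reads A tibble with columns `id` and `sequence` (DNA).
#' @param word_size Word length.
#' @param strands `"both"` or `"forward"`.
#' @return A tibble with columns `word`, `read_id`, `start`, `strand`.
#' @export
build_word_index <- function(reads, word_size, strands = "both") {
  word_size <- as.integer(word_size)
  res <- purrr::map2(reads$id, reads$sequence, function(id, seq) {
    n <- nchar(seq)
    if (n < word_size) return(NULL)
    starts <- seq_len(n - word_size + 1L)
    fwd <- substring(seq, starts, starts + word_size - 1L)
    out <- tibble::tibble(word = fwd, read_id = id, start = starts,
                          strand = "+")
    if (strands == "both") {
      rc <- reverse_complement(seq)
      rcw <- substring(rc, starts, starts + word_size - 1L)
      # word at position p of the reverse complement occupies forward
      # positions [n - p - w + 2, n - p + 1]
      out <- dplyr::bind_rows(out, tibble::tibble(
        word = rcw, read_id = id,
        start = n - starts - word_size + 2L, strand = "-"))
    }
    out[!grepl("N", out$word, fixed = TRUE), , drop = FALSE]
  })
  dplyr::bind_rows(res)
}

# Disjoint seed blocks guaranteeing no false negatives at <= k mismatches:
# k + 1 blocks of length floor(L / (k + 1)); the exact-match seed is the
# first min(word_size, block) characters of each block.
seed_offsets <- function(mature_len, k, word_size) {
  block <- mature_len %/% (k + 1L)
  s <- min(word_size, block)
  list(offsets = (0:k) * block, seed_len = s)
}

#' Find mismatch-bounded occurrences of mature miRNAs on reads
#'
#' Every full-length, ungapped placement of a mature query on either strand
#' of a read with Hamming distance at most `config$max_mismatches` is
#' reported exactly once. Seeding uses disjoint exact blocks sized so the
#' pigeonhole principle rules out false negatives; results are identical to
#' a brute-force sliding-window scan.
#'
#' @param matures A tibble with columns `name`, `family`, `sequence` (RNA or
#'   DNA); deduplicate first with [dedup_matures()].
#' @param reads A tibble with columns `id` and `sequence` (DNA).
#' @param config A [search_config()].
#' @return A tibble of hits with columns `mirna_name`, `family`, `read_id`,
#'   `strand`, `read_start`, `read_end` (1-based inclusive on the forward
#'   read), `mismatches` and `matched_subsequence` (the read segment,
#'   reverse-complemented for minus-strand hits so it is always in mature
#'   orientation, DNA alphabet), sorted by read, start, then miRNA name.
#' @export
find_hits <- function(matures, reads, config = search_config()) {
  stopifnot(inherits(config, "mir_search_config"))
  k <- config$max_mismatches
  queries <- rna_to_dna(toupper(matures$sequence))
  lens <- nchar(queries)
  short <- lens < config$word_size
  if (any(short)) {
    warning(sum(short), " mature query(ies) shorter than word_size skipped")
  }
  read_seq <- stats::setNames(reads$sequence, reads$id)
  read_len <- nchar(read_seq)

  hits <- vector("list", nrow(matures))
  # group queries by seed length so each word index is built once
  seed_len <- vapply(lens, function(L) {
    min(config$word_size, max(1L, L %/% (k + 1L)))
  }, integer(1))
  for (s in unique(seed_len[!short])) {
    idx_tbl <- build_word_index(reads, s, strands = "forward")
    index <- split(seq_len(nrow(idx_tbl)), idx_tbl$word)
    for (qi in which(seed_len == s & !short)) {
      pat_fwd <- queries[qi]
      L <- lens[qi]
      sd <- seed_offsets(L, k, config$word_size)
      pats <- list(`+` = pat_fwd)
      if (config$strands == "both") {
        pats[["-"]] <- reverse_complement(pat_fwd)
      }
      placements <- list()
      for (strand in names(pats)) {
        pat <- pats[[strand]]
        for (off in sd$offsets) {
          seed <- substr(pat, off + 1L, off + sd$seed_len)
          rows <- index[[seed]]
          if (is.null(rows)) next
          cand_start <- idx_tbl$start[rows] - off
          cand_read <- idx_tbl$read_id[rows]
          ok <- cand_start >= 1L & cand_start + L - 1L <= read_len[cand_read]
          if (!any(ok)) next
          placements[[length(placements) + 1L]] <- tibble::tibble(
            read_id = cand_read[ok], read_start = cand_start[ok],
            strand = strand)
        }
      }
      if (length(placements) == 0L) next
      pl <- dplyr::distinct(dplyr::bind_rows(placements))
      seg <- substring(read_seq[pl$read_id], pl$read_start,
                       pl$read_start + L - 1L)
      oriented <- ifelse(pl$strand == "-", reverse_complement(seg), seg)
      mm <- vapply(oriented, count_mismatches, integer(1),
                   b = pats[["+"]], USE.NAMES = FALSE)
      keep <- mm <= k
      if (!any(keep)) next
      hits[[qi]] <- tibble::tibble(
        mirna_name = matures$name[qi],
        family = if ("family" %in% names(matures)) matures$family[qi]
                 else mirna_family(matures$name[qi]),
        read_id = pl$read_id[keep],
        strand = pl$strand[keep],
        read_start = pl$read_start[keep],
        read_end = pl$read_start[keep] + L - 1L,
        mismatches = as.integer(mm[keep]),
        matched_subsequence = unname(oriented[keep]))
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(mirna_name = character(), family = character(),
                          read_id = character(), strand = character(),
                          read_start = integer(), read_end = integer(),
                          mismatches = integer(),
                          matched_subsequence = character()))
  }
  dplyr::arrange(out, .data$read_id, .data$read_start, .data$mirna_name,
                 .data$strand)
}

#' Write or read a homology hit table as TSV
#'
#' Columns follow the hit-table convention: `mirna`, `family`, `read`,
#' `strand`, `start`, `end`, `mismatches`, `sequence`; coordinates are
#' 1-based inclusive.
#'
#' @param hits A hit tibble from [find_hits()].
#' @param path Output (or input) path.
#' @return `write_hit_table()`: `path` invisibly; `read_hit_table()`: the
#'   hit tibble with internal column names.
#' @export
write_hit_table <- function(hits, path) {
  out <- dplyr::rename(hits, mirna = "mirna_name", read = "read_id",
                       start = "read_start", end = "read_end",
                       sequence = "matched_subsequence")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                            colClasses = "character"))
  tb$start <- as.integer(tb$start)
  tb$end <- as.integer(tb$end)
  tb$mismatches <- as.integer(tb$mismatches)
  dplyr::rename(tb, mirna_name = "mirna", read_id = "read",
                read_start = "start", read_end = "end",
                matched_subsequence = "sequence")
}
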