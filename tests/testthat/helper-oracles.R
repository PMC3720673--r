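# Independent oracles: exhaustive structure enumeration with its own loop
# scorer, and a Biostrings-based brute-force homology scan. Neither shares
# code paths with the package implementations they check.

random_rna_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_dna_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# --- folding oracle ---------------------------------------------------------

oracle_pair_type <- function(a, b) {
  key <- paste0(a, b)
  idx <- match(key, c("AU", "CG", "GC", "UA", "GU", "UG"))
  if (is.na(idx)) 0L else idx
}

# integer decikcal coefficients derived directly from the parameter object
oracle_coefs <- function(params) {
  list(stack = round(10 * params$stack),
       hp = function(size) {
         if (size < params$min_hairpin) return(Inf)
         round(10 * (params$hairpin_base +
                       params$hairpin_per_nt * (size - 3)))
       },
       il = function(size) {
         if (size < 1 || size > params$interior_max) return(Inf)
         round(10 * (params$interior_base + params$interior_per_nt * size))
       },
       mba = round(10 * params$multibranch_close),
       mbb = round(10 * params$multibranch_branch),
       mbc = round(10 * params$multibranch_unpaired))
}

# all pseudoknot-free pair sets over seq (list of 2-col matrices)
oracle_enumerate <- function(ch, min_hairpin = 3L) {
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (i > j) return(list(cbind(integer(0), integer(0))))
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- enum(i + 1L, j) # i unpaired
    k0 <- i + min_hairpin + 1L
    if (k0 <= j) {
      for (k in k0:j) {
        if (oracle_pair_type(ch[i], ch[k]) == 0L) next
        for (a in enum(i + 1L, k - 1L)) {
          for (b in enum(k + 1L, j)) {
            res[[length(res) + 1L]] <- rbind(c(i, k), a, b)
          }
        }
      }
    }
    memo[[key]] <- res
    res
  }
  enum(1L, n)
}

# score one pair set by recursive loop decomposition (decikcal)
oracle_score <- function(ch, pairs, co) {
  n <- length(ch)
  pt <- integer(n)
  if (nrow(pairs) > 0L) {
    pt[pairs[, 1]] <- pairs[, 2]
    pt[pairs[, 2]] <- pairs[, 1]
  }
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- min(pairs[r, ]); j <- max(pairs[r, ])
    kids <- NULL
    unpaired <- 0L
    p <- i + 1L
    while (p < j) {
      if (pt[p] == 0L) {
        unpaired <- unpaired + 1L
        p <- p + 1L
      } else {
        kids <- rbind(kids, c(p, pt[p]))
        p <- pt[p] + 1L
      }
    }
    if (is.null(kids)) {
      total <- total + co$hp(unpaired)
    } else if (nrow(kids) == 1L) {
      if (unpaired == 0L) {
        total <- total + co$stack[oracle_pair_type(ch[i], ch[j]),
                                  oracle_pair_type(ch[kids[1, 1]],
                                                   ch[kids[1, 2]])]
      } else {
        total <- total + co$il(unpaired)
      }
    } else {
      total <- total + co$mba + co$mbb * (nrow(kids) + 1L) +
        co$mbc * unpaired
    }
  }
  total
}

# exhaustive MFE in kcal/mol (0 for the open chain included)
oracle_mfe <- function(seq, params = fold_params()) {
  ch <- strsplit(seq, "")[[1]]
  co <- oracle_coefs(params)
  best <- min(vapply(oracle_enumerate(ch, params$min_hairpin),
                     function(p) oracle_score(ch, p, co), numeric(1)))
  best / 10
}

# --- homology search oracle -------------------------------------------------

# full-length sliding-window scan on both strands via Biostrings
oracle_hits <- function(matures, reads, max_mismatches) {
  rows <- list()
  for (qi in seq_len(nrow(matures))) {
    pat <- Biostrings::DNAString(rna_to_dna(matures$sequence[qi]))
    rcp <- Biostrings::reverseComplement(pat)
    for (ri in seq_len(nrow(reads))) {
      subj <- Biostrings::DNAString(reads$sequence[ri])
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else rcp
        m <- Biostrings::matchPattern(p, subj,
                                      max.mismatch = max_mismatches)
        if (length(m) == 0L) next
        st <- Biostrings::start(m)
        mm <- Biostrings::neditStartingAt(p, subj, starting.at = st)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mirna_name = matures$name[qi], read_id = reads$id[ri],
          strand = strand, read_start = st,
          read_end = st + length(p) - 1L, mismatches = as.integer(mm))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(mirna_name = character(), read_id = character(),
                          strand = character(), read_start = integer(),
                          read_end = integer(), mismatches = integer()))
  }
  dplyr::arrange(out, read_id, read_start, mirna_name, strand)
}

hit_key <- function(h) {
  paste(h$mirna_name, h$read_id, h$strand, h$read_start, h$read_end,
        h$mismatches, sep = "|")
}
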