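#' Specification for a synthetic survey-read fixture bundle
#'
#' The generator emulates the inputs of a chromosome survey miRNA screen:
#' 454-style genomic reads (lengths normal(350, 50) truncated to
#' [100, 600]), a miRBase-style mature query set, implanted precursor
#' hairpins with known ground truth, structured decoys exercising each
#' rejection reason, a RepeatMasker-style annotation table with a MITE-like
#' palindromic motif, and EST/protein evidence tables. Everything is driven
#' by one seed: reruns are byte-identical.
#'
#' @param seed Integer RNG seed.
#' @param implants Tibble with one row per implanted family: columns
#'   `copies`, `star_mismatches`, `loop_len`, `arm`, `in_repeat`, and
#'   optionally `sequence` (mature, RNA; generated when absent).
#' @param decoys Tibble with columns `type` (`"shuffle"`, `"multibranch"`,
#'   `"mismatch_overflow"`) and `copies`.
#' @param n_background Background reads carrying no implant.
#' @param read_length_mean,read_length_sd,read_length_min,read_length_max
#'   Read-length distribution (nt).
#' @param background_gc Background GC fraction (0-1) of the order-1 Markov
#'   background model.
#' @param mature_length Length of generated mature sequences.
#' @return A list of class `mir_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         implants = default_implants(),
                         decoys = default_decoys(),
                         n_background = 10L,
                         read_length_mean = 350, read_length_sd = 50,
                         read_length_min = 100, read_length_max = 600,
                         background_gc = 0.44, mature_length = 21L) {
  stopifnot(all(implants$copies >= 1L),
            all(decoys$type %in% c("shuffle", "multibranch",
                                   "mismatch_overflow")))
  structure(list(seed = as.integer(seed), implants = implants,
                 decoys = decoys, n_background = as.integer(n_background),
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 read_length_min = read_length_min,
                 read_length_max = read_length_max,
                 background_gc = background_gc,
                 mature_length = as.integer(mature_length)),
            class = "mir_fixture_spec")
}

#' @rdname fixture_spec
#' @param n_families,copies Families and per-family copy numbers for the
#'   default implant design (10 families at copy numbers 1..10).
#' @export
default_implants <- function(n_families = 10L, copies = seq_len(n_families)) {
  tibble::tibble(
    copies = as.integer(copies),
    star_mismatches = 0L,
    loop_len = 8L,
    arm = rep(c("5p", "3p"), length.out = n_families),
    in_repeat = rep(c(FALSE, FALSE, FALSE, FALSE, TRUE),
                    length.out = n_families)
  )
}

#' @rdname fixture_spec
#' @param copies_each Copies per decoy type.
#' @export
default_decoys <- function(copies_each = 10L) {
  tibble::tibble(type = c("shuffle", "multibranch", "mismatch_overflow"),
                 copies = as.integer(copies_each))
}

# order-1 Markov background with configurable GC and mild homopolymer
# persistence; DNA alphabet
random_background <- function(n, gc = 0.44, persist = 0.12) {
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- character(n)
  prev <- sample(names(base_p), 1, prob = base_p)
  out[1] <- prev
  for (i in seq_len(n - 1L)) {
    if (runif(1) < persist) {
      nxt <- prev
    } else {
      nxt <- sample(names(base_p), 1, prob = base_p)
    }
    out[i + 1L] <- nxt
    prev <- nxt
  }
  paste(out, collapse = "")
}

random_rna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random mature that is far from its own reverse complement, so a query
# can never hit its designed star site within the mismatch budget even
# after star edits (quasi-palindromic matures would create such hits)
random_mature <- function(n, gc = 0.5, min_self_dist = 12L) {
  repeat {
    s <- random_rna(n, gc)
    if (count_mismatches(s, rc_rna(s)) >= min_self_dist) return(s)
  }
}

# unpairable filler: A/C-only stretches cannot pair with each other
random_ac <- function(n) paste(sample(c("A", "C"), n, replace = TRUE,
                                      prob = c(0.5, 0.5)), collapse = "")

# substitution that can pair with neither the mature base nor wobble
no_pair_substitute <- function(base) {
  c(A = "C", C = "A", G = "A", U = "C")[base]
}

rc_rna <- function(seq) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Construct a designed precursor hairpin around a mature sequence
#'
#' Layout (5p arm): 5' A/C tail, stem extension, mature, terminal loop,
#' star (reverse complement of extension + mature), stem extension
#' complement, 3' A/C tail; the 3p arm mirrors it with the mature
#' downstream of the loop. Star mismatches are introduced as point changes
#' at interior, spaced positions opposite the mature, using substitutions
#' that cannot re-pair (no Watson-Crick, no wobble), so each designed
#' mismatch leaves exactly one mature position unpaired. Under the default
#' engine the designed region folds as a single stem.
#'
#' @param mature Mature sequence (RNA, 18-26 nt).
#' @param loop_len Terminal loop length (>= 4).
#' @param star_mismatches Designed unpaired mature positions (0 gives a
#'   perfect duplex).
#' @param arm `"5p"` or `"3p"`.
#' @param stem_ext Loop-distal stem extension (bp) beyond the mature.
#' @param inner_ext GC-rich loop-side stem extension (bp); anchors the
#'   duplex register so designed star mismatches stay opposite their
#'   mature positions instead of shifting the pairing frame.
#' @param tail_len Unpaired A/C tail on each side.
#' @return A list: `sequence` (RNA precursor), `mature_start`,
#'   `mature_end`, `star_start`, `star_end`, `stem_start`, `stem_end`
#'   (all 1-based inclusive), `arm`.
#' @export
make_precursor <- function(mature, loop_len = 8L, star_mismatches = 0L,
                           arm = c("5p", "3p"), stem_ext = 6L,
                           inner_ext = 4L, tail_len = 6L) {
  arm <- match.arg(arm)
  L <- nchar(mature)
  stopifnot(L >= 18L, L <= 26L)
  if (loop_len < 4L) stop("loop_len must be >= 4 (minimum hairpin loop)")
  if (star_mismatches > L - 4L) stop("too many designed star mismatches")
  mature <- dna_to_rna(toupper(mature))
  ext <- random_rna(stem_ext, gc = 0.6)
  inner <- if (inner_ext > 0L) random_rna(inner_ext, gc = 0.9) else ""
  loop <- random_ac(loop_len)
  tail5 <- random_ac(tail_len)
  tail3 <- random_ac(tail_len)

  mm_pos <- integer(0)
  if (star_mismatches > 0L) {
    mm_pos <- unique(round(seq(3, L - 2, length.out = star_mismatches)))
    while (length(mm_pos) < star_mismatches) {
      extra <- setdiff(3:(L - 2), mm_pos)
      mm_pos <- sort(c(mm_pos, extra[1L]))
    }
  }
  mutate_star <- function(star, top, top_offset) {
    # top position i sits at star position nchar(top_side) - (i - 1)
    ch <- strsplit(star, "")[[1]]
    for (p in mm_pos) {
      i_top <- top_offset + p
      j <- length(ch) - i_top + 1L
      ch[j] <- no_pair_substitute(substr(top, i_top, i_top))
    }
    paste(ch, collapse = "")
  }
  if (arm == "5p") {
    top <- paste0(ext, mature, inner)    # 5' side of the stem
    star <- mutate_star(rc_rna(top), top, top_offset = stem_ext)
    seqn <- paste0(tail5, top, loop, star, tail3)
    mature_start <- tail_len + stem_ext + 1L
    star_start <- tail_len + nchar(top) + loop_len + 1L
    star_end <- star_start + nchar(star) - 1L
    out <- list(sequence = seqn,
                mature_start = mature_start,
                mature_end = mature_start + L - 1L,
                star_start = star_start, star_end = star_end)
  } else {
    bottom <- paste0(inner, mature, ext) # 3' side of the stem
    star <- mutate_star(rc_rna(bottom), bottom,
                        top_offset = inner_ext)
    seqn <- paste0(tail5, star, loop, bottom, tail3)
    star_start <- tail_len + 1L
    star_end <- star_start + nchar(star) - 1L
    mature_start <- tail_len + nchar(star) + loop_len + inner_ext + 1L
    out <- list(sequence = seqn,
                mature_start = mature_start,
                mature_end = mature_start + L - 1L,
                star_start = star_start, star_end = star_end)
  }
  out$stem_start <- tail_len + 1L
  out$stem_end <- nchar(out$sequence) - tail_len
  out$arm <- arm
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian-walk shuffle: the result has exactly the same
#' mononucleotide and dinucleotide counts as the input and the same first
#' and last characters.
#'
#' @param seq Sequence string (length >= 3 for a non-trivial shuffle).
#' @return A shuffled sequence string.
#' @export
dinucleotide_shuffle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 3L) return(seq)
  verts <- unique(ch)
  succ <- lapply(stats::setNames(verts, verts), function(v) {
    ch[which(ch[-n] == v) + 1L]
  })
  last <- ch[n]
  # choose random last edges forming a tree toward the final vertex
  for (attempt in seq_len(1000L)) {
    last_edge <- vapply(verts, function(v) {
      if (v == last || length(succ[[v]]) == 0L) NA_character_
      else sample(succ[[v]], 1L)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last || length(succ[[v]]) == 0L) next
      seen <- character(0)
      cur <- v
      while (!is.na(cur) && cur != last && !cur %in% seen) {
        seen <- c(seen, cur)
        cur <- if (cur %in% names(last_edge)) last_edge[[cur]] else NA
      }
      if (is.na(cur) || cur %in% seen) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) return(seq)  # degenerate input; give it back unchanged
  pools <- lapply(stats::setNames(verts, verts), function(v) {
    pool <- succ[[v]]
    le <- last_edge[[v]]
    if (!is.na(le) && v != last) {
      pool <- pool[-match(le, pool)]
    }
    c(sample(pool), if (v != last && !is.na(le)) le)
  })
  used <- stats::setNames(integer(length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- pools[[cur]][used[cur]]
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

# small GC-rich side hairpin used to build multibranch decoys
side_hairpin <- function(stem = 8L, loop = 4L) {
  s <- random_rna(stem, gc = 0.8)
  paste0(s, random_ac(loop), rc_rna(s))
}

# designed-violator constructors: the designed property is checked on the
# folded precursor (register slips can occasionally rescue an edited duplex,
# and two random side hairpins can merge into one stem); invalid draws are
# discarded so the emitted ground truth is guaranteed to hold
make_overflow_precursor <- function(mature, edits = 8L) {
  for (t in seq_len(15L)) {
    pre <- make_precursor(mature, star_mismatches = edits)
    f <- fold(pre$sequence)
    ls <- locate_star(f, pre$mature_start, pre$mature_end)
    if (ls$status == "ok" && ls$star_mismatches >= edits &&
        ls$mature_loop_overlap == 0L) {
      return(pre)
    }
  }
  NULL
}

make_multibranch_precursor <- function(mature) {
  L <- nchar(mature)
  for (t in seq_len(15L)) {
    seqn <- paste0(random_ac(6L), mature, side_hairpin(), random_ac(2L),
                   side_hairpin(), rc_rna(mature), random_ac(6L))
    f <- fold(seqn)
    ls <- locate_star(f, 7L, 6L + L)
    if (ls$status == "ok" && isTRUE(ls$multibranch_in_duplex) &&
        ls$star_mismatches <= 6L && ls$mature_loop_overlap == 0L) {
      return(list(sequence = seqn, mature_start = 7L,
                  mature_end = 6L + L))
    }
  }
  NULL
}

#' Generate a fixture bundle with ground truth
#'
#' Implants each precursor copy into its own read at a seeded random
#' position and strand with unique random flanks (each copy is a distinct
#' locus), implants decoys analogously, simulates a MITE-like palindromic
#' repeat motif in a subset of background reads, annotates repeats in
#' RepeatMasker-out layout, and synthesizes EST/protein evidence tables.
#' Re-running with the same spec is byte-identical.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `mir_fixture`: tibbles `reads`, `matures`,
#'   `repeat_annotations`, `est_hits`, `protein_hits`, `ground_truth`, and
#'   the originating `spec`. Ground-truth columns include the designed
#'   acceptance and the set of designed rejection reasons
#'   (`expected_reasons`, comma-separated; decoy classes map one-to-one to
#'   rejection reasons, shuffles to the full designed rejection set).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "mir_fixture_spec"))
  withr::with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  implants <- spec$implants
  n_fam <- nrow(implants)
  if (!"sequence" %in% names(implants)) {
    implants$sequence <- vapply(seq_len(n_fam), function(i) {
      random_mature(spec$mature_length, gc = 0.5)
    }, character(1))
  }
  implants$family <- paste0("miR", 9000L + seq_len(n_fam))
  implants$name <- paste0("sim-", implants$family)

  decoys <- spec$decoys
  decoys$family <- paste0("miR", 9900L + seq_len(nrow(decoys)))
  decoys$name <- paste0("sim-", decoys$family)
  decoys$sequence <- NA_character_

  draw_len <- function(min_needed) {
    for (i in seq_len(50L)) {
      len <- round(rnorm(1, spec$read_length_mean, spec$read_length_sd))
      len <- max(spec$read_length_min, min(spec$read_length_max, len))
      if (len >= min_needed) return(as.integer(len))
    }
    as.integer(min_needed)
  }
  min_flank <- 20L

  embed <- function(pre_rna, read_id) {
    pre_dna <- rna_to_dna(pre_rna)
    plen <- nchar(pre_dna)
    len <- draw_len(plen + 2L * (min_flank + 5L))
    pos_choices <- seq.int(min_flank + 3L, len - plen - min_flank - 2L)
    pos <- pos_choices[sample.int(length(pos_choices), 1L)]
    strand <- sample(c("+", "-"), 1L)
    insert <- if (strand == "-") {
      reverse_complement(pre_dna)
    } else {
      pre_dna
    }
    left <- random_background(pos - 1L, spec$background_gc)
    right <- random_background(len - plen - pos + 1L, spec$background_gc)
    seqn <- paste0(left, insert, right)
    list(read = tibble::tibble(id = read_id, description = "",
                               sequence = seqn),
         start = pos, end = pos + plen - 1L, strand = strand)
  }

  reads <- list()
  truth <- list()
  repeat_rows <- list()
  used_ext <- new.env(parent = emptyenv())

  for (i in seq_len(n_fam)) {
    fam <- implants$family[i]
    for (cp in seq_len(implants$copies[i])) {
      # distinct stem extension per copy so each locus is unique
      repeat {
        pre <- make_precursor(implants$sequence[i],
                              loop_len = implants$loop_len[i],
                              star_mismatches = implants$star_mismatches[i],
                              arm = implants$arm[i])
        key <- paste0(fam, "|", pre$sequence)
        if (!exists(key, envir = used_ext)) break
      }
      assign(key, TRUE, envir = used_ext)
      rid <- sprintf("read_%s_c%02d", fam, cp)
      emb <- embed(pre$sequence, rid)
      reads[[length(reads) + 1L]] <- emb$read
      ok <- implants$star_mismatches[i] <= 6L
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "implant", family = fam, mirna_name = implants$name[i],
        read_id = rid, strand = emb$strand, copy = cp,
        precursor_start = emb$start, precursor_end = emb$end,
        expected_accept = ok,
        expected_reasons = if (ok) "" else "star_mismatches")
      if (isTRUE(implants$in_repeat[i])) {
        repeat_rows[[length(repeat_rows) + 1L]] <- tibble::tibble(
          score = 1500, read_id = rid,
          start = max(1L, emb$start - 5L), end = emb$end + 5L,
          strand = emb$strand, repeat_name = "MITE_sim_Mariner",
          class_family = "DNA/TcMar-Stowaway")
      }
    }
  }

  shuffle_reason_set <- paste(c("no_duplex", "star_mismatches",
                                "mature_spans_loop",
                                "multibranch_in_duplex", "low_mfei"),
                              collapse = ",")
  for (i in seq_len(nrow(decoys))) {
    type <- decoys$type[i]
    fam <- decoys$family[i]
    # the designed rejection reason presumes the homology stage sees only
    # the designed mature locus on each decoy read; rebuild the family
    # (fresh mature and reads) until that bookkeeping invariant holds
    query <- tibble::tibble(name = decoys$name[i], family = fam,
                            sequence = NA_character_)
    for (attempt in seq_len(25L)) {
      mat <- random_mature(spec$mature_length, gc = 0.5)
      query$sequence <- mat
      fam_reads <- list()
      fam_truth <- list()
      family_ok <- TRUE
      for (cp in seq_len(decoys$copies[i])) {
        rid <- sprintf("read_decoy_%s_%02d", type, cp)
        emb <- NULL
        for (try in seq_len(10L)) {
          if (type == "mismatch_overflow") {
            pre <- make_overflow_precursor(mat)
            if (is.null(pre)) break
            pre_seq <- pre$sequence
            reasons <- "star_mismatches"
          } else if (type == "multibranch") {
            pre <- make_multibranch_precursor(mat)
            if (is.null(pre)) break
            pre_seq <- pre$sequence
            reasons <- "multibranch_in_duplex"
          } else { # shuffle: mature kept, hairpin context shuffled
            pre <- make_precursor(mat, star_mismatches = 0L)
            s <- pre$sequence
            ctx <- paste0(substr(s, 1, pre$mature_start - 1L),
                          substr(s, pre$mature_end + 1L, nchar(s)))
            shuf <- dinucleotide_shuffle(ctx)
            pre_seq <- paste0(substr(shuf, 1, pre$mature_start - 1L), mat,
                              substr(shuf, pre$mature_start, nchar(shuf)))
            reasons <- shuffle_reason_set
          }
          cand_emb <- embed(pre_seq, rid)
          if (type == "shuffle") {
            # shuffled decoys are statistical controls; no certification
            emb <- cand_emb
            break
          }
          # certify the emitted instance against its designed rejection:
          # the read context is random and can occasionally hand the
          # mature an alternative duplex, so the ground-truth claim is
          # checked on the actual read and the context redrawn otherwise
          cc <- classify_hits(
            find_hits(query, cand_emb$read, search_config()),
            cand_emb$read, criteria = criteria_config())
          if (nrow(cc) == 1L && !cc$accepted &&
              identical(cc$reject_reason, reasons)) {
            emb <- cand_emb
            break
          }
        }
        if (is.null(emb)) { family_ok <- FALSE; break }
        fam_reads[[cp]] <- emb$read
        fam_truth[[cp]] <- tibble::tibble(
          kind = paste0("decoy_", type), family = fam,
          mirna_name = decoys$name[i], read_id = rid,
          strand = emb$strand, copy = cp,
          precursor_start = emb$start, precursor_end = emb$end,
          expected_accept = FALSE, expected_reasons = reasons)
      }
      if (family_ok) break
    }
    if (!family_ok) {
      stop("could not realize designed decoy family of type ", type)
    }
    decoys$sequence[i] <- mat
    reads <- c(reads, fam_reads)
    truth <- c(truth, fam_truth)
  }

  matures <- tibble::tibble(
    name = c(implants$name, decoys$name),
    family = c(implants$family, decoys$family),
    species = "sim",
    sequence = c(implants$sequence, decoys$sequence))

  # background reads; a third carry the palindromic MITE-like motif
  mite_core <- random_rna(18L, gc = 0.6)
  mite <- rna_to_dna(paste0(mite_core, "ACAC", rc_rna(mite_core)))
  for (b in seq_len(spec$n_background)) {
    rid <- sprintf("read_bg_%03d", b)
    len <- draw_len(spec$read_length_min)
    seqn <- random_background(len, spec$background_gc)
    if (b %% 3L == 0L && len > nchar(mite) + 40L) {
      pos_choices <- seq.int(20L, len - nchar(mite) - 19L)
      pos <- pos_choices[sample.int(length(pos_choices), 1L)]
      seqn <- paste0(substr(seqn, 1, pos - 1L), mite,
                     substr(seqn, pos + nchar(mite), len))
      repeat_rows[[length(repeat_rows) + 1L]] <- tibble::tibble(
        score = 800, read_id = rid, start = pos,
        end = pos + nchar(mite) - 1L, strand = "+",
        repeat_name = "MITE_sim_Mariner",
        class_family = "DNA/TcMar-Stowaway")
    }
    reads[[length(reads) + 1L]] <- tibble::tibble(
      id = rid, description = "", sequence = seqn)
  }

  # EST / protein evidence: families 1-2 retained; 3 eliminated as
  # protein-coding; 4 below coverage; 5 below identity
  ev_fams <- implants$family[seq_len(min(5L, n_fam))]
  est_hits <- tibble::tibble(
    family = ev_fams,
    est_id = sprintf("EST%05d", seq_along(ev_fams)),
    query_coverage = c(100, 99, 100, 95, 100)[seq_along(ev_fams)],
    identity = c(100, 98, 99.5, 99, 97.5)[seq_along(ev_fams)],
    e_value = 1e-30)
  protein_hits <- tibble::tibble(
    est_id = if (length(ev_fams) >= 3L) "EST00003" else character(0),
    protein_id = if (length(ev_fams) >= 3L) "XP_sim_0001" else character(0),
    e_value = if (length(ev_fams) >= 3L) 1e-10 else numeric(0))
  retained <- ev_fams[c(1L, 2L)]

  out <- list(
    reads = dplyr::bind_rows(reads),
    matures = matures,
    repeat_annotations = if (length(repeat_rows)) {
      dplyr::bind_rows(repeat_rows)
    } else {
      tibble::tibble(score = numeric(), read_id = character(),
                     start = integer(), end = integer(),
                     strand = character(), repeat_name = character(),
                     class_family = character())
    },
    est_hits = est_hits,
    protein_hits = protein_hits,
    est_retained_families = retained,
    ground_truth = dplyr::bind_rows(truth),
    spec = spec)
  class(out) <- "mir_fixture"
  out
}

#' Write a fixture bundle to disk
#'
#' Emits the same plain-text formats the pipeline consumes: reads and
#' matures as FASTA, repeat annotations in RepeatMasker-out layout,
#' evidence tables as TSV, and the ground truth plus spec echo as JSON.
#'
#' @param fixture A `mir_fixture` from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_fixture_bundle <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_fasta(fixture$reads, p("reads.fasta"))
  write_fasta(tibble::tibble(id = fixture$matures$name,
                             description = "simulated mature",
                             sequence = fixture$matures$sequence),
              p("matures.fasta"))
  ann <- fixture$repeat_annotations
  ann$repeat_class <- repeat_class_of(ann$class_family)
  write_repeatmasker_out(ann, p("repeats.out"))
  utils::write.table(fixture$est_hits, p("est_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$protein_hits, p("protein_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- fixture$ground_truth
  jsonlite::write_json(list(seed = fixture$spec$seed, ground_truth = gt,
                            est_retained_families =
                              fixture$est_retained_families),
                       p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
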