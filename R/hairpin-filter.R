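#' Structural acceptance criteria for precursor candidates
#'
#' @param max_star_mismatches Maximum number of mature positions allowed to
#'   be unpaired in the mature:star duplex (default 6, the classical cap for
#'   homology-predicted plant precursors).
#' @param require_mature_in_one_arm Reject candidates whose mature sequence
#'   overlaps the terminal loop by more than `max_mature_loop_overlap`.
#' @param forbid_multibranch_in_duplex Reject candidates with a multibranch
#'   loop inside the mature:star span (automated replacement for manual
#'   multibranch elimination).
#' @param min_mfei MFEI discrimination threshold (default 0.67). By default
#'   report-only: candidates below it are flagged `low_mfei` but kept;
#'   set `enforce_mfei = TRUE` to make it a hard filter.
#' @param enforce_mfei Make `min_mfei` disqualifying.
#' @param max_mature_loop_overlap Mature nucleotides tolerated inside the
#'   terminal hairpin loop (default 0).
#' @param min_flank Minimum read flank on each side of the hit required
#'   before folding (default 20 nt).
#' @param trim_tail Unpaired tail retained on each side when trimming the
#'   precursor to the outermost stem pair (default 0 nt).
#' @param keep_flagged Keep multibranch-rejected rows in CLI/classify output
#'   tables instead of dropping them.
#' @return A list of class `mir_criteria_config`.
#' @export
criteria_config <- function(max_star_mismatches = 6L,
                            require_mature_in_one_arm = TRUE,
                            forbid_multibranch_in_duplex = TRUE,
                            min_mfei = 0.67, enforce_mfei = FALSE,
                            max_mature_loop_overlap = 0L,
                            min_flank = 20L, trim_tail = 0L,
                            keep_flagged = FALSE) {
  stopifnot(max_star_mismatches >= 0, max_mature_loop_overlap >= 0,
            min_flank >= 0, trim_tail >= 0,
            is.null(min_mfei) || min_mfei >= 0)
  structure(list(
    max_star_mismatches = as.integer(max_star_mismatches),
    require_mature_in_one_arm = isTRUE(require_mature_in_one_arm),
    forbid_multibranch_in_duplex = isTRUE(forbid_multibranch_in_duplex),
    min_mfei = min_mfei, enforce_mfei = isTRUE(enforce_mfei),
    max_mature_loop_overlap = as.integer(max_mature_loop_overlap),
    min_flank = as.integer(min_flank), trim_tail = as.integer(trim_tail),
    keep_flagged = isTRUE(keep_flagged)
  ), class = "mir_criteria_config")
}

#' Fold the read carrying a homology hit
#'
#' The whole read is folded; minus-strand hits are folded on the reverse
#' complement so the mature always appears in sense orientation, and the
#' mature coordinates are remapped accordingly.
#'
#' @param read_seq Read sequence (DNA, forward orientation).
#' @param hit One row of a [find_hits()] table (list or one-row tibble).
#' @param criteria A [criteria_config()]; only `min_flank` is used here.
#' @param params,engine Passed to [fold()].
#' @return A list with `status` (`"ok"` or `"insufficient_flank"`), `fold`
#'   (a `mir_fold` of the oriented read), and `mature_start`, `mature_end`
#'   (1-based inclusive in the folded sequence).
#' @export
fold_hit_region <- function(read_seq, hit, criteria = criteria_config(),
                            params = fold_params(), engine = "internal") {
  n <- nchar(read_seq)
  stopifnot(hit$read_start >= 1L, hit$read_end <= n)
  if (identical(hit$strand, "-")) {
    oriented <- reverse_complement(read_seq)
    ms <- n - hit$read_end + 1L
    me <- n - hit$read_start + 1L
  } else {
    oriented <- read_seq
    ms <- hit$read_start
    me <- hit$read_end
  }
  if (ms - 1L < criteria$min_flank || n - me < criteria$min_flank) {
    return(list(status = "insufficient_flank", fold = NULL,
                mature_start = ms, mature_end = me))
  }
  f <- fold(oriented, params = params, engine = engine)
  list(status = "ok", fold = f, mature_start = ms, mature_end = me)
}

#' Locate the star strand of a mature miRNA in a folded sequence
#'
#' The star region is the span of positions paired with the mature,
#' extended across interior loops and bulges by taking the full span
#' between the outermost and innermost partners. Star mismatches count the
#' mature positions that are unpaired (or paired within the mature itself)
#' in the structure.
#'
#' @param fold A `mir_fold`.
#' @param mature_start,mature_end 1-based inclusive mature interval in
#'   `fold$sequence`.
#' @return A list: `status` (`"ok"` or `"no_duplex"`), `star_start`,
#'   `star_end`, `star_mismatches`, `arm` (`"5p"`/`"3p"`/`NA`),
#'   `mature_loop_overlap` (mature nt inside a hairpin loop),
#'   `multibranch_in_duplex` (logical).
#' @export
locate_star <- function(fold, mature_start, mature_end) {
  pt <- pair_table(fold$structure)
  stopifnot(mature_start >= 1L, mature_end <= length(pt),
            mature_start <= mature_end)
  m_idx <- mature_start:mature_end
  partners <- pt[m_idx]
  outside <- partners > 0L & (partners < mature_start | partners > mature_end)
  star_mismatches <- sum(!outside)
  if (!any(outside)) {
    return(list(status = "no_duplex", star_start = NA_integer_,
                star_end = NA_integer_,
                star_mismatches = star_mismatches, arm = NA_character_,
                mature_loop_overlap = NA_integer_,
                multibranch_in_duplex = NA))
  }
  star_start <- min(partners[outside])
  star_end <- max(partners[outside])
  arm <- if (mature_end < star_start) "5p"
         else if (mature_start > star_end) "3p"
         else NA_character_
  census <- loop_census(fold$structure)
  # mature nucleotides falling inside a terminal hairpin loop
  loop_overlap <- 0L
  pt_len <- length(pt)
  for (i in seq_len(pt_len)) {
    j <- pt[i]
    if (j <= i) next
    inner <- if (i + 1L <= j - 1L) (i + 1L):(j - 1L) else integer(0)
    if (length(inner) > 0L && all(pt[inner] == 0L)) {
      loop_overlap <- loop_overlap + length(intersect(inner, m_idx))
    }
  }
  span_lo <- min(mature_start, star_start)
  span_hi <- max(mature_end, star_end)
  mb <- census$multibranch_closers
  mb_in <- nrow(mb) > 0L && any(mb[, 1] >= span_lo & mb[, 2] <= span_hi)
  list(status = "ok", star_start = star_start, star_end = star_end,
       star_mismatches = star_mismatches, arm = arm,
       mature_loop_overlap = loop_overlap, multibranch_in_duplex = mb_in)
}

#' Trim a folded read to the hairpin containing the mature:star duplex
#'
#' Starting from the outermost base pair of the duplex, the stem is followed
#' outward through stacked pairs and interior loops until the enclosing loop
#' branches (multibranch) or the external region is reached; that outermost
#' pair bounds the precursor.
#'
#' @param fold A `mir_fold` of the full read.
#' @param mature_start,mature_end Mature interval in the folded sequence.
#' @param tail Extra unpaired tail kept on each side (clipped to the
#'   sequence bounds).
#' @return A list `start`, `end` (1-based inclusive precursor interval), or
#'   `NULL` when the mature has no duplex.
#' @export
trim_to_hairpin <- function(fold, mature_start, mature_end, tail = 0L) {
  pt <- pair_table(fold$structure)
  m_idx <- mature_start:mature_end
  paired <- m_idx[pt[m_idx] > 0L &
                  (pt[m_idx] < mature_start | pt[m_idx] > mature_end)]
  if (length(paired) == 0L) return(NULL)
  ends <- c(paired, pt[paired])
  a <- min(ends)
  b <- pt[a]
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  # ascend through parents while the parent loop has this stem as its only
  # branch (stack or interior loop)
  repeat {
    parent <- enclosing_pair(pt, a, b)
    if (is.null(parent)) break
    if (n_children(pt, parent[1], parent[2]) != 1L) break
    a <- parent[1]
    b <- parent[2]
  }
  n <- length(pt)
  # the precursor always contains the full mature, even when its edge
  # bases are unpaired and fall outside the outermost stem pair
  a <- min(a, mature_start)
  b <- max(b, mature_end)
  list(start = max(1L, a - as.integer(tail)),
       end = min(n, b + as.integer(tail)))
}

# innermost pair strictly enclosing (a, b); NULL when external
enclosing_pair <- function(pt, a, b) {
  q <- a - 1L
  while (q >= 1L) {
    if (pt[q] == 0L) {
      q <- q - 1L
    } else if (pt[q] < q) {
      q <- pt[q] - 1L  # skip a sibling stem
    } else {
      return(c(q, pt[q]))
    }
  }
  NULL
}

n_children <- function(pt, i, j) {
  kids <- 0L
  p <- i + 1L
  while (p < j) {
    if (pt[p] == 0L) {
      p <- p + 1L
    } else {
      kids <- kids + 1L
      p <- pt[p] + 1L
    }
  }
  kids
}

#' Evaluate one homology hit as a precursor candidate
#'
#' Implements the two-stage structural screen: fold the whole (oriented)
#' read, locate the mature:star duplex and drop hits whose mature exceeds
#' the duplex mismatch cap; trim to the duplex-bearing hairpin, re-fold the
#' trimmed precursor, and re-evaluate all criteria on the re-fold. MFEI,
#' AMFE, GC% and MFE are computed on the trimmed precursor. Rejections are
#' data, not errors: every row carries `accepted` and a machine-readable
#' `reject_reason`.
#'
#' @param read_seq Forward-orientation read sequence (DNA).
#' @param hit One hit (list or one-row tibble) from [find_hits()].
#' @param criteria A [criteria_config()].
#' @param params,engine Passed to [fold()].
#' @param read_fold Optional pre-computed `mir_fold` of the oriented read
#'   (cache for reads carrying several hits).
#' @return A one-row candidate tibble.
#' @export
evaluate_candidate <- function(read_seq, hit, criteria = criteria_config(),
                               params = fold_params(), engine = "internal",
                               read_fold = NULL) {
  n <- nchar(read_seq)
  base <- tibble::tibble(
    read_id = hit$read_id, mirna_name = hit$mirna_name,
    family = hit$family %||% mirna_family(hit$mirna_name),
    strand = hit$strand, hit_mismatches = hit$mismatches,
    precursor_start = NA_integer_, precursor_end = NA_integer_,
    precursor_sequence = NA_character_, structure = NA_character_,
    mature_start = NA_integer_, mature_end = NA_integer_,
    arm = NA_character_, star_start = NA_integer_, star_end = NA_integer_,
    star_mismatches = NA_integer_, length = NA_integer_,
    gc_percent = NA_real_, mfe = NA_real_, amfe = NA_real_,
    mfei = NA_real_, flag_multibranch = NA, flag_mature_spans_loop = NA,
    flag_low_mfei = NA, accepted = FALSE, reject_reason = NA_character_)

  if (identical(hit$strand, "-")) {
    ms <- n - hit$read_end + 1L
    me <- n - hit$read_start + 1L
  } else {
    ms <- hit$read_start
    me <- hit$read_end
  }
  if (ms - 1L < criteria$min_flank || n - me < criteria$min_flank) {
    base$reject_reason <- "insufficient_flank"
    return(base)
  }
  f <- if (!is.null(read_fold)) {
    read_fold
  } else {
    fold_hit_region(read_seq, hit, criteria, params, engine)$fold
  }

  stage1 <- locate_star(f, ms, me)
  if (stage1$status != "ok") {
    base$reject_reason <- "no_duplex"
    base$star_mismatches <- stage1$star_mismatches
    return(base)
  }
  iv <- trim_to_hairpin(f, ms, me, tail = criteria$trim_tail)
  pre_seq <- substr(f$sequence, iv$start, iv$end)
  pf <- fold(pre_seq, params = params, engine = engine)
  pms <- ms - iv$start + 1L
  pme <- me - iv$start + 1L
  final <- locate_star(pf, pms, pme)
  stats <- hairpin_stats(pf)

  oriented_len <- n
  if (identical(hit$strand, "-")) {
    fwd_start <- oriented_len - iv$end + 1L
    fwd_end <- oriented_len - iv$start + 1L
  } else {
    fwd_start <- iv$start
    fwd_end <- iv$end
  }
  base$precursor_start <- fwd_start
  base$precursor_end <- fwd_end
  base$precursor_sequence <- pf$sequence
  base$structure <- pf$structure
  base$mature_start <- pms
  base$mature_end <- pme
  base$length <- stats$length
  base$gc_percent <- stats$gc_percent
  base$mfe <- stats$mfe
  base$amfe <- stats$amfe
  base$mfei <- stats$mfei

  if (final$status != "ok") {
    base$star_mismatches <- final$star_mismatches
    base$reject_reason <- "no_duplex"
    return(base)
  }
  base$arm <- final$arm
  base$star_start <- final$star_start
  base$star_end <- final$star_end
  # the duplex screen applies at both stages
  base$star_mismatches <- max(stage1$star_mismatches, final$star_mismatches)
  base$flag_multibranch <- isTRUE(final$multibranch_in_duplex)
  overlap <- final$mature_loop_overlap
  base$flag_mature_spans_loop <- overlap > criteria$max_mature_loop_overlap
  low_mfei <- !stats$mfei_defined ||
    (!is.null(criteria$min_mfei) && stats$mfei < criteria$min_mfei)
  base$flag_low_mfei <- low_mfei

  reason <- NA_character_
  if (base$star_mismatches > criteria$max_star_mismatches) {
    reason <- "star_mismatches"
  } else if (criteria$forbid_multibranch_in_duplex && base$flag_multibranch) {
    reason <- "multibranch_in_duplex"
  } else if (criteria$require_mature_in_one_arm &&
             base$flag_mature_spans_loop) {
    reason <- "mature_spans_loop"
  } else if (criteria$enforce_mfei && low_mfei) {
    reason <- "low_mfei"
  }
  base$accepted <- is.na(reason)
  base$reject_reason <- reason
  base
}

#' Classify all homology hits into precursor candidates
#'
#' Folds each hit-bearing read (once per orientation), evaluates every hit
#' with [evaluate_candidate()], and resolves multiple placements of the same
#' miRNA on one read by keeping the accepted candidate with the lowest
#' re-folded MFE (ties: leftmost precursor start).
#'
#' @param hits A [find_hits()] table.
#' @param reads Read tibble (`id`, `sequence`).
#' @param criteria A [criteria_config()].
#' @param params,engine Passed to [fold()].
#' @return A `mir_candidates` tibble, one row per (read, miRNA), including
#'   rejected candidates with their reasons.
#' @export
classify_hits <- function(hits, reads, criteria = criteria_config(),
                          params = fold_params(), engine = "internal") {
  read_seq <- stats::setNames(reads$sequence, reads$id)
  unknown <- setdiff(unique(hits$read_id), names(read_seq))
  if (length(unknown) > 0L) {
    stop("hit table references unknown read id(s): ",
         paste(head(unknown, 3), collapse = ", "))
  }
  fold_cache <- new.env(parent = emptyenv())
  rows <- purrr::map(seq_len(nrow(hits)), function(i) {
    hit <- as.list(hits[i, ])
    seq <- read_seq[[hit$read_id]]
    key <- paste0(hit$read_id, "|", hit$strand)
    rf <- NULL
    n <- nchar(seq)
    ms <- if (hit$strand == "-") n - hit$read_end + 1L else hit$read_start
    me <- if (hit$strand == "-") n - hit$read_start + 1L else hit$read_end
    if (ms - 1L >= criteria$min_flank && n - me >= criteria$min_flank) {
      if (!exists(key, envir = fold_cache)) {
        oriented <- if (hit$strand == "-") reverse_complement(seq) else seq
        assign(key, fold(oriented, params = params, engine = engine),
               envir = fold_cache)
      }
      rf <- get(key, envir = fold_cache)
    }
    evaluate_candidate(seq, hit, criteria, params, engine, read_fold = rf)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0L) {
    out <- out |>
      dplyr::group_by(.data$read_id, .data$mirna_name) |>
      dplyr::arrange(dplyr::desc(.data$accepted), .data$mfe,
                     .data$precursor_start, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$read_id, .data$mirna_name)
  }
  class(out) <- c("mir_candidates", class(out))
  out
}
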