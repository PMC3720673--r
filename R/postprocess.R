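#' Per-family representation counts across sequence sets
#'
#' Counts the distinct accepted candidate loci supporting each miRNA family
#' in each set (e.g. chromosome arm). To prevent over-representation,
#' identical hits for the same family collapse to one locus before
#' counting; the deduplication key is either the precursor sequence
#' (default) or the read identity.
#'
#' @param candidates A candidate tibble (from [classify_hits()]) with an
#'   additional `set` column labelling the sequence set of origin. Rejected
#'   rows (`accepted == FALSE`) are ignored.
#' @param dedup `"identical_precursor"` or `"identical_read"`.
#' @return A `mir_family_report` tibble: `family`, one count column per
#'   set, `total`, and `specificity` (`"shared"` when the family occurs in
#'   two or more sets, otherwise `"<set>-specific"`), ordered by family.
#' @export
representation <- function(candidates,
                           dedup = c("identical_precursor",
                                     "identical_read")) {
  dedup <- match.arg(dedup)
  stopifnot("set" %in% names(candidates))
  acc <- dplyr::filter(candidates, .data$accepted)
  key <- if (dedup == "identical_precursor") "precursor_sequence" else "read_id"
  sets <- sort(unique(as.character(candidates$set)))
  counts <- acc |>
    dplyr::distinct(.data$family, .data$set, .data[[key]]) |>
    dplyr::count(.data$family, .data$set, name = "n") |>
    tidyr::pivot_wider(names_from = "set", values_from = "n",
                       values_fill = 0L)
  for (s in setdiff(sets, names(counts))) counts[[s]] <- 0L
  counts <- counts[, c("family", sets), drop = FALSE]
  count_mat <- as.matrix(counts[, sets, drop = FALSE])
  present <- count_mat >= 1L
  specificity <- vapply(seq_len(nrow(counts)), function(i) {
    in_sets <- sets[present[i, ]]
    if (length(in_sets) >= 2L) "shared" else paste0(in_sets, "-specific")
  }, character(1))
  out <- counts |>
    dplyr::mutate(total = as.integer(rowSums(count_mat)),
                  specificity = specificity) |>
    dplyr::arrange(.data$family)
  class(out) <- c("mir_family_report", class(out))
  out
}

#' Descriptive statistics of a numeric vector
#'
#' Sample (n - 1) standard deviation; the median of an even-length vector
#' is the midpoint average. A single observation yields `sd = 0` with the
#' `degenerate` flag set.
#'
#' @param values Non-empty numeric vector.
#' @return One-row tibble: `n`, `mean`, `sd`, `median`, `min`, `max`,
#'   `degenerate`.
#' @export
describe_stats <- function(values) {
  if (length(values) == 0L) stop("no values to describe")
  degenerate <- length(values) == 1L
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    sd = if (degenerate) 0 else stats::sd(values),
    median = stats::median(values),
    min = min(values),
    max = max(values),
    degenerate = degenerate
  )
}

#' Read a RepeatMasker-style .out annotation table
#'
#' Parses the fixed whitespace-separated layout (two header lines plus a
#' blank line, then one row per masked interval). The class/family string is
#' mapped to a coarse class: `DNA*` to `"Class II DNA transposon"`,
#' `LINE*`/`SINE*`/`LTR*` to `"Class I retroelement"`, anything else to
#' `"other"`.
#'
#' @param path Path to a `.out`-layout file.
#' @return A tibble: `score`, `read_id`, `start`, `end`, `strand`,
#'   `repeat_name`, `class_family`, `repeat_class`, `superfamily`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[-seq_len(min(3L, length(lines)))]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    return(tibble::tibble(score = numeric(), read_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), repeat_name = character(),
                          class_family = character(),
                          repeat_class = character(),
                          superfamily = character()))
  }
  fields <- strsplit(trimws(body), "\\s+")
  grab <- function(k) vapply(fields, `[[`, character(1), k)
  cf <- grab(11)
  tibble::tibble(
    score = as.numeric(grab(1)),
    read_id = grab(5),
    start = as.integer(grab(6)),
    end = as.integer(grab(7)),
    strand = ifelse(grab(9) == "C", "-", "+"),
    repeat_name = grab(10),
    class_family = cf,
    repeat_class = repeat_class_of(cf),
    superfamily = sub("^[^/]*/?", "", cf)
  )
}

repeat_class_of <- function(class_family) {
  dplyr::case_when(
    grepl("^DNA", class_family) ~ "Class II DNA transposon",
    grepl("^(LINE|SINE|LTR)", class_family) ~ "Class I retroelement",
    TRUE ~ "other"
  )
}

#' Write repeat annotations in RepeatMasker .out layout
#'
#' @param annotations A tibble as returned by [read_repeatmasker_out()]
#'   (only `score`, `read_id`, `start`, `end`, `strand`, `repeat_name`,
#'   `class_family` are used).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(annotations, path) {
  header <- c(
    "   SW   perc perc perc  query     position in query    matching repeat      position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat  class/family  begin end (left)",
    "")
  rows <- sprintf("%5.0f %5.1f %4.1f %4.1f  %s %d %d (0) %s %s %s 1 %d (0) %d",
                  annotations$score, 0, 0, 0, annotations$read_id,
                  annotations$start, annotations$end,
                  ifelse(annotations$strand == "-", "C", "+"),
                  annotations$repeat_name, annotations$class_family,
                  annotations$end - annotations$start + 1L,
                  seq_len(nrow(annotations)))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Flag candidates overlapping masked repeat intervals
#'
#' A candidate is repeat-associated when its precursor interval on the read
#' overlaps a masked interval by at least one nucleotide; the overlap
#' fraction (of the precursor length) is also reported. Annotations that
#' reference reads absent from the candidate table are skipped with a
#' warning.
#'
#' @param candidates Candidate tibble with `read_id`, `precursor_start`,
#'   `precursor_end`.
#' @param annotations Repeat annotation tibble from
#'   [read_repeatmasker_out()].
#' @return A list: `candidates` (input plus `repeat_associated`,
#'   `repeat_overlap_nt`, `repeat_overlap_fraction`, `repeat_class`,
#'   `repeat_superfamily`) and `summary` (percent of candidates per repeat
#'   class and superfamily, plus the overall masked percentage).
#' @export
repeat_overlap <- function(candidates, annotations) {
  unknown <- setdiff(unique(annotations$read_id),
                     unique(candidates$read_id))
  if (length(unknown) > 0L) {
    warning(length(unknown),
            " annotation read id(s) not present among candidates; skipped")
    annotations <- dplyr::filter(annotations,
                                 !.data$read_id %in% unknown)
  }
  per <- purrr::map(seq_len(nrow(candidates)), function(i) {
    cs <- candidates$precursor_start[i]
    ce <- candidates$precursor_end[i]
    if (is.na(cs)) {
      return(tibble::tibble(repeat_associated = FALSE,
                            repeat_overlap_nt = 0L,
                            repeat_overlap_fraction = 0,
                            repeat_class = NA_character_,
                            repeat_superfamily = NA_character_))
    }
    ann <- annotations[annotations$read_id == candidates$read_id[i], ,
                       drop = FALSE]
    ov <- pmax(0L, pmin(ce, ann$end) - pmax(cs, ann$start) + 1L)
    hit <- which(ov > 0L)
    if (length(hit) == 0L) {
      return(tibble::tibble(repeat_associated = FALSE,
                            repeat_overlap_nt = 0L,
                            repeat_overlap_fraction = 0,
                            repeat_class = NA_character_,
                            repeat_superfamily = NA_character_))
    }
    best <- hit[which.max(ov[hit])]
    tibble::tibble(
      repeat_associated = TRUE,
      repeat_overlap_nt = as.integer(max(ov)),
      repeat_overlap_fraction = max(ov) / (ce - cs + 1L),
      repeat_class = ann$repeat_class[best],
      repeat_superfamily = ann$superfamily[best])
  })
  flagged <- dplyr::bind_rows(per)
  out <- dplyr::bind_cols(candidates, flagged)
  n <- nrow(out)
  summary <- out |>
    dplyr::filter(.data$repeat_associated) |>
    dplyr::count(.data$repeat_class, .data$repeat_superfamily) |>
    dplyr::mutate(percent = 100 * .data$n / !!n)
  list(candidates = out, summary = summary,
       percent_masked = if (n > 0) 100 * sum(flagged$repeat_associated) / n
                        else NA_real_)
}

#' Read a tabular alignment evidence file
#'
#' Expects the standard 12-column tabular alignment layout with an added
#' 13th query-coverage column and a header line:
#' `query_id subject_id identity length mismatches gaps qstart qend sstart
#' send e_value bit_score query_coverage`.
#'
#' @param path Path to a TSV evidence file.
#' @return A tibble with those columns, numeric where appropriate.
#' @export
read_evidence_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                            stringsAsFactors = FALSE))
  tb
}

#' Transcription evidence from EST and protein alignment tables
#'
#' An EST supports a family when its alignment reaches both thresholds
#' (inclusive, `coverage >= min_coverage` and `identity >= min_identity`).
#' ESTs that also match a protein at `e_value <= protein_evalue` are taken
#' as protein-coding and eliminated.
#'
#' @param est_hits Tibble with columns `family`, `est_id`,
#'   `query_coverage`, `identity`.
#' @param protein_hits Tibble with columns `est_id`, `e_value`; may be
#'   empty or `NULL`.
#' @param min_coverage,min_identity Inclusive thresholds (percent).
#' @param protein_evalue Inclusive protein-coding elimination threshold.
#' @return Tibble of surviving `(family, est_id)` pairs.
#' @export
est_evidence <- function(est_hits, protein_hits = NULL,
                         min_coverage = 99, min_identity = 98,
                         protein_evalue = 1e-3) {
  keep <- dplyr::filter(est_hits,
                        .data$query_coverage >= min_coverage,
                        .data$identity >= min_identity)
  if (!is.null(protein_hits) && nrow(protein_hits) > 0L) {
    coding <- unique(protein_hits$est_id[protein_hits$e_value <=
                                           protein_evalue])
    keep <- dplyr::filter(keep, !.data$est_id %in% coding)
  }
  dplyr::distinct(keep, .data$family, .data$est_id) |>
    dplyr::arrange(.data$family, .data$est_id)
}
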