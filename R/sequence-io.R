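#' Read a FASTA file into a tibble of sequence records
#'
#' Sequences are uppercased and converted to the requested alphabet
#' (`T` to `U` in RNA mode, `U` to `T` in DNA mode). `N` bases are kept.
#' Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param mode `"dna"` or `"rna"`; the alphabet records are normalized to.
#' @return A tibble with columns `id`, `description` and `sequence`.
#'   An empty file yields a zero-row tibble with a warning.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1 a read", "acgt"), fa)
#' read_fasta(fa, mode = "rna")
#' @export
read_fasta <- function(path, mode = c("dna", "rna")) {
  mode <- match.arg(mode)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  non_empty <- which(!grepl("^\\s*$", lines))
  if (length(non_empty) == 0L) {
    warning("empty FASTA file: ", path)
    return(tibble::tibble(id = character(), description = character(),
                          sequence = character()))
  }
  headers <- grepl("^>", lines)
  first <- non_empty[1L]
  if (!headers[first]) {
    stop("malformed FASTA: sequence before first header at line ", first,
         " of ", path)
  }
  set <- Biostrings::readBStringSet(path)
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  description <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- normalize_alphabet(unname(as.character(set)), mode)
  bad <- which(id == "" | seqs == "")
  if (length(bad) > 0L) {
    stop("malformed FASTA: empty id or sequence for record ", bad[1L])
  }
  tibble::tibble(id = id, description = description, sequence = seqs)
}

#' Write sequence records to a FASTA file
#'
#' @param records A tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) {
    records$description
  } else {
    rep("", nrow(records))
  }
  header <- ifelse(is.na(desc) | desc == "", records$id,
                   paste(records$id, desc))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- header
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

normalize_alphabet <- function(seqs, mode) {
  seqs <- toupper(seqs)
  if (mode == "rna") seqs <- chartr("T", "U", seqs) else seqs <- chartr("U", "T", seqs)
  alphabet <- if (mode == "rna") "ACGUN" else "ACGTN"
  bad <- grepl(sprintf("[^%s]", alphabet), seqs)
  if (any(bad)) {
    ch <- regmatches(seqs[bad][1L],
                     regexpr(sprintf("[^%s]", alphabet), seqs[bad][1L]))
    stop("invalid character '", ch, "' for ", mode, " alphabet in record ",
         which(bad)[1L])
  }
  seqs
}

#' Convert between DNA and RNA alphabets
#'
#' @param seq Character vector of sequences.
#' @return The same sequences with `U` substituted for `T` (or vice versa).
#' @export
dna_to_rna <- function(seq) chartr("Tt", "Uu", seq)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(seq) chartr("Uu", "Tt", seq)

#' Reverse-complement DNA sequences
#'
#' `N` complements to `N`. Vectorized over `seq`.
#'
#' @param seq Character vector of DNA sequences (alphabet `ACGTN`).
#' @return Reverse complements, same lengths.
#' @export
reverse_complement <- function(seq) {
  bad <- regexpr("[^ACGTNacgtn]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("invalid DNA character at position ", bad[i], " of sequence ", i)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Read a miRBase-style mature miRNA FASTA
#'
#' Headers are parsed as `>name optional-description` where `name` is a
#' species-prefixed miRNA name such as `tae-miR2118` or `osa-miR169a`.
#' The family is derived from the name (see [mirna_family()]) and the
#' sequence normalized to RNA.
#'
#' @param path Path to a mature-miRNA FASTA file.
#' @param min_len,max_len Accepted mature length bounds; records outside the
#'   bounds are dropped with a warning.
#' @return A tibble with columns `name`, `family`, `species`, `sequence`.
#' @export
read_mature_mirnas <- function(path, min_len = 18L, max_len = 26L) {
  rec <- read_fasta(path, mode = "rna")
  out <- tibble::tibble(
    name = rec$id,
    family = mirna_family(rec$id),
    species = mirna_species(rec$id),
    sequence = rec$sequence
  )
  len <- nchar(out$sequence)
  drop <- len < min_len | len > max_len
  if (any(drop)) {
    warning(sum(drop), " mature record(s) outside length bounds [",
            min_len, ", ", max_len, "] dropped")
    out <- out[!drop, , drop = FALSE]
  }
  out
}

#' Derive the miRNA family from a species-prefixed miRNA name
#'
#' The rule: strip the three-letter species prefix, normalize the `mir`/`miR`
#' tag to `miR`, keep the core family number, and strip trailing variant
#' suffixes (lettered paralog tags such as `a`, `b-5p`, arm tags `-5p`/`-3p`,
#' and dotted or dashed numeric sub-variants such as `.2` or `-2` after a
#' letter). A bare trailing number that is part of the family identifier is
#' kept (`miR5049` stays `miR5049`).
#'
#' @param name Character vector of miRNA names, e.g. `"tae-miR169a-5p"`.
#' @return Character vector of family names, e.g. `"miR169"`.
#' @examples
#' mirna_family(c("tae-miR2118", "ath-miR169a", "osa-miR169a-5p", "bdi-miR5049"))
#' @export
mirna_family <- function(name) {
  x <- sub("^[A-Za-z]{3,4}-", "", name)
  x <- sub("^(mir|miR|MIR)", "miR", x)
  core <- stringr::str_match(x, "^miR-?([0-9]+)")[, 2L]
  ifelse(is.na(core), x, paste0("miR", core))
}

#' @rdname mirna_family
#' @return `mirna_species()`: the species prefix (e.g. `"tae"`), or `NA`
#'   when the name carries none.
#' @export
mirna_species <- function(name) {
  sp <- stringr::str_match(name, "^([A-Za-z]{3,4})-")[, 2L]
  sp
}

#' Remove mature miRNAs with identical sequences
#'
#' Entries sharing a sequence string collapse to the first occurrence, which
#' mirrors how redundant miRBase matures are removed before a homology
#' search. Input order is preserved for the retained entries.
#'
#' @param matures A tibble as returned by [read_mature_mirnas()].
#' @return A list with `matures` (the retained tibble) and `merge_map`
#'   (a tibble with columns `name`, `retained` mapping every input name to
#'   its retained representative).
#' @export
dedup_matures <- function(matures) {
  stopifnot(all(c("name", "sequence") %in% names(matures)))
  first_idx <- match(matures$sequence, matures$sequence)
  keep <- first_idx == seq_len(nrow(matures))
  merge_map <- tibble::tibble(
    name = matures$name,
    retained = matures$name[first_idx]
  )
  list(matures = matures[keep, , drop = FALSE], merge_map = merge_map)
}
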