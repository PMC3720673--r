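#' Predict the minimum-free-energy secondary structure of an RNA
#'
#' The default engine is a deterministic Zuker-style dynamic program over
#' the nearest-neighbor model described in [fold_params()]: pseudoknot-free
#' structures, Watson-Crick plus G-U pairs, minimum hairpin loop of 3 nt,
#' `N` never pairs. Among co-optimal structures the traceback applies a
#' fixed preference order (stacking/interior continuation before hairpin
#' closure before multibranch, smaller indices first), so identical inputs
#' always give identical structures.
#'
#' @param seq RNA sequence (string, alphabet `ACGUN`; `T` is accepted and
#'   read as `U`), length >= 10.
#' @param params A [fold_params()] object.
#' @param engine `"internal"` or a function `(seq, params) -> list(structure,
#'   mfe)` implementing the same contract, for plugging in an external
#'   thermodynamic engine. Downstream criteria only consume the returned
#'   structure and energy, so swapping engines never changes the data flow.
#' @return An object of class `mir_fold`: list with `sequence`, `structure`
#'   (dot-bracket), `mfe` (kcal/mol, <= 0) and `engine`.
#' @examples
#' fold("GGGGCGAAAACGCCCC")
#' @export
fold <- function(seq, params = fold_params(), engine = "internal") {
  seq <- dna_to_rna(toupper(seq))
  if (nchar(seq) < 10L) {
    stop("sequence too short to fold (", nchar(seq), " nt, need >= 10)")
  }
  if (grepl("[^ACGUN]", seq)) {
    stop("non-RNA character at position ", regexpr("[^ACGUN]", seq))
  }
  if (is.function(engine)) {
    res <- engine(seq, params)
    out <- structure(list(sequence = seq, structure = res$structure,
                          mfe = res$mfe, engine = res$engine %||% "external"),
                     class = "mir_fold")
    return(out)
  }
  stopifnot(identical(engine, "internal"))
  n <- nchar(seq)
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U", "N")) - 1L
  pi <- fold_params_int(params, n)
  res <- fold_engine_cpp(codes, pi$stack, pi$hairpin, pi$interior,
                         pi$mb_close, pi$mb_branch, pi$mb_unpaired,
                         pi$min_hairpin)
  structure(list(sequence = seq, structure = res$structure,
                 mfe = res$energy / 10, engine = params$version),
            class = "mir_fold")
}

#' @export
print.mir_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", sprintf("%.1f", x$mfe), ")\n",
      sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pair table of a dot-bracket structure
#'
#' @param structure Dot-bracket string (characters `.`, `(`, `)`).
#' @return Integer vector: position `i` holds the 1-based partner of base
#'   `i`, or 0 when unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  bad <- which(!ch %in% c(".", "(", ")"))
  if (length(bad) > 0L) {
    stop("invalid dot-bracket character at position ", bad[1L])
  }
  pt <- integer(length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (length(open) == 0L) stop("unbalanced structure: ')' at ", i)
      j <- open[length(open)]
      open <- open[-length(open)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(open) > 0L) {
    stop("unbalanced structure: unmatched '(' at ", open[1L])
  }
  pt
}

#' GC content of a sequence, in percent
#'
#' `N` counts in the denominator only.
#'
#' @param seq Non-empty sequence string.
#' @return Percentage on the 0-100 scale.
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  ch <- charToRaw(toupper(seq))
  100 * sum(ch == charToRaw("G") | ch == charToRaw("C")) / length(ch)
}

#' Adjusted MFE and minimal folding free-energy index
#'
#' `amfe(mfe, length)` is `|mfe| / length * 100` (kcal/mol per 100 nt);
#' `mfei(mfe, length, gc_percent)` divides it by the GC percentage (0-100
#' scale). Vectorized.
#'
#' @param mfe Minimum free energy (kcal/mol, <= 0).
#' @param length Sequence length (nt).
#' @param gc_percent GC content, percent (0-100).
#' @return Numeric vector.
#' @examples
#' mfei(-61.82, 130, 40.45)
#' @export
amfe <- function(mfe, length) abs(mfe) / length * 100

#' @rdname amfe
#' @export
mfei <- function(mfe, length, gc_percent) {
  ifelse(gc_percent > 0, amfe(mfe, length) / gc_percent, NA_real_)
}

#' Thermodynamic summary statistics of a folded precursor
#'
#' AMFE is the adjusted MFE, `|MFE| / length * 100` (kcal/mol per 100 nt);
#' MFEI is the minimal folding free-energy index, `AMFE / GC%` with GC on
#' the 0-100 scale. MFEI separates miRNA precursors (typically > 0.67) from
#' other cellular RNAs. Values are reported to 3 decimals.
#'
#' @param fold A `mir_fold` object.
#' @return One-row tibble: `length`, `gc_percent`, `mfe`, `amfe`, `mfei`,
#'   `mfei_defined` (FALSE when GC is 0, in which case `mfei` is `NA`).
#' @export
hairpin_stats <- function(fold) {
  stopifnot(inherits(fold, "mir_fold"))
  len <- nchar(fold$sequence)
  gc <- gc_content(fold$sequence)
  mfei_defined <- gc > 0
  tibble::tibble(
    length = len,
    gc_percent = round(gc, 3),
    mfe = fold$mfe,
    amfe = round(amfe(fold$mfe, len), 3),
    mfei = round(mfei(fold$mfe, len, gc), 3),
    mfei_defined = mfei_defined
  )
}

#' Count the loops of a secondary structure
#'
#' Loops are classified by the standard nesting decomposition: a pair whose
#' enclosed region contains no other pair closes a hairpin loop; exactly one
#' directly nested pair with at least one unpaired base between them closes
#' an interior loop or bulge; two or more directly nested pairs close a
#' multibranch loop. Stacked pairs (no intervening unpaired bases) close no
#' loop.
#'
#' @param structure Dot-bracket string.
#' @return A list with integer counts `hairpin`, `interior` (bulges
#'   included) and `multibranch`, plus `multibranch_closers`, the 1-based
#'   `(i, j)` pairs closing each multibranch loop (two-column matrix).
#' @export
loop_census <- function(structure) {
  pt <- pair_table(structure)
  n <- length(pt)
  hairpin <- 0L
  interior <- 0L
  multibranch <- 0L
  closers <- NULL
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j <= i) next
    # direct children of pair (i, j)
    kids <- 0L
    unpaired <- 0L
    first_kid <- NA_integer_
    p <- i + 1L
    while (p < j) {
      if (pt[p] == 0L) {
        unpaired <- unpaired + 1L
        p <- p + 1L
      } else {
        kids <- kids + 1L
        if (is.na(first_kid)) first_kid <- p
        p <- pt[p] + 1L
      }
    }
    if (kids == 0L) {
      hairpin <- hairpin + 1L
    } else if (kids == 1L) {
      if (unpaired > 0L) interior <- interior + 1L
    } else {
      multibranch <- multibranch + 1L
      closers <- rbind(closers, c(i, j))
    }
  }
  list(hairpin = hairpin, interior = interior, multibranch = multibranch,
       multibranch_closers = if (is.null(closers)) {
         matrix(integer(0), ncol = 2)
       } else {
         closers
       })
}

#' Write folds in Vienna dot-bracket format
#'
#' Each record is a `>id` header, the sequence line, and the structure line
#' suffixed with the energy in parentheses.
#'
#' @param folds A list of `mir_fold` objects (optionally named; names become
#'   record ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(folds, path) {
  ids <- names(folds) %||% paste0("fold", seq_along(folds))
  if (is.null(names(folds))) names(folds) <- ids
  lines <- unlist(purrr::imap(folds, function(f, id) {
    c(paste0(">", id), f$sequence,
      sprintf("%s (%.1f)", f$structure, f$mfe))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
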