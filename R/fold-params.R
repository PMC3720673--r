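#' Nearest-neighbor energy parameters for the internal folding engine
#'
#' The internal engine scores pseudoknot-free secondary structures with a
#' loop-based nearest-neighbor model: a 6x6 helix stacking table over the
#' canonical pairs (Watson-Crick plus G-U wobble), affine hairpin and
#' interior/bulge loop penalties, and a linear multibranch term. Values are
#' kcal/mol in the style of published Turner-rule stacking sets; internally
#' all arithmetic is done in integer tenths of kcal/mol so results are
#' bit-reproducible across platforms.
#'
#' Model conventions: minimum hairpin loop 3 nt; interior/bulge loops larger
#' than `interior_max` unpaired nt are disallowed; no dangling ends, coaxial
#' stacking or terminal-pair corrections; `N` never pairs.
#'
#' @param hairpin_base,hairpin_per_nt Hairpin loop penalty:
#'   `hairpin_base + hairpin_per_nt * (size - 3)` kcal/mol.
#' @param interior_base,interior_per_nt Interior/bulge penalty:
#'   `interior_base + interior_per_nt * size` kcal/mol, `size` the total
#'   unpaired count on both sides.
#' @param interior_max Largest allowed interior/bulge size (unpaired nt).
#' @param multibranch_close,multibranch_branch,multibranch_unpaired
#'   Multibranch loop energy: `close + branch * (helices incident on the
#'   loop) + unpaired * (unpaired nt in the loop)`.
#' @param min_hairpin Minimum unpaired length of a hairpin loop.
#' @return A list of class `mir_fold_params` with a `stack` matrix (rows =
#'   outer pair 5'-3', columns = inner pair) and the loop coefficients.
#' @export
fold_params <- function(hairpin_base = 4.5, hairpin_per_nt = 0.25,
                        interior_base = 2.0, interior_per_nt = 0.3,
                        interior_max = 30L,
                        multibranch_close = 4.6, multibranch_branch = 0.4,
                        multibranch_unpaired = 0.1, min_hairpin = 3L) {
  pairs <- c("AU", "CG", "GC", "UA", "GU", "UG")
  stack <- matrix(c(
    # inner:  AU    CG    GC    UA    GU    UG
    -0.9, -2.2, -2.1, -1.1, -0.6, -1.4,  # outer AU
    -2.1, -3.3, -2.4, -2.1, -1.4, -2.1,  # outer CG
    -2.4, -3.4, -3.3, -2.2, -1.5, -2.5,  # outer GC
    -1.3, -2.4, -2.1, -0.9, -1.0, -1.3,  # outer UA
    -1.3, -2.5, -2.1, -1.4, -0.5,  1.3,  # outer GU
    -1.0, -1.5, -1.4, -0.6,  0.3, -0.5   # outer UG
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  structure(list(
    stack = stack,
    hairpin_base = hairpin_base, hairpin_per_nt = hairpin_per_nt,
    interior_base = interior_base, interior_per_nt = interior_per_nt,
    interior_max = as.integer(interior_max),
    multibranch_close = multibranch_close,
    multibranch_branch = multibranch_branch,
    multibranch_unpaired = multibranch_unpaired,
    min_hairpin = as.integer(min_hairpin),
    version = "mirsurvey-nn-1"
  ), class = "mir_fold_params")
}

# decikcal integerization shared by the engine and any scorer
fold_params_int <- function(params, n) {
  sizes <- 0:n
  hairpin <- ifelse(sizes < params$min_hairpin, NA_integer_,
                    as.integer(round(10 * (params$hairpin_base +
                      params$hairpin_per_nt * (sizes - 3)))))
  interior <- ifelse(sizes == 0L | sizes > params$interior_max, NA_integer_,
                     as.integer(round(10 * (params$interior_base +
                       params$interior_per_nt * sizes))))
  inf <- 100000000L
  list(
    stack = matrix(as.integer(round(10 * params$stack)), 6, 6),
    hairpin = ifelse(is.na(hairpin), inf, hairpin),
    interior = ifelse(is.na(interior), inf, interior),
    mb_close = as.integer(round(10 * params$multibranch_close)),
    mb_branch = as.integer(round(10 * params$multibranch_branch)),
    mb_unpaired = as.integer(round(10 * params$multibranch_unpaired)),
    min_hairpin = params$min_hairpin
  )
}
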