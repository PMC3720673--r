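#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a candidate table
#'
#' @param x A `mir_candidates` tibble.
#' @param ... Unused.
#' @return A tibble with the identifying, structural and thermodynamic
#'   columns, one row per candidate.
#' @method tidy mir_candidates
#' @export
tidy.mir_candidates <- function(x, ...) {
  tibble::as_tibble(x)[, c("read_id", "mirna_name", "family", "strand",
                           "arm", "star_mismatches", "length", "gc_percent",
                           "mfe", "amfe", "mfei", "accepted",
                           "reject_reason")]
}

#' One-row summary of a candidate table
#'
#' @param x A `mir_candidates` tibble.
#' @param ... Unused.
#' @return A tibble with candidate, acceptance and family counts plus mean
#'   MFE/MFEI of accepted candidates.
#' @method glance mir_candidates
#' @export
glance.mir_candidates <- function(x, ...) {
  acc <- x[x$accepted, , drop = FALSE]
  tibble::tibble(
    n_candidates = nrow(x),
    n_accepted = nrow(acc),
    n_families = length(unique(acc$family)),
    mean_mfe = if (nrow(acc)) mean(acc$mfe) else NA_real_,
    mean_mfei = if (nrow(acc)) mean(acc$mfei, na.rm = TRUE) else NA_real_
  )
}

#' MFEI distribution plot of a candidate table
#'
#' Accepted and rejected candidates are overlaid with the classical MFEI
#' discrimination threshold (0.67) marked.
#'
#' @param object A `mir_candidates` tibble.
#' @param threshold Reference MFEI threshold to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mir_candidates
#' @export
autoplot.mir_candidates <- function(object, threshold = 0.67, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$mfei), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mfei, fill = .data$accepted)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "MFEI", y = "candidates", fill = "accepted") +
    ggplot2::theme_minimal()
}

#' Family representation bar plot
#'
#' @param object A `mir_family_report` from [representation()].
#' @param ... Unused.
#' @return A ggplot object with per-set counts by family.
#' @method autoplot mir_family_report
#' @export
autoplot.mir_family_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = -c("family", "total", "specificity"),
    names_to = "set", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$family, y = .data$count,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "representation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
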