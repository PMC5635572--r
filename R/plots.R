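#' Plot the unique-overlap token histogram
#'
#' Bar chart of the number of unique lexical overlaps by the token count of
#' the overlapped string — the classic profile of a compositional ontology
#' peaks at two-token overlaps.
#'
#' @param object A [find_overlaps()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synsub_overlaps <- function(object, ...) {
  hist <- overlap_token_histogram(object)
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$n_tokens),
                                     y = .data$n_overlaps)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "tokens in the overlapped string",
                  y = "unique lexical overlaps") +
    ggplot2::theme_minimal()
}

#' Plot the IC bin distribution of a term universe
#'
#' @param object An [information_content()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synsub_ic <- function(object, ...) {
  bins <- bin_ic(object)
  ggplot2::ggplot(bins, ggplot2::aes(x = factor(.data$bin,
                                                levels = .data$bin),
                                     y = .data$n_terms)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "information content", y = "terms") +
    ggplot2::theme_minimal()
}

#' Plot the stage funnel of an enrichment run
#'
#' Shows how many strings survive each stage: synonyms after pruning,
#' unique overlaps, generated candidates, novel strings, and accepted
#' synonyms.
#'
#' @param object A [enrich_ontology()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synsub_enrichment <- function(object, ...) {
  s <- object$stats
  df <- tibble::tibble(
    stage = factor(
      c("synonyms (pruned)", "unique overlaps", "generated", "novel strings",
        "accepted"),
      levels = c("synonyms (pruned)", "unique overlaps", "generated",
                 "novel strings", "accepted")
    ),
    n = c(s$n_synonyms_after, s$n_unique_overlaps, s$n_generated,
          s$n_novel_strings, nrow(object$accepted))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "count (log scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot retrieval increase rates by IC bin
#'
#' @param report A [retrieval_increase()] result.
#' @return A ggplot object.
#' @export
plot_retrieval_increase <- function(report) {
  df <- dplyr::filter(report, .data$volume_band == "Total")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$ic_bin,
                                              levels = unique(.data$ic_bin)),
                                   y = .data$increase_rate)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "information content", y = "increase rate (%)") +
    ggplot2::theme_minimal()
}
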