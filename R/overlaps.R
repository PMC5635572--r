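#' Find lexical overlaps between hierarchically related terms
#'
#' A lexical overlap is a synonym of an ancestor term occurring as a proper
#' contiguous token subsequence inside a synonym of one of its (direct or
#' indirect) descendants — e.g. \emph{hearing loss} inside
#' \emph{sensorineural hearing loss}. For every pair in the transitive
#' closure and every (ancestor synonym, descendant synonym) combination, one
#' record is produced per containment occurrence, with the overlapped span
#' in 0-based token coordinates of the descendant synonym. Synonyms of the
#' same term are never compared against each other. Redundancy removal
#' ([remove_redundant_synonyms()]) is expected to have been applied first.
#'
#' @param ontology A (pruned) [ontology()] object.
#' @param closure Optional precomputed [term_closure()] tibble; computed
#'   over the whole ontology when `NULL`.
#' @return A tibble of class `synsub_overlaps`, one row per occurrence, with
#'   columns `ancestor_id`, `descendant_id`, `ancestor_synonym`,
#'   `ancestor_scope`, `descendant_synonym`, `descendant_scope`,
#'   `ancestor_norm`, `descendant_norm`, `start`, `n_tokens` (the span is
#'   `[start, start + n_tokens)`), in deterministic order.
#' @export
find_overlaps <- function(ontology, closure = NULL) {
  stopifnot(inherits(ontology, "synsub_ontology"))
  if (is.null(closure)) closure <- term_closure(ontology)
  syn <- active_synonyms(ontology)
  syn$n_tok <- lengths(strsplit(syn$norm, " ", fixed = TRUE))

  anc <- dplyr::select(syn, ancestor_id = "id", ancestor_synonym = "text",
                       ancestor_scope = "scope", ancestor_norm = "norm",
                       anc_tok = "n_tok")
  des <- dplyr::select(syn, descendant_id = "id", descendant_synonym = "text",
                       descendant_scope = "scope", descendant_norm = "norm",
                       des_tok = "n_tok")
  combos <- dplyr::inner_join(closure, anc, by = "ancestor_id",
                              relationship = "many-to-many")
  combos <- dplyr::inner_join(combos, des, by = "descendant_id",
                              relationship = "many-to-many")
  combos <- dplyr::filter(combos, .data$des_tok > .data$anc_tok)
  if (nrow(combos) > 0) {
    combos <- dplyr::filter(combos, stringr::str_detect(
      pad_phrase(.data$descendant_norm),
      stringr::fixed(pad_phrase(.data$ancestor_norm))
    ))
  }
  if (nrow(combos) == 0) {
    out <- tibble::tibble(
      ancestor_id = character(), descendant_id = character(),
      ancestor_synonym = character(), ancestor_scope = character(),
      descendant_synonym = character(), descendant_scope = character(),
      ancestor_norm = character(), descendant_norm = character(),
      start = integer(), n_tokens = integer()
    )
    return(structure(out, class = c("synsub_overlaps", class(out))))
  }

  # expand each detected containment into its occurrence positions
  starts <- purrr::map2(
    strsplit(combos$descendant_norm, " ", fixed = TRUE),
    strsplit(combos$ancestor_norm, " ", fixed = TRUE),
    token_starts
  )
  combos$start <- starts
  out <- tidyr::unnest(combos, "start")
  out <- dplyr::transmute(out,
    ancestor_id = .data$ancestor_id, descendant_id = .data$descendant_id,
    ancestor_synonym = .data$ancestor_synonym,
    ancestor_scope = .data$ancestor_scope,
    descendant_synonym = .data$descendant_synonym,
    descendant_scope = .data$descendant_scope,
    ancestor_norm = .data$ancestor_norm,
    descendant_norm = .data$descendant_norm,
    start = as.integer(.data$start), n_tokens = as.integer(.data$anc_tok)
  )
  out <- dplyr::arrange(out, .data$ancestor_id, .data$descendant_id,
                        .data$ancestor_norm, .data$descendant_norm, .data$start)
  structure(out, class = c("synsub_overlaps", class(tibble::tibble())))
}

#' Unique lexical overlaps and their token histogram
#'
#' Two occurrences count as the same overlap when they share the ordered
#' pair (normalized ancestor string, normalized descendant string); the
#' token count of an overlap identity is that of the overlapped (ancestor)
#' string. `unique_overlaps()` returns one row per identity;
#' `overlap_token_histogram()` tabulates identities by token count.
#'
#' @param overlaps A [find_overlaps()] result.
#' @return `unique_overlaps()`: tibble with `ancestor_norm`,
#'   `descendant_norm`, `n_tokens`, `n_occurrences`, `n_term_pairs`.
#'   `overlap_token_histogram()`: tibble with `n_tokens`, `n_overlaps`.
#' @export
unique_overlaps <- function(overlaps) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(overlaps),
                    .data$ancestor_norm, .data$descendant_norm),
    n_tokens = .data$n_tokens[1],
    n_occurrences = dplyr::n(),
    n_term_pairs = dplyr::n_distinct(paste(.data$ancestor_id, .data$descendant_id)),
    .groups = "drop"
  )
}

#' @rdname unique_overlaps
#' @export
overlap_token_histogram <- function(overlaps) {
  dplyr::count(unique_overlaps(overlaps), .data$n_tokens, name = "n_overlaps")
}

#' Overlap summary counts
#'
#' One-row tibble with the occurrence total and both deduplicated counts the
#' "unique overlap" statistic can refer to: unique (ancestor string,
#' descendant string) pairs — the convention used for reporting — and unique
#' (ancestor term, descendant term) pairs.
#'
#' @param x A [find_overlaps()] result.
#' @param ... Unused.
#' @export
glance.synsub_overlaps <- function(x, ...) {
  u <- unique_overlaps(x)
  tibble::tibble(
    n_occurrences = nrow(tibble::as_tibble(x)),
    n_unique_string_pairs = nrow(u),
    n_unique_term_pairs = dplyr::n_distinct(
      paste(x$ancestor_id, x$descendant_id)),
    max_tokens = if (nrow(u) > 0) max(u$n_tokens) else NA_integer_
  )
}
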