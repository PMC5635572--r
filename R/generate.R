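#' Combine synonym scopes under the restrictiveness ordering
#'
#' The scope of a generated synonym is the weakest synonymy claim among the
#' scopes that produced it, under the ordering
#' `EXACT > NARROW = BROAD > RELATED > UNSPECIFIED`; the incomparable pair
#' `NARROW`/`BROAD` meets at `RELATED`. `scope_meet()` is the vectorized
#' pairwise meet (commutative and associative); `infer_scope()` applies it
#' to the three scopes involved in a substitution: the descendant synonym,
#' the overlapped ancestor synonym, and the replacement synonym.
#'
#' @param a,b Character vectors of scopes (recycled).
#' @return Character vector of scopes.
#' @examples
#' infer_scope("EXACT", "EXACT", "RELATED")  # "RELATED"
#' scope_meet("NARROW", "BROAD")             # "RELATED"
#' @export
scope_meet <- function(a, b) {
  assert_scope(a, "a"); assert_scope(b, "b")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  ra <- scope_rank[a]; rb <- scope_rank[b]
  out <- ifelse(ra <= rb, a, b)
  # NARROW meets BROAD at RELATED: equal rank, different claim
  out[ra == 3L & rb == 3L & a != b] <- "RELATED"
  unname(out)
}

#' @rdname scope_meet
#' @param descendant,ancestor,replacement Scopes of the descendant synonym,
#'   the overlapped ancestor synonym, and the substituted replacement.
#' @export
infer_scope <- function(descendant, ancestor, replacement) {
  scope_meet(scope_meet(descendant, ancestor), replacement)
}

# splice replacement tokens into the descendant's token list and restore a
# leading capital iff the descendant surface led with one; reproduces the
# printed casing of generated synonyms ("Cortical cataract" + "Lens
# opacities" -> "Cortical lens opacities")
splice_candidate <- function(descendant_surface, descendant_tokens,
                             start, len, replacement_norm) {
  n <- length(descendant_tokens)
  text <- paste(
    c(descendant_tokens[seq_len(start)],
      replacement_norm,
      if (start + len < n) descendant_tokens[(start + len + 1L):n]),
    collapse = " "
  )
  first <- stringr::str_extract(descendant_surface, "[[:alpha:]]")
  if (!is.na(first) && first == toupper(first)) {
    text <- sub("^([[:lower:]])", "\\U\\1", text, perl = TRUE)
  }
  text
}

#' Generate one candidate synonym by substitution
#'
#' Replaces one occurrence of the overlapped string inside the descendant
#' synonym with a replacement synonym of the ancestor term, preserving the
#' surrounding tokens: substituting \emph{hearing defect} for
#' \emph{hearing loss} in \emph{sensorineural hearing loss} yields
#' \emph{sensorineural hearing defect}.
#'
#' @param descendant Descendant synonym surface string.
#' @param overlapped The overlapped (ancestor synonym) string.
#' @param replacement The replacement synonym of the ancestor term; must
#'   differ from `overlapped` after normalization.
#' @param start Optional 0-based token position of the occurrence to
#'   replace; the first occurrence when `NULL`.
#' @return The candidate synonym string.
#' @examples
#' substitute_synonym("sensorineural hearing loss", "hearing loss",
#'                    "hearing defect")
#' substitute_synonym("Cortical cataract", "cataract", "Lens opacities")
#' @export
substitute_synonym <- function(descendant, overlapped, replacement, start = NULL) {
  d_tok <- phrase_tokens(descendant)[[1]]
  o_tok <- phrase_tokens(overlapped)[[1]]
  r_norm <- normalize_phrase(replacement)
  if (identical(r_norm, paste(o_tok, collapse = " "))) {
    abort("replacement is identical to the overlapped string: substitution is a no-op")
  }
  pos <- token_starts(d_tok, o_tok)
  if (length(pos) == 0) {
    abort(sprintf("\"%s\" does not contain \"%s\"", descendant, overlapped))
  }
  if (is.null(start)) start <- pos[1]
  if (!start %in% pos) {
    abort(sprintf("no occurrence of \"%s\" at token position %d", overlapped, start))
  }
  splice_candidate(descendant, d_tok, start, length(o_tok), r_norm)
}

#' Generate all candidate synonyms from the lexical overlaps
#'
#' For every overlap occurrence and every synonym of the ancestor term other
#' than the overlapped one, a candidate synonym for the descendant term is
#' produced by [substitute_synonym()], with its scope inferred by
#' [infer_scope()]. With `max_depth > 1`, candidates from the previous depth
#' are re-scanned for the same overlap strings of their term and substituted
#' again. The raw output (the multiset \eqn{A}) is then partitioned against
#' the ontology's synonym strings (the set \eqn{B}): `existing` rows are
#' candidates whose normalized string already occurs anywhere in the
#' ontology, `novel` rows are the set difference. Candidates whose string
#' properly contains another synonym of their own term are additionally
#' flagged `redundant` (the same pruning rule applied to the input), and
#' `eligible = novel & !redundant` marks the candidates that may enter the
#' enriched ontology.
#'
#' @param ontology A (pruned) [ontology()] object.
#' @param overlaps A [find_overlaps()] result computed on `ontology`.
#' @param max_depth Maximum substitution depth (default 1: every printed
#'   example of the method is a single substitution).
#' @return An object of class `synsub_generation`: a list with `candidates`
#'   (tibble, one row per generated candidate with provenance and flags) and
#'   `max_depth`. Use [glance()] for the count summary.
#' @export
generate_candidates <- function(ontology, overlaps, max_depth = 1L) {
  stopifnot(inherits(ontology, "synsub_ontology"))
  if (!is.numeric(max_depth) || max_depth < 1) {
    abort("`max_depth` must be a positive integer")
  }
  syn <- active_synonyms(ontology)
  term_names <- setNames(ontology$terms$name, ontology$terms$id)
  global_norms <- unique(syn$norm)

  repl <- dplyr::select(syn, ancestor_id = "id", replacement = "text",
                        replacement_scope = "scope", replacement_norm = "norm")

  expand_depth <- function(ov, depth) {
    # ov: overlap-shaped tibble (occurrence rows)
    rows <- dplyr::inner_join(tibble::as_tibble(ov), repl, by = "ancestor_id",
                              relationship = "many-to-many")
    rows <- dplyr::filter(rows, .data$replacement_norm != .data$ancestor_norm)
    if (nrow(rows) == 0) return(NULL)
    d_tok <- strsplit(rows$descendant_norm, " ", fixed = TRUE)
    rows$text <- purrr::pmap_chr(
      list(rows$descendant_synonym, d_tok, rows$start, rows$n_tokens,
           rows$replacement_norm),
      splice_candidate
    )
    tibble::tibble(
      term_id = rows$descendant_id,
      term_name = unname(term_names[rows$descendant_id]),
      text = rows$text,
      norm = normalize_phrase(rows$text),
      scope = infer_scope(rows$descendant_scope, rows$ancestor_scope,
                          rows$replacement_scope),
      ancestor_id = rows$ancestor_id,
      substituted_synonym = rows$replacement,
      overlap_string = rows$ancestor_synonym,
      descendant_synonym = rows$descendant_synonym,
      depth = depth
    )
  }

  all_rows <- expand_depth(overlaps, 1L)
  if (max_depth > 1 && !is.null(all_rows)) {
    # overlap identities applicable to each descendant term
    idents <- dplyr::distinct(
      tibble::as_tibble(overlaps),
      .data$descendant_id, .data$ancestor_id, .data$ancestor_synonym,
      .data$ancestor_scope, .data$ancestor_norm, .data$n_tokens
    )
    seen <- unique(paste(all_rows$term_id, all_rows$norm))
    frontier <- dplyr::distinct(all_rows, .data$term_id, .data$text,
                                .data$norm, .data$scope)
    for (depth in 2:max_depth) {
      if (nrow(frontier) == 0) break
      scan <- dplyr::inner_join(
        dplyr::rename(frontier, descendant_id = "term_id"),
        idents, by = "descendant_id", relationship = "many-to-many"
      )
      if (nrow(scan) == 0) break
      starts <- purrr::map2(
        strsplit(scan$norm, " ", fixed = TRUE),
        strsplit(scan$ancestor_norm, " ", fixed = TRUE),
        token_starts
      )
      scan$start <- starts
      scan <- tidyr::unnest(scan, "start")
      if (nrow(scan) == 0) break
      ov_d <- dplyr::transmute(scan,
        ancestor_id = .data$ancestor_id, descendant_id = .data$descendant_id,
        ancestor_synonym = .data$ancestor_synonym,
        ancestor_scope = .data$ancestor_scope,
        descendant_synonym = .data$text, descendant_scope = .data$scope,
        ancestor_norm = .data$ancestor_norm, descendant_norm = .data$norm,
        start = as.integer(.data$start), n_tokens = .data$n_tokens
      )
      new_rows <- expand_depth(ov_d, depth)
      if (is.null(new_rows)) break
      key <- paste(new_rows$term_id, new_rows$norm)
      fresh <- !key %in% seen
      all_rows <- dplyr::bind_rows(all_rows, new_rows)
      seen <- c(seen, unique(key[fresh]))
      frontier <- dplyr::distinct(new_rows[fresh, ], .data$term_id,
                                  .data$text, .data$norm, .data$scope)
    }
  }

  if (is.null(all_rows)) {
    all_rows <- tibble::tibble(
      term_id = character(), term_name = character(), text = character(),
      norm = character(), scope = character(), ancestor_id = character(),
      substituted_synonym = character(), overlap_string = character(),
      descendant_synonym = character(), depth = integer()
    )
  }

  all_rows$existing <- all_rows$norm %in% global_norms
  all_rows$novel <- !all_rows$existing

  # redundancy rule against the candidate's own term
  own <- dplyr::select(syn, term_id = "id", own_norm = "norm")
  red <- dplyr::inner_join(
    dplyr::mutate(dplyr::select(all_rows, "term_id", "norm"),
                  ..row = dplyr::row_number()),
    own, by = "term_id", relationship = "many-to-many"
  )
  red <- dplyr::filter(red, phrase_contains(.data$norm, .data$own_norm,
                                            proper = TRUE))
  all_rows$redundant <- seq_len(nrow(all_rows)) %in% red$..row
  all_rows$eligible <- all_rows$novel & !all_rows$redundant

  structure(
    list(candidates = all_rows, max_depth = as.integer(max_depth)),
    class = "synsub_generation"
  )
}

#' @export
print.synsub_generation <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<synsub_generation> depth %d: %d generated (%d distinct strings), %d already in ontology, %d novel strings\n",
    x$max_depth, g$n_generated, g$n_distinct_strings, g$n_existing, g$n_novel_strings
  ))
  invisible(x)
}

#' Candidate-generation count summary
#'
#' One-row tibble with the multiset size of the raw substitution output
#' (`n_generated`), its distinct-string size, the number of rows whose
#' string already exists in the ontology (`n_existing`, with multiplicity),
#' and the novel set (`n_novel` rows, `n_novel_strings` distinct,
#' `n_eligible_strings` distinct after the redundancy rule).
#'
#' @param x A [generate_candidates()] result.
#' @param ... Unused.
#' @export
glance.synsub_generation <- function(x, ...) {
  cand <- x$candidates
  tibble::tibble(
    n_generated = nrow(cand),
    n_distinct_strings = dplyr::n_distinct(cand$norm),
    n_existing = sum(cand$existing),
    n_novel = sum(cand$novel),
    n_novel_strings = dplyr::n_distinct(cand$norm[cand$novel]),
    n_eligible_strings = dplyr::n_distinct(cand$norm[cand$eligible]),
    max_depth = x$max_depth
  )
}

#' @export
tidy.synsub_generation <- function(x, ...) {
  x$candidates
}

#' Distinct novel candidates ready for validation or enrichment
#'
#' One row per (term, normalized string): the set-difference side of the
#' generation result, with the redundancy rule applied; provenance columns
#' keep the first generating substitution.
#'
#' @param generation A [generate_candidates()] result.
#' @export
novel_candidates <- function(generation) {
  stopifnot(inherits(generation, "synsub_generation"))
  dplyr::distinct(
    dplyr::filter(generation$candidates, .data$eligible),
    .data$term_id, .data$norm, .keep_all = TRUE
  )
}
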