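#' Construct an ontology from tidy tables
#'
#' The in-memory ontology model is a light container of three tibbles:
#' `terms` (one row per term: `id`, `name`, `obsolete`), `synonyms` (one row
#' per synonym string: `id`, `text`, `scope`, `is_name`, `norm`) and `edges`
#' (one is-a row per `id`/`parent` pair). Following the convention that
#' counting and matching treat the preferred name as a synonym, every term
#' name is folded into the synonym table with scope `EXACT` and
#' `is_name = TRUE`.
#'
#' @param terms Data frame with columns `id`, `name` and optionally
#'   `obsolete` (logical, default `FALSE`).
#' @param edges Data frame with columns `id`, `parent` giving is-a links
#'   (child to parent), or `NULL`.
#' @param synonyms Data frame with columns `id`, `text` and optionally
#'   `scope` (default `"UNSPECIFIED"`), or `NULL`.
#' @return An object of class `synsub_ontology`.
#' @details Validation errors: duplicate term ids; edges referencing unknown
#'   ids (all dangling references are listed); a cycle in the is-a graph
#'   restricted to non-obsolete terms (one cycle is named).
#' @examples
#' onto <- ontology(
#'   terms = tibble::tibble(id = c("X:1", "X:2"),
#'                          name = c("hearing impairment",
#'                                   "sensorineural hearing impairment")),
#'   edges = tibble::tibble(id = "X:2", parent = "X:1"),
#'   synonyms = tibble::tibble(id = "X:1", text = "hearing loss",
#'                             scope = "EXACT")
#' )
#' onto
#' @export
ontology <- function(terms, edges = NULL, synonyms = NULL) {
  stopifnot(is.data.frame(terms), all(c("id", "name") %in% names(terms)))
  terms <- tibble::as_tibble(terms)
  if (!"obsolete" %in% names(terms)) terms$obsolete <- FALSE
  terms <- dplyr::select(terms, "id", "name", "obsolete")
  if (anyNA(terms$id) || any(!nzchar(terms$id))) abort("term ids must be non-empty")
  dup <- unique(terms$id[duplicated(terms$id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate term id(s): %s", paste(dup, collapse = ", ")))
  }
  if (anyNA(terms$name) || any(!nzchar(trimws(terms$name)))) {
    abort("every term needs a non-empty name")
  }

  if (is.null(edges)) edges <- tibble::tibble(id = character(), parent = character())
  stopifnot(is.data.frame(edges), all(c("id", "parent") %in% names(edges)))
  edges <- dplyr::distinct(dplyr::select(tibble::as_tibble(edges), "id", "parent"))
  dangling <- setdiff(c(edges$id, edges$parent), terms$id)
  if (length(dangling) > 0) {
    abort(sprintf("is_a reference(s) to unknown id(s): %s",
                  paste(sort(dangling), collapse = ", ")))
  }

  active_ids <- terms$id[!terms$obsolete]
  active_edges <- edges[edges$id %in% active_ids & edges$parent %in% active_ids, ]
  cyc <- find_one_cycle(active_edges)
  if (!is.null(cyc)) {
    abort(sprintf("is_a cycle among non-obsolete terms: %s",
                  paste(cyc, collapse = " -> ")))
  }

  if (is.null(synonyms)) synonyms <- tibble::tibble(id = character(), text = character())
  stopifnot(is.data.frame(synonyms), all(c("id", "text") %in% names(synonyms)))
  synonyms <- tibble::as_tibble(synonyms)
  if (!"scope" %in% names(synonyms)) synonyms$scope <- "UNSPECIFIED"
  synonyms$scope[is.na(synonyms$scope)] <- "UNSPECIFIED"
  assert_scope(synonyms$scope)
  unknown <- setdiff(synonyms$id, terms$id)
  if (length(unknown) > 0) {
    abort(sprintf("synonym(s) for unknown term id(s): %s",
                  paste(sort(unknown), collapse = ", ")))
  }
  syn <- dplyr::bind_rows(
    tibble::tibble(id = terms$id, text = terms$name, scope = "EXACT", is_name = TRUE),
    tibble::tibble(id = synonyms$id, text = synonyms$text,
                   scope = synonyms$scope, is_name = FALSE)
  )
  syn <- dplyr::arrange(syn, .data$id, dplyr::desc(.data$is_name), .data$text)
  syn$norm <- normalize_phrase(syn$text)

  structure(
    list(terms = terms, synonyms = syn, edges = edges),
    class = "synsub_ontology"
  )
}

# DFS cycle finder over child->parent edges; returns one cycle as an id
# vector (closed: first == last) or NULL
find_one_cycle <- function(edges) {
  if (nrow(edges) == 0) return(NULL)
  adj <- split(edges$parent, edges$id)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- mget(v, envir = state, ifnotfound = list("new"))[[1]]
    if (st == "done") return()
    if (st == "open") {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    assign(v, "open", envir = state)
    path <<- c(path, v)
    for (w in adj[[v]] %||% character(0)) visit(w)
    path <<- path[-length(path)]
    assign(v, "done", envir = state)
  }
  for (v in unique(edges$id)) {
    visit(v)
    if (!is.null(found)) return(found)
  }
  NULL
}

#' @export
print.synsub_ontology <- function(x, ...) {
  act <- active_terms(x)
  cat(sprintf(
    "<synsub_ontology> %d terms (%d obsolete), %d synonyms incl. names, %d is-a edges\n",
    nrow(x$terms), sum(x$terms$obsolete), nrow(active_synonyms(x)), nrow(x$edges)
  ))
  cat(sprintf("roots: %s\n", paste(ontology_roots(x), collapse = ", ")))
  invisible(x)
}

#' Ontology accessors
#'
#' Obsolete terms are excluded from every downstream computation; these
#' accessors return the live part of the ontology. `ontology_roots()` gives
#' the non-obsolete terms with no non-obsolete parent; `ontology_categories()`
#' gives the top-level category roots used for closure traversal — the
#' children of the root when the ontology has a single root (the usual
#' layout of a phenotype ontology, whose root is a formal "All"-style term),
#' otherwise the roots themselves.
#'
#' @param ontology A [ontology()] object.
#' @return Tibbles (`active_terms()`, `active_synonyms()`, `active_edges()`)
#'   or character vectors of term ids (`ontology_roots()`,
#'   `ontology_categories()`).
#' @export
active_terms <- function(ontology) {
  stopifnot(inherits(ontology, "synsub_ontology"))
  dplyr::filter(ontology$terms, !.data$obsolete)
}

#' @rdname active_terms
#' @export
active_synonyms <- function(ontology) {
  stopifnot(inherits(ontology, "synsub_ontology"))
  dplyr::filter(ontology$synonyms, .data$id %in% active_terms(ontology)$id)
}

#' @rdname active_terms
#' @export
active_edges <- function(ontology) {
  ids <- active_terms(ontology)$id
  dplyr::filter(ontology$edges, .data$id %in% ids, .data$parent %in% ids)
}

#' @rdname active_terms
#' @export
ontology_roots <- function(ontology) {
  ids <- active_terms(ontology)$id
  sort(setdiff(ids, active_edges(ontology)$id))
}

#' @rdname active_terms
#' @export
ontology_categories <- function(ontology) {
  roots <- ontology_roots(ontology)
  if (length(roots) == 1) {
    ed <- active_edges(ontology)
    kids <- sort(unique(ed$id[ed$parent == roots]))
    if (length(kids) > 0) return(kids)
  }
  roots
}

#' Summary counts for an ontology
#'
#' One-row tibble with the headline metrics of the lexical-overlap analysis:
#' total and non-obsolete term counts, synonym count including term names,
#' and synonyms per term.
#'
#' @param x A [ontology()] object.
#' @param ... Unused.
#' @export
glance.synsub_ontology <- function(x, ...) {
  act <- active_terms(x)
  syn <- active_synonyms(x)
  tibble::tibble(
    n_terms_total = nrow(x$terms),
    n_obsolete = sum(x$terms$obsolete),
    n_terms = nrow(act),
    n_synonyms = nrow(syn),
    synonyms_per_term = nrow(syn) / max(nrow(act), 1L),
    n_edges = nrow(active_edges(x)),
    n_categories = length(ontology_categories(x))
  )
}

#' @export
tidy.synsub_ontology <- function(x, ...) {
  dplyr::left_join(x$synonyms,
                   dplyr::select(x$terms, "id", "obsolete"), by = "id")
}

# add accepted candidate synonyms (term_id, text, scope) to an ontology;
# shared by write_obo and the pipeline
add_synonyms <- function(ontology, accepted) {
  stopifnot(inherits(ontology, "synsub_ontology"))
  if (is.null(accepted) || nrow(accepted) == 0) return(ontology)
  stopifnot(all(c("term_id", "text", "scope") %in% names(accepted)))
  unknown <- setdiff(accepted$term_id, ontology$terms$id)
  if (length(unknown) > 0) {
    abort(sprintf("candidate(s) for unknown term id(s): %s",
                  paste(sort(unique(unknown)), collapse = ", ")))
  }
  assert_scope(accepted$scope)
  new <- tibble::tibble(
    id = accepted$term_id, text = accepted$text, scope = accepted$scope,
    is_name = FALSE, norm = normalize_phrase(accepted$text)
  )
  key_old <- paste(ontology$synonyms$id, ontology$synonyms$norm)
  key_new <- paste(new$id, new$norm)
  clash <- key_new %in% key_old | duplicated(key_new)
  if (any(clash)) {
    abort(sprintf(
      "candidate(s) duplicating an existing synonym (case-insensitive): %s",
      paste(utils::head(sprintf("%s \"%s\"", new$id[clash], new$text[clash]), 5),
            collapse = "; ")
    ))
  }
  ontology$synonyms <- dplyr::arrange(
    dplyr::bind_rows(ontology$synonyms, new),
    .data$id, dplyr::desc(.data$is_name), .data$text
  )
  ontology
}
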