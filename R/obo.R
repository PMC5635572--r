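#' Read an OBO 1.2 flat file
#'
#' Loads every `[Term]` stanza into the ontology model. The tags `id`,
#' `name`, `synonym`, `is_a` and `is_obsolete` are interpreted; all other
#' tags (`def`, `xref`, `comment`, ...) are ignored, as are non-`[Term]`
#' stanzas such as `[Typedef]`. Synonym scope is read from the scope keyword
#' on the synonym line and set to `UNSPECIFIED` when absent. Term names are
#' folded into the synonym table with scope `EXACT` (see [ontology()]).
#'
#' @param path Path to an OBO flat file (UTF-8).
#' @return A [ontology()] object.
#' @details Errors: a line inside a `[Term]` stanza that is not a `tag: value`
#'   pair (reported with its line number); a stanza without `id` or `name`;
#'   duplicate ids; `is_a` references to ids not present in the file (all
#'   dangling references listed); an is-a cycle among non-obsolete terms.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  cur_line <- 0L
  terms <- list()
  edges <- list()
  synonyms <- list()

  flush_term <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) {
      abort(sprintf("[Term] stanza starting at line %d has no id", cur_line))
    }
    if (is.null(cur$name)) {
      abort(sprintf("[Term] stanza for %s (line %d) has no name", cur$id, cur_line))
    }
    terms[[length(terms) + 1L]] <<- tibble::tibble(
      id = cur$id, name = cur$name, obsolete = isTRUE(cur$obsolete)
    )
    if (length(cur$parents) > 0) {
      edges[[length(edges) + 1L]] <<- tibble::tibble(id = cur$id, parent = cur$parents)
    }
    if (length(cur$syn_text) > 0) {
      synonyms[[length(synonyms) + 1L]] <<- tibble::tibble(
        id = cur$id, text = cur$syn_text, scope = cur$syn_scope
      )
    }
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[[i]])
    if (!nzchar(line) || grepl("^!", line)) next
    if (grepl("^\\[", line)) {
      flush_term()
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(parents = character(0),
                    syn_text = character(0), syn_scope = character(0))
        cur_line <- i
      }
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) == 0) {
      abort(sprintf("malformed stanza line %d: %s", i, line))
    }
    tag <- m[2]
    value <- m[3]
    if (tag == "id") {
      cur$id <- trimws(value)
    } else if (tag == "name") {
      cur$name <- trimws(value)
    } else if (tag == "is_a") {
      cur$parents <- c(cur$parents, trimws(sub("!.*$", "", value)))
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(trimws(value), "true")
    } else if (tag == "synonym") {
      sm <- regmatches(value,
        regexec("^\"((?:\\\\.|[^\"\\\\])*)\"\\s*([A-Z_]+)?", value))[[1]]
      if (length(sm) == 0) {
        abort(sprintf("malformed synonym line %d: %s", i, line))
      }
      text <- gsub("\\\\(.)", "\\1", sm[2])
      scope <- sm[3]
      if (!nzchar(scope) || !scope %in% SCOPE_LEVELS) scope <- "UNSPECIFIED"
      cur$syn_text <- c(cur$syn_text, text)
      cur$syn_scope <- c(cur$syn_scope, scope)
    }
  }
  flush_term()

  ontology(
    terms = if (length(terms) > 0) dplyr::bind_rows(terms) else
      tibble::tibble(id = character(), name = character(), obsolete = logical()),
    edges = if (length(edges) > 0) dplyr::bind_rows(edges) else NULL,
    synonyms = if (length(synonyms) > 0) dplyr::bind_rows(synonyms) else NULL
  )
}

obo_escape <- function(x) gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x))

#' Write an ontology (optionally enriched) as an OBO 1.2 flat file
#'
#' Serializes the model with one `[Term]` stanza per term, sorted by id.
#' Accepted candidate synonyms, if supplied, are appended to their term's
#' synonym list with their inferred scope; `UNSPECIFIED` scope is emitted as
#' a scope-less synonym line, which round-trips back to `UNSPECIFIED` on
#' re-parsing. A candidate that duplicates an existing synonym of its term
#' (case-insensitive on the normalized form) is an error.
#'
#' @param ontology A [ontology()] object.
#' @param path Output file path.
#' @param accepted Optional data frame of accepted candidates with columns
#'   `term_id`, `text`, `scope`.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path, accepted = NULL) {
  enriched <- add_synonyms(ontology, accepted)
  con <- file(path, open = "wb")
  on.exit(close(con))
  terms <- dplyr::arrange(enriched$terms, .data$id)
  syn <- dplyr::arrange(
    dplyr::filter(enriched$synonyms, !.data$is_name),
    .data$text, .data$scope
  )
  syn_lines <- sprintf("synonym: \"%s\"%s []", obo_escape(syn$text),
                       ifelse(syn$scope == "UNSPECIFIED", "", paste0(" ", syn$scope)))
  syn_by_id <- split(syn_lines, factor(syn$id, levels = terms$id))
  edges <- dplyr::arrange(enriched$edges, .data$parent)
  par_by_id <- split(paste0("is_a: ", edges$parent),
                     factor(edges$id, levels = terms$id))
  stanzas <- lapply(seq_len(nrow(terms)), function(k) {
    id <- terms$id[k]
    c("[Term]", paste0("id: ", id), paste0("name: ", terms$name[k]),
      syn_by_id[[id]], par_by_id[[id]],
      if (terms$obsolete[k]) "is_obsolete: true", "")
  })
  out <- c("format-version: 1.2", "", unlist(stanzas))
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}

#' Write a candidate-synonym report as TSV
#'
#' One row per candidate, sorted by (`term_id`, `candidate_text`), with the
#' full provenance chain: the receiving term, the generated string and its
#' inferred scope, the ancestor term whose synonym was substituted in, the
#' substituted synonym, the overlapped string, and whether the candidate
#' passed exact-phrase corpus validation (`NA` when no corpus was used).
#'
#' @param candidates Data frame with columns `term_id`, `term_name`, `text`,
#'   `scope`, `ancestor_id`, `substituted_synonym`, `overlap_string` and
#'   optionally `corpus_validated`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  need <- c("term_id", "term_name", "text", "scope",
            "ancestor_id", "substituted_synonym", "overlap_string")
  missing <- setdiff(need, names(candidates))
  if (length(missing) > 0) {
    abort(sprintf("candidates lack column(s): %s", paste(missing, collapse = ", ")))
  }
  candidates <- tibble::as_tibble(candidates)
  if (!"corpus_validated" %in% names(candidates)) candidates$corpus_validated <- NA
  out <- dplyr::arrange(
    dplyr::transmute(candidates,
      term_id = .data$term_id, term_name = .data$term_name,
      candidate_text = .data$text, scope = .data$scope,
      ancestor_term_id = .data$ancestor_id,
      substituted_synonym = .data$substituted_synonym,
      overlap_string = .data$overlap_string,
      corpus_validated = .data$corpus_validated
    ),
    .data$term_id, .data$candidate_text
  )
  readr::write_tsv(out, path)
  invisible(path)
}
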