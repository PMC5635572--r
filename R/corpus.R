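#' Read a local document corpus
#'
#' `read_corpus()` reads the package's plain TSV corpus format (columns
#' `doc_id`, `title`, `abstract`); `read_medline_xml()` reads MEDLINE /
#' PubMed XML, taking `PMID` as the document id and concatenating the
#' `ArticleTitle` and `AbstractText` nodes of each article.
#'
#' @param path File path.
#' @return A tibble with columns `doc_id`, `title`, `abstract`.
#' @export
read_corpus <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    doc_id = readr::col_character(),
    title = readr::col_character(),
    abstract = readr::col_character()
  ))
  missing <- setdiff(c("doc_id", "title", "abstract"), names(out))
  if (length(missing) > 0) {
    abort(sprintf("corpus lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  dup <- unique(out$doc_id[duplicated(out$doc_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate doc_id(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  out
}

#' @rdname read_corpus
#' @export
read_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle | .//MedlineCitation[not(ancestor::PubmedArticle)]")
  get1 <- function(node, xp) {
    n <- xml2::xml_find_all(node, xp)
    if (length(n) == 0) "" else paste(xml2::xml_text(n), collapse = " ")
  }
  tibble::tibble(
    doc_id = purrr::map_chr(arts, get1, ".//MedlineCitation/PMID | ./PMID"),
    title = purrr::map_chr(arts, get1, ".//ArticleTitle"),
    abstract = purrr::map_chr(arts, get1, ".//AbstractText")
  )
}

# Document-side normalization: lowercase, hyphen split, punctuation stripped
# from token edges. Bracketed content is NOT removed — brackets in running
# prose carry text, unlike the clarifications in ontology labels.
normalize_doc <- function(x) {
  y <- tolower(x)
  y[is.na(y)] <- ""
  y <- gsub("(?<=[[:alnum:]])-(?=[[:alnum:]])", " ", y, perl = TRUE)
  y <- stringr::str_replace_all(y, "(?<=\\s|^)[[:punct:]]+|[[:punct:]]+(?=\\s|$)", "")
  y <- gsub("[[:space:]]+", " ", y)
  trimws(y)
}

#' Exact-phrase occurrence in a document
#'
#' `TRUE` for each document whose title or abstract contains the phrase's
#' token sequence contiguously. Matching is token-based on normalized text,
#' so an occurrence inside a longer noun phrase counts — \emph{anterior
#' spinal fusion} is found inside \emph{anterior spinal fusion surgery} —
#' mirroring the exact-phrase behavior of a bibliographic search engine.
#'
#' @param corpus A data frame with columns `doc_id`, `title`, `abstract`
#'   (a single document row works too).
#' @param phrase A single phrase (normalized internally).
#' @return Logical vector, one element per document.
#' @export
phrase_occurs <- function(corpus, phrase) {
  stopifnot(is.data.frame(corpus), length(phrase) == 1)
  p <- normalize_phrase(phrase)
  pat <- stringr::fixed(pad_phrase(p))
  stringr::str_detect(pad_phrase(normalize_doc(corpus$title)), pat) |
    stringr::str_detect(pad_phrase(normalize_doc(corpus$abstract)), pat)
}

#' Rule out candidates lacking exact-phrase corpus evidence
#'
#' Every candidate is searched, as an exact phrase, in the title and
#' abstract of every corpus document; candidates found in no document are
#' ruled out as likely nonsensical. `hit_count` counts matching documents
#' (not occurrences), and `retained` is `hit_count >= 1`. Candidate order is
#' preserved and no candidate is ever added.
#'
#' @param candidates A data frame of candidates with a `norm` or `text`
#'   column, or a [generate_candidates()] result (its eligible novel
#'   candidates are filtered).
#' @param corpus A corpus data frame (`doc_id`, `title`, `abstract`); must
#'   be non-empty — filtering against an empty corpus would silently discard
#'   everything.
#' @return The candidate tibble with `hit_count` and `retained` columns
#'   appended.
#' @export
filter_candidates <- function(candidates, corpus) {
  if (inherits(candidates, "synsub_generation")) {
    candidates <- novel_candidates(candidates)
  }
  stopifnot(is.data.frame(candidates))
  if (!is.data.frame(corpus) || nrow(corpus) == 0) {
    abort("corpus is empty: refusing to filter against nothing")
  }
  candidates <- tibble::as_tibble(candidates)
  if (!"norm" %in% names(candidates)) {
    if (!"text" %in% names(candidates)) {
      abort("candidates need a `norm` or `text` column")
    }
    candidates$norm <- normalize_phrase(candidates$text)
  }
  titles <- pad_phrase(normalize_doc(corpus$title))
  abstracts <- pad_phrase(normalize_doc(corpus$abstract))
  phrases <- unique(candidates$norm)
  hits <- purrr::map_int(phrases, function(p) {
    pat <- stringr::fixed(pad_phrase(p))
    sum(stringr::str_detect(titles, pat) | stringr::str_detect(abstracts, pat))
  })
  candidates$hit_count <- hits[match(candidates$norm, phrases)]
  candidates$retained <- candidates$hit_count >= 1L
  candidates$corpus_validated <- candidates$retained
  candidates
}
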