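#' Synonym scope vocabulary
#'
#' The five synonym scopes recognised throughout the package, from the most
#' to the least restrictive synonymy claim: `EXACT`, then `NARROW` and
#' `BROAD` (mutually incomparable), then `RELATED`, then `UNSPECIFIED`
#' (a synonym whose relatedness the source ontology does not state).
#'
#' @format Character vector of length five.
#' @export
SCOPE_LEVELS <- c("EXACT", "NARROW", "BROAD", "RELATED", "UNSPECIFIED")

# rank under the restrictiveness ordering; NARROW and BROAD share a rank and
# meet at RELATED (see scope_meet)
scope_rank <- c(EXACT = 4L, NARROW = 3L, BROAD = 3L, RELATED = 2L, UNSPECIFIED = 1L)

assert_scope <- function(scope, arg = "scope") {
  bad <- setdiff(unique(scope), SCOPE_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf("invalid %s value(s): %s", arg, paste(bad, collapse = ", ")))
  }
  invisible(scope)
}

# Remove matched bracket spans entirely; innermost-first so nesting works.
# Unmatched brackets are left as literal characters.
strip_brackets <- function(x) {
  pats <- c("\\([^()]*\\)", "\\[[^][]*\\]", "\\{[^{}]*\\}")
  repeat {
    y <- x
    for (p in pats) y <- gsub(p, " ", y)
    if (identical(y, x)) break
    x <- y
  }
  x
}

#' Normalize a phrase for lexical comparison
#'
#' Applies the preprocessing conventions used by every matching stage:
#' bracketed spans (`()`, `[]`, `{}`) are removed entirely (they are
#' clarifications or acronyms, not mining targets), the string is lowercased,
#' hyphens between word characters are split into spaces (so
#' `"criss-cross"` becomes `"criss cross"`), and whitespace is collapsed.
#' Other punctuation stays attached to its token. Normalization is
#' idempotent.
#'
#' @param x Character vector of surface strings.
#' @param allow_empty If `FALSE` (default), a string that is empty or reduced
#'   to empty by normalization raises an error; if `TRUE` it yields `""`.
#' @return Character vector of normalized strings.
#' @examples
#' normalize_phrase("criss-cross atrioventricular valves")
#' normalize_phrase("Thyroid stimulating hormone receptor (tshr) defect")
#' @export
normalize_phrase <- function(x, allow_empty = FALSE) {
  if (!is.character(x)) abort("`x` must be a character vector")
  y <- strip_brackets(x)
  y <- tolower(y)
  y <- gsub("(?<=[[:alnum:]])-(?=[[:alnum:]])", " ", y, perl = TRUE)
  y <- gsub("[[:space:]]+", " ", y)
  y <- trimws(y)
  if (!allow_empty && any(!nzchar(y) | is.na(y))) {
    bad <- x[!nzchar(y) | is.na(y)]
    abort(sprintf(
      "degenerate phrase(s): %s",
      paste(sprintf("\"%s\"", utils::head(bad, 5)), collapse = ", ")
    ))
  }
  y
}

#' Tokenize a phrase
#'
#' Tokens are the whitespace-delimited chunks of the normalized phrase.
#'
#' @inheritParams normalize_phrase
#' @return `phrase_tokens()`: a list of character vectors, one per input
#'   string. `token_count()`: an integer vector of token counts.
#' @examples
#' phrase_tokens("criss-cross valves")
#' token_count("thyroid stimulating hormone receptor (tshr) defect") # 5
#' @export
phrase_tokens <- function(x) {
  strsplit(normalize_phrase(x), " ", fixed = TRUE)
}

#' @rdname phrase_tokens
#' @export
token_count <- function(x) {
  lengths(phrase_tokens(x))
}

# pad with sentinel spaces so fixed-string search respects token boundaries
pad_phrase <- function(x) paste0(" ", x, " ")

#' Token-sequence containment between phrases
#'
#' `TRUE` where the tokens of `contained` occur as a contiguous subsequence
#' of the tokens of `container`. Containment is at the token level, never
#' inside a token (`"art"` is not contained in `"heart disease"`). With
#' `proper = TRUE` the container must additionally be strictly longer in
#' tokens, which is the notion of lexical overlap used throughout.
#'
#' @param container,contained Character vectors (normalized internally;
#'   normalization is idempotent so pre-normalized input is fine). Recycled
#'   to a common length.
#' @param proper Require strict containment (container longer than contained)?
#' @return Logical vector.
#' @examples
#' phrase_contains("sensorineural hearing loss", "hearing loss", proper = TRUE)
#' phrase_contains("hearing loss", "hearing loss", proper = TRUE) # FALSE
#' phrase_contains("heart disease", "art", proper = TRUE)         # FALSE
#' @export
phrase_contains <- function(container, contained, proper = FALSE) {
  big <- normalize_phrase(container, allow_empty = TRUE)
  small <- normalize_phrase(contained, allow_empty = TRUE)
  hit <- stringr::str_detect(pad_phrase(big), stringr::fixed(pad_phrase(small)))
  if (proper) {
    hit <- hit & lengths(strsplit(big, " ", fixed = TRUE)) >
      lengths(strsplit(small, " ", fixed = TRUE))
  }
  hit & nzchar(small)
}

# all 0-based start positions of the token vector `small` inside `big`
token_starts <- function(big, small) {
  n <- length(big)
  m <- length(small)
  if (m == 0L || m > n) return(integer(0))
  out <- integer(0)
  for (i in 0:(n - m)) {
    if (all(big[(i + 1L):(i + m)] == small)) out <- c(out, i)
  }
  out
}

#' Flag and remove redundant synonyms of a term
#'
#' A synonym is redundant for concept recognition when its normalized form
#' properly contains another synonym of the same term: any recognizer that
#' matches the longer synonym would also have matched the shorter one
#' (e.g. `"congenital hearing loss"` alongside `"hearing loss"`). Such
#' synonyms degrade overlap detection and are removed before any downstream
#' stage. The preferred name of a term is never removed.
#'
#' `flag_redundant_synonyms()` takes a synonym table and adds a logical
#' `redundant` column; `remove_redundant_synonyms()` takes an ontology and
#' returns the pruned ontology together with the removed synonyms.
#'
#' @param synonyms A data frame with columns `id`, `text` and (optionally)
#'   `is_name`; one row per synonym, term names included.
#' @return `flag_redundant_synonyms()`: the input tibble with a `redundant`
#'   column. `remove_redundant_synonyms()`: a list with elements `ontology`
#'   (pruned) and `removed` (tibble of removed synonym rows).
#' @examples
#' syn <- tibble::tibble(
#'   id = "HP:0000365",
#'   text = c("Hearing impairment", "hearing loss", "congenital hearing loss"),
#'   is_name = c(TRUE, FALSE, FALSE)
#' )
#' flag_redundant_synonyms(syn)
#' @export
flag_redundant_synonyms <- function(synonyms) {
  stopifnot(is.data.frame(synonyms), all(c("id", "text") %in% names(synonyms)))
  synonyms <- tibble::as_tibble(synonyms)
  if (!"is_name" %in% names(synonyms)) synonyms$is_name <- FALSE
  if (!"norm" %in% names(synonyms)) synonyms$norm <- normalize_phrase(synonyms$text)
  synonyms$..row <- seq_len(nrow(synonyms))
  pairs <- dplyr::inner_join(
    dplyr::select(synonyms, "id", "..row", big = "norm", big_name = "is_name"),
    dplyr::select(synonyms, "id", small = "norm"),
    by = "id", relationship = "many-to-many"
  )
  pairs <- dplyr::filter(
    pairs, !.data$big_name,
    phrase_contains(.data$big, .data$small, proper = TRUE)
  )
  synonyms$redundant <- synonyms$..row %in% pairs$..row
  dplyr::select(synonyms, -"..row")
}

#' @rdname flag_redundant_synonyms
#' @param ontology A [ontology()] object.
#' @export
remove_redundant_synonyms <- function(ontology) {
  stopifnot(inherits(ontology, "synsub_ontology"))
  syn <- flag_redundant_synonyms(ontology$synonyms)
  pruned <- ontology
  pruned$synonyms <- dplyr::select(
    dplyr::filter(syn, !.data$redundant), -"redundant"
  )
  list(
    ontology = pruned,
    removed = dplyr::select(dplyr::filter(syn, .data$redundant), -"redundant")
  )
}
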