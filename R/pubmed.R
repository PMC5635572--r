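#' Exact-phrase hit counts from live PubMed (network required)
#'
#' Optional adapter querying NCBI E-utilities `esearch` with each phrase
#' quoted and restricted to the title/abstract fields (`[TIAB]`). Because
#' MEDLINE counts drift over time, every result is cached to `cache_dir`
#' together with the query date, and cached counts are reused on rerun.
#' This adapter is never exercised by the package tests; the local corpus
#' scanner ([filter_candidates()]) is the reproducible code path.
#'
#' @param phrases Character vector of phrases.
#' @param email Contact e-mail sent with each request (E-utilities
#'   etiquette).
#' @param cache_dir Directory for cached counts; `NULL` disables caching.
#' @param delay Seconds to sleep between requests.
#' @return A tibble with columns `phrase`, `hit_count`, `retained`,
#'   `query_date`.
#' @export
pubmed_phrase_counts <- function(phrases, email = NULL, cache_dir = NULL,
                                 delay = 0.4) {
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi"
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  one <- function(phrase) {
    key <- NULL
    if (!is.null(cache_dir)) {
      key <- file.path(cache_dir, paste0(
        gsub("[^a-z0-9]+", "_", normalize_phrase(phrase)), ".tsv"))
      if (file.exists(key)) {
        hit <- readr::read_tsv(key, col_types = "cic", progress = FALSE)
        return(hit)
      }
    }
    q <- utils::URLencode(sprintf("\"%s\"[TIAB]", phrase), reserved = TRUE)
    url <- sprintf("%s?db=pubmed&term=%s&rettype=count%s", base, q,
                   if (is.null(email)) "" else paste0("&email=", email))
    xml <- xml2::read_xml(url)
    n <- as.integer(xml2::xml_text(xml2::xml_find_first(xml, "//Count")))
    Sys.sleep(delay)
    out <- tibble::tibble(phrase = phrase, hit_count = n,
                          query_date = as.character(Sys.Date()))
    if (!is.null(key)) readr::write_tsv(out, key)
    out
  }
  res <- purrr::map_dfr(phrases, one)
  res$retained <- res$hit_count >= 1L
  res[, c("phrase", "hit_count", "retained", "query_date")]
}
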