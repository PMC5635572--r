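#' Run the full synonym-enrichment pipeline
#'
#' Executes the method end to end on an ontology: prune redundant synonyms,
#' compute the is-a transitive closure, detect lexical overlaps, generate
#' candidate synonyms by substitution with inferred scopes, optionally rule
#' out candidates lacking exact-phrase evidence in a corpus, and assemble
#' the enriched ontology. Every stage count is collected into a stats
#' summary so that a divergence on reference data can be localized to the
#' stage that produced it.
#'
#' @param ontology A [ontology()] object or a path to an OBO file.
#' @param corpus Optional corpus (tibble `doc_id`, `title`, `abstract` or a
#'   path readable by [read_corpus()]); when `NULL` no corpus filtering is
#'   applied and all eligible novel candidates are accepted
#'   (`corpus_validated = NA`).
#' @param max_depth Substitution depth passed to [generate_candidates()].
#' @return An object of class `synsub_enrichment`: a list with `ontology`
#'   (pruned input), `removed` (pruned redundant synonyms), `overlaps`,
#'   `generation`, `candidates` (novel candidates with filter outcome),
#'   `accepted`, `enriched` (pruned ontology plus accepted synonyms),
#'   `stats` (one-row tibble; also via [glance()]) and `config`.
#' @examples
#' fx <- synth_ontology(seed = 7)
#' res <- enrich_ontology(fx$ontology)
#' glance(res)
#' @export
enrich_ontology <- function(ontology, corpus = NULL, max_depth = 1L) {
  if (is.character(ontology)) ontology <- read_obo(ontology)
  stopifnot(inherits(ontology, "synsub_ontology"))
  if (is.character(corpus)) corpus <- read_corpus(corpus)

  n_total <- nrow(ontology$terms)
  n_obsolete <- sum(ontology$terms$obsolete)
  n_syn_before <- nrow(active_synonyms(ontology))

  pruned <- remove_redundant_synonyms(ontology)
  onto <- pruned$ontology
  removed <- dplyr::filter(pruned$removed,
                           .data$id %in% active_terms(ontology)$id)

  closure <- term_closure(onto)
  overlaps <- find_overlaps(onto, closure)
  generation <- generate_candidates(onto, overlaps, max_depth = max_depth)
  candidates <- novel_candidates(generation)

  if (!is.null(corpus)) {
    candidates <- filter_candidates(candidates, corpus)
    accepted <- dplyr::filter(candidates, .data$retained)
  } else {
    candidates$hit_count <- NA_integer_
    candidates$retained <- NA
    candidates$corpus_validated <- NA
    accepted <- candidates
  }
  enriched <- add_synonyms(onto, accepted)

  ov_glance <- glance(overlaps)
  gen_glance <- glance(generation)
  n_act <- nrow(active_terms(onto))
  scope_split <- function(scopes) {
    if (length(scopes) == 0) return(setNames(rep(NA_real_, 3),
      c("pct_exact", "pct_related", "pct_unspecified")))
    c(pct_exact = 100 * mean(scopes == "EXACT"),
      pct_related = 100 * mean(scopes == "RELATED"),
      pct_unspecified = 100 * mean(scopes == "UNSPECIFIED"))
  }
  sp <- scope_split(accepted$scope)
  stats <- tibble::tibble(
    n_terms_total = n_total,
    n_obsolete = n_obsolete,
    n_terms = n_act,
    n_synonyms_incl_names = n_syn_before,
    n_redundant_removed = nrow(removed),
    n_synonyms_after = n_syn_before - nrow(removed),
    synonyms_per_term = n_syn_before / max(n_act, 1L),
    n_closure_pairs = nrow(closure),
    n_overlap_occurrences = ov_glance$n_occurrences,
    n_unique_overlaps = ov_glance$n_unique_string_pairs,
    n_unique_overlap_term_pairs = ov_glance$n_unique_term_pairs,
    n_generated = gen_glance$n_generated,
    n_existing = gen_glance$n_existing,
    n_novel = gen_glance$n_novel,
    n_novel_strings = gen_glance$n_novel_strings,
    n_candidates = nrow(candidates),
    n_retained = if (is.null(corpus)) NA_integer_ else nrow(accepted),
    n_terms_with_new_synonyms = dplyr::n_distinct(accepted$term_id),
    accepted_pct_exact = sp[["pct_exact"]],
    accepted_pct_related = sp[["pct_related"]],
    accepted_pct_unspecified = sp[["pct_unspecified"]]
  )

  structure(list(
    ontology = onto, removed = removed, closure = closure,
    overlaps = overlaps, generation = generation, candidates = candidates,
    accepted = accepted, enriched = enriched, stats = stats,
    config = list(max_depth = as.integer(max_depth),
                  corpus_filtered = !is.null(corpus),
                  n_corpus_docs = if (is.null(corpus)) 0L else nrow(corpus))
  ), class = "synsub_enrichment")
}

#' @export
print.synsub_enrichment <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0(
    "<synsub_enrichment>\n",
    "  terms: %d non-obsolete (of %d)\n",
    "  synonyms incl. names: %d; redundant removed: %d\n",
    "  unique lexical overlaps: %d (%d occurrences)\n",
    "  generated: %d (existing %d, novel strings %d)\n",
    "  accepted candidates: %d%s\n"),
    s$n_terms, s$n_terms_total, s$n_synonyms_incl_names,
    s$n_redundant_removed, s$n_unique_overlaps, s$n_overlap_occurrences,
    s$n_generated, s$n_existing, s$n_novel_strings, nrow(x$accepted),
    if (x$config$corpus_filtered) " (corpus-validated)" else " (no corpus filter)"
  ))
  invisible(x)
}

#' @export
glance.synsub_enrichment <- function(x, ...) x$stats

#' @export
tidy.synsub_enrichment <- function(x, ...) x$candidates

#' Write the artifact bundle of an enrichment run
#'
#' Emits the candidate report TSV, the enriched OBO file, the overlap TSV,
#' the stats summary TSV and a JSON run manifest into one directory.
#'
#' @param result A [enrich_ontology()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_enrichment <- function(result, dir) {
  stopifnot(inherits(result, "synsub_enrichment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_candidates(result$candidates, file.path(dir, "candidates.tsv"))
  write_obo(result$enriched, file.path(dir, "enriched.obo"))
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(result$overlaps),
                  "ancestor_id", "descendant_id", ancestor_string = "ancestor_norm",
                  descendant_string = "descendant_norm", start_token = "start",
                  token_length = "n_tokens"),
    file.path(dir, "overlaps.tsv")
  )
  readr::write_tsv(result$stats, file.path(dir, "stats.tsv"))
  manifest <- c(result$config, as.list(result$stats))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
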