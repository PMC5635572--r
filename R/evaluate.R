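#' Micro-averaged precision, recall and F-measure on concept annotations
#'
#' Scores a system's (document, term) annotation set against a gold
#' standard by exact pair equality: \eqn{P = TP/(TP+FP)},
#' \eqn{R = TP/(TP+FN)}, \eqn{F = 2PR/(P+R)} (0 when \eqn{P+R=0}; an empty
#' system output scores \eqn{P = 0} by convention). Both sets are
#' deduplicated on (`doc_id`, `term_id`) before scoring.
#'
#' @param system,gold Data frames with columns `doc_id`, `term_id`; `gold`
#'   must be non-empty.
#' @return A one-row tibble: `n_system`, `n_gold`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_measure`.
#' @examples
#' gold <- tibble::tibble(doc_id = c("d1", "d1", "d2", "d3"),
#'                        term_id = c("a", "b", "a", "c"))
#' system <- tibble::tibble(doc_id = c("d1", "d1", "d2"),
#'                          term_id = c("a", "b", "x"))
#' prf_scores(system, gold)  # P = 2/3, R = 1/2, F = 4/7
#' @export
prf_scores <- function(system, gold) {
  for (nm in list(system, gold)) {
    stopifnot(is.data.frame(nm), all(c("doc_id", "term_id") %in% names(nm)))
  }
  if (nrow(gold) == 0) abort("gold standard is empty")
  system <- dplyr::distinct(tibble::as_tibble(system), .data$doc_id, .data$term_id)
  gold <- dplyr::distinct(tibble::as_tibble(gold), .data$doc_id, .data$term_id)
  tp <- nrow(dplyr::semi_join(system, gold, by = c("doc_id", "term_id")))
  fp <- nrow(system) - tp
  fn <- nrow(gold) - tp
  p <- if (nrow(system) == 0) 0 else tp / (tp + fp)
  r <- tp / (tp + fn)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(n_system = nrow(system), n_gold = nrow(gold),
                 tp = tp, fp = fp, fn = fn,
                 precision = p, recall = r, f_measure = f)
}

#' Minimal dictionary-based concept annotator
#'
#' An exact normalized-phrase recognizer used to make end-to-end fixtures
#' runnable: every dictionary phrase is searched in the title and abstract
#' of every document, and when overlapping matches exist the more detailed
#' (longer) annotation wins — a match whose span lies strictly inside
#' another match's span is dropped. This deliberately omits the stemming
#' and word-order permutation of full-blown concept recognizers.
#'
#' @param corpus A corpus data frame (`doc_id`, `title`, `abstract`).
#' @param dictionary A data frame with columns `term_id`, `text` (e.g.
#'   [active_synonyms()] renamed, or an enriched synonym table).
#' @return A tibble of distinct (`doc_id`, `term_id`) annotations.
#' @export
annotate_corpus <- function(corpus, dictionary) {
  stopifnot(is.data.frame(corpus), is.data.frame(dictionary),
            all(c("term_id", "text") %in% names(dictionary)))
  dict <- dplyr::distinct(
    tibble::tibble(term_id = dictionary$term_id,
                   norm = normalize_phrase(dictionary$text))
  )
  fields <- list(pad_phrase(normalize_doc(corpus$title)),
                 pad_phrase(normalize_doc(corpus$abstract)))
  hits <- list()
  for (fi in seq_along(fields)) {
    fld <- fields[[fi]]
    for (k in seq_len(nrow(dict))) {
      pat <- stringr::fixed(pad_phrase(dict$norm[k]))
      loc <- stringr::str_locate_all(fld, pat)
      n_per_doc <- vapply(loc, nrow, integer(1))
      idx <- which(n_per_doc > 0)
      if (length(idx) == 0) next
      hits[[length(hits) + 1L]] <- tibble::tibble(
        doc_id = rep(corpus$doc_id[idx], n_per_doc[idx]),
        field = fi,
        term_id = dict$term_id[k],
        start = unlist(lapply(loc[idx], function(m) m[, 1])),
        end = unlist(lapply(loc[idx], function(m) m[, 2]))
      )
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(doc_id = character(), term_id = character()))
  }
  all_hits <- dplyr::bind_rows(hits)
  # longest-match-wins: drop spans strictly nested inside a longer match
  kept <- dplyr::group_modify(
    dplyr::group_by(all_hits, .data$doc_id, .data$field),
    function(df, key) {
      len <- df$end - df$start
      nested <- vapply(seq_len(nrow(df)), function(i) {
        any(df$start <= df$start[i] & df$end >= df$end[i] & len > len[i])
      }, logical(1))
      df[!nested, , drop = FALSE]
    }
  )
  dplyr::distinct(dplyr::ungroup(kept), .data$doc_id, .data$term_id)
}

increase_rate <- function(baseline, enriched, denominator = c("baseline", "enriched")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "baseline") baseline else enriched
  ifelse(enriched == baseline, 0,
         ifelse(den == 0, NA_real_, 100 * (enriched - baseline) / den))
}

#' Document-retrieval gain from enrichment, stratified by IC and volume
#'
#' Compares the documents retrieved per term by a baseline annotation run
#' and an enriched run (same term universe), reporting for each IC bin and
#' abstract-volume band the number of distinct annotated documents under
#' each run and the increase rate, percent change relative to the baseline
#' count by default (`(enriched - baseline) / baseline * 100`). Volume
#' bands — more than 1000, 100 to 1000, and fewer than 100 annotated
#' abstracts — are assigned from the enriched run's per-term counts.
#' Per-IC-bin and grand total rows aggregate distinct documents, so a
#' document annotated by terms of two bands appears in both band rows but
#' once in the total.
#'
#' @param baseline,enriched Data frames of per-term retrieved documents,
#'   columns `term_id`, `doc_id`.
#' @param ic An [information_content()] result covering the term universe.
#' @param terms Optional explicit term universe; when `NULL` the two runs
#'   must cover the same term set (a mismatch is an error).
#' @param denominator `"baseline"` (default) or `"enriched"`.
#' @return A tibble with columns `ic_bin`, `volume_band`, `n_terms`,
#'   `pct_terms`, `baseline_docs`, `enriched_docs`, `increase_rate`;
#'   `volume_band = "Total"` rows aggregate each IC bin and
#'   `ic_bin = "Total"` rows aggregate everything.
#' @export
retrieval_increase <- function(baseline, enriched, ic, terms = NULL,
                               denominator = c("baseline", "enriched")) {
  denominator <- match.arg(denominator)
  for (nm in list(baseline, enriched)) {
    stopifnot(is.data.frame(nm), all(c("term_id", "doc_id") %in% names(nm)))
  }
  baseline <- dplyr::distinct(tibble::as_tibble(baseline), .data$term_id, .data$doc_id)
  enriched <- dplyr::distinct(tibble::as_tibble(enriched), .data$term_id, .data$doc_id)
  if (is.null(terms)) {
    mismatch <- union(setdiff(baseline$term_id, enriched$term_id),
                      setdiff(enriched$term_id, baseline$term_id))
    if (length(mismatch) > 0) {
      abort(sprintf("term universes differ between runs: %s",
                    paste(head(sort(mismatch), 5), collapse = ", ")))
    }
    terms <- union(baseline$term_id, enriched$term_id)
  } else {
    bad <- setdiff(union(baseline$term_id, enriched$term_id), terms)
    if (length(bad) > 0) {
      abort(sprintf("run term(s) outside the supplied universe: %s",
                    paste(head(sort(bad), 5), collapse = ", ")))
    }
  }
  lost <- nrow(dplyr::anti_join(baseline, enriched, by = c("term_id", "doc_id")))
  if (lost > 0) {
    warn(sprintf("%d baseline (term, doc) pairs missing from the enriched run",
                 lost))
  }

  stopifnot(is.data.frame(ic), all(c("term_id", "bin") %in% names(ic)))
  info <- tibble::tibble(term_id = terms)
  info <- dplyr::left_join(info, dplyr::select(ic, "term_id", ic_bin = "bin"),
                           by = "term_id")
  info$ic_bin[is.na(info$ic_bin)] <- "undefined"
  n_enr <- dplyr::count(enriched, .data$term_id, name = "n_docs")
  info <- dplyr::left_join(info, n_enr, by = "term_id")
  info$n_docs <- dplyr::coalesce(info$n_docs, 0L)
  info$volume_band <- dplyr::case_when(
    info$n_docs > 1000 ~ ">1000",
    info$n_docs >= 100 ~ "[100,1000)",
    TRUE ~ "(0,100)"
  )

  cell <- function(term_set) {
    tibble::tibble(
      n_terms = length(term_set),
      baseline_docs = dplyr::n_distinct(baseline$doc_id[baseline$term_id %in% term_set]),
      enriched_docs = dplyr::n_distinct(enriched$doc_id[enriched$term_id %in% term_set])
    )
  }
  bands <- c(">1000", "[100,1000)", "(0,100)")
  bins <- intersect(IC_BINS, unique(info$ic_bin))
  rows <- list()
  for (b in c(bins, "Total")) {
    in_bin <- if (b == "Total") info else info[info$ic_bin == b, ]
    for (v in c(bands, "Total")) {
      grp <- if (v == "Total") in_bin else in_bin[in_bin$volume_band == v, ]
      r <- cell(grp$term_id)
      r$ic_bin <- b
      r$volume_band <- v
      r$pct_terms <- 100 * r$n_terms / max(nrow(in_bin), 1L)
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- dplyr::bind_rows(rows)
  out$increase_rate <- increase_rate(out$baseline_docs, out$enriched_docs,
                                     denominator)
  dplyr::select(out, "ic_bin", "volume_band", "n_terms", "pct_terms",
                "baseline_docs", "enriched_docs", "increase_rate")
}
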