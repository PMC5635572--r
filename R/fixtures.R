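#' Generate a seeded synthetic ontology with known ground truth
#'
#' Builds a phenotype-ontology-like DAG: a single formal root, `n_categories`
#' top-level categories beneath it, and under each category a tree of the
#' given `depth` and `branching`. Child names follow the genus–differentia
#' convention with probability `genus_differentia_rate` — a fresh modifier
#' token prefixed to the parent name — which is exactly what creates lexical
#' overlaps; otherwise the child gets a fresh, unrelated name. Each term
#' additionally receives a Poisson(`synonym_rate`) number of variant
#' synonyms built from fresh tokens (so variants never overlap anything),
#' a redundant synonym (a modifier prefixed to the term's own name) with
#' probability `redundant_rate`, and a few obsolete terms are appended.
#' Optional cross edges add extra non-compositional parents, exercising the
#' DAG closure without touching the overlap ground truth. Because every
#' token is drawn fresh from disjoint vocabularies, the planted structures
#' are the only containments that can occur, and the generator records them
#' exhaustively at construction.
#'
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @param n_categories Top-level categories under the root.
#' @param depth Tree depth below each category root.
#' @param branching Children per internal term.
#' @param genus_differentia_rate Probability a child name embeds its parent
#'   name.
#' @param synonym_rate Expected variant synonyms per term (term names are
#'   counted separately, as everywhere in the package).
#' @param redundant_rate Probability a term gets a planted redundant
#'   synonym.
#' @param obsolete_rate Fraction of extra obsolete terms appended.
#' @param cross_edge_rate Probability a term below the category level gets
#'   one extra (non-compositional) parent.
#' @return A list of class `synsub_synth`: `ontology` (a [ontology()]
#'   object) and `truth`, a list with `n_terms`, `n_obsolete`,
#'   `n_synonyms_incl_names`, `redundant` (planted redundant synonyms),
#'   `overlaps` (every lexical overlap present after pruning:
#'   `ancestor_id`, `descendant_id`, `ancestor_norm`, `descendant_norm`,
#'   `start`, `n_tokens`), and `candidates` (every candidate a depth-1
#'   substitution must produce: `term_id`, `norm`, `scope`,
#'   `ancestor_id`), all exhaustive by construction.
#' @export
synth_ontology <- function(seed, n_categories = 3, depth = 3, branching = 2,
                           genus_differentia_rate = 0.6, synonym_rate = 0.7,
                           redundant_rate = 0.03, obsolete_rate = 0.005,
                           cross_edge_rate = 0.1) {
  rates <- c(genus_differentia_rate, redundant_rate, obsolete_rate, cross_edge_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (n_categories < 1 || depth < 0 || branching < 0 || synonym_rate < 0) {
    abort("structure parameters must be positive")
  }
  withr::with_seed(as.integer(seed), synth_ontology_impl(
    n_categories, depth, branching, genus_differentia_rate, synonym_rate,
    redundant_rate, obsolete_rate, cross_edge_rate
  ))
}

synth_ontology_impl <- function(n_categories, depth, branching, gd_rate,
                                synonym_rate, redundant_rate, obsolete_rate,
                                cross_edge_rate) {
  counter <- new.env(parent = emptyenv())
  fresh <- function(prefix, n = 1) {
    i <- (counter[[prefix]] %||% 0L) + seq_len(n)
    counter[[prefix]] <- i[n]
    sprintf("%s%04d", prefix, i)
  }
  next_id <- local({
    k <- 0L
    function() {
      k <<- k + 1L
      sprintf("SYN:%07d", k)
    }
  })

  terms <- list()
  edges <- list()
  synonyms <- list()
  truth_overlaps <- list()
  truth_candidates <- list()
  truth_redundant <- list()
  # per-term bookkeeping: name tokens, embedded-ancestor chain, level
  info <- new.env(parent = emptyenv())

  add_term <- function(id, name, level, parent = NULL, compositional = FALSE) {
    terms[[length(terms) + 1L]] <<- tibble::tibble(id = id, name = name,
                                                   obsolete = FALSE)
    embedded <- character(0)
    if (!is.null(parent)) {
      edges[[length(edges) + 1L]] <<- tibble::tibble(id = id, parent = parent)
      if (compositional) {
        embedded <- c(parent, info[[parent]]$embedded)
      }
    }
    info[[id]] <- list(name = name, level = level, embedded = embedded,
                       variants = tibble::tibble(text = character(),
                                                 scope = character()))
    id
  }

  root <- add_term(next_id(), paste(fresh("rootname", 2), collapse = " "), 0L)
  scope_pool <- c("EXACT", "RELATED", "NARROW", "BROAD", "UNSPECIFIED")
  scope_prob <- c(0.5, 0.2, 0.1, 0.1, 0.1)

  levels <- list()
  levels[[1]] <- vapply(seq_len(n_categories), function(i) {
    add_term(next_id(), paste(fresh("cat", 2), collapse = " "), 1L, parent = root)
  }, character(1))

  if (depth > 0) {
    for (lv in seq_len(depth)) {
      parents <- levels[[lv]]
      kids <- character(0)
      for (p in parents) {
        for (b in seq_len(branching)) {
          comp <- runif(1) < gd_rate
          name <- if (comp) {
            paste(c(fresh("mod"), info[[p]]$name), collapse = " ")
          } else {
            paste(fresh("gen", sample(1:2, 1)), collapse = " ")
          }
          kids <- c(kids, add_term(next_id(), name, lv + 1L, parent = p,
                                   compositional = comp))
        }
      }
      levels[[lv + 1]] <- kids
    }
  }

  all_ids <- unlist(levels)
  # variant synonyms and planted redundant synonyms
  for (id in c(root, all_ids)) {
    nv <- rpois(1, synonym_rate)
    if (nv > 0) {
      vt <- vapply(seq_len(nv), function(i) {
        paste(fresh("var", sample(1:2, 1)), collapse = " ")
      }, character(1))
      vs <- sample(scope_pool, nv, replace = TRUE, prob = scope_prob)
      info[[id]]$variants <- tibble::tibble(text = vt, scope = vs)
      synonyms[[length(synonyms) + 1L]] <- tibble::tibble(id = id, text = vt,
                                                          scope = vs)
    }
    if (runif(1) < redundant_rate) {
      red <- paste(c(fresh("red"), info[[id]]$name), collapse = " ")
      synonyms[[length(synonyms) + 1L]] <- tibble::tibble(id = id, text = red,
                                                          scope = "EXACT")
      truth_redundant[[length(truth_redundant) + 1L]] <-
        tibble::tibble(id = id, text = red)
    }
  }

  # cross edges: extra parent from a strictly higher level, never an
  # ancestor or descendant (level ordering keeps the graph acyclic)
  if (cross_edge_rate > 0 && length(levels) > 2) {
    for (lv in 3:length(levels)) {
      for (id in levels[[lv]]) {
        if (runif(1) < cross_edge_rate) {
          ed <- dplyr::bind_rows(edges)
          anc <- id
          repeat {
            up <- setdiff(ed$parent[ed$id %in% anc], anc)
            if (length(up) == 0) break
            anc <- c(anc, up)
          }
          pool <- setdiff(unlist(levels[seq_len(lv - 1)]), anc)
          if (length(pool) > 0) {
            edges[[length(edges) + 1L]] <- tibble::tibble(
              id = id, parent = sample(pool, 1))
          }
        }
      }
    }
  }

  # exhaustive planted overlaps (post-pruning) and depth-1 candidates
  for (id in all_ids) {
    emb <- info[[id]]$embedded
    if (length(emb) == 0) next
    d_tok <- strsplit(info[[id]]$name, " ", fixed = TRUE)[[1]]
    for (a in emb) {
      a_tok <- strsplit(info[[a]]$name, " ", fixed = TRUE)[[1]]
      truth_overlaps[[length(truth_overlaps) + 1L]] <- tibble::tibble(
        ancestor_id = a, descendant_id = id,
        ancestor_norm = info[[a]]$name, descendant_norm = info[[id]]$name,
        start = length(d_tok) - length(a_tok), n_tokens = length(a_tok)
      )
      va <- info[[a]]$variants
      if (nrow(va) > 0) {
        prefix <- paste(d_tok[seq_len(length(d_tok) - length(a_tok))],
                        collapse = " ")
        truth_candidates[[length(truth_candidates) + 1L]] <- tibble::tibble(
          term_id = id,
          norm = paste(prefix, va$text),
          scope = va$scope, ancestor_id = a
        )
      }
    }
  }

  n_obs <- ceiling(obsolete_rate * (length(all_ids) + 1))
  if (n_obs > 0) {
    for (i in seq_len(n_obs)) {
      terms[[length(terms) + 1L]] <- tibble::tibble(
        id = next_id(), name = paste(fresh("obs", 2), collapse = " "),
        obsolete = TRUE
      )
    }
  }

  onto <- ontology(
    terms = dplyr::bind_rows(terms),
    edges = dplyr::bind_rows(edges),
    synonyms = if (length(synonyms) > 0) dplyr::bind_rows(synonyms) else NULL
  )
  empty_ov <- tibble::tibble(ancestor_id = character(),
                             descendant_id = character(),
                             ancestor_norm = character(),
                             descendant_norm = character(),
                             start = integer(), n_tokens = integer())
  empty_cd <- tibble::tibble(term_id = character(), norm = character(),
                             scope = character(), ancestor_id = character())
  truth <- list(
    n_terms = length(all_ids) + 1L,
    n_obsolete = n_obs,
    n_synonyms_incl_names = nrow(active_synonyms(onto)),
    redundant = if (length(truth_redundant) > 0) {
      dplyr::bind_rows(truth_redundant)
    } else tibble::tibble(id = character(), text = character()),
    overlaps = if (length(truth_overlaps) > 0) {
      dplyr::arrange(dplyr::bind_rows(truth_overlaps),
                     .data$ancestor_id, .data$descendant_id)
    } else empty_ov,
    candidates = if (length(truth_candidates) > 0) {
      dplyr::arrange(dplyr::bind_rows(truth_candidates),
                     .data$term_id, .data$norm)
    } else empty_cd,
    categories = levels[[1]]
  )
  structure(list(ontology = onto, truth = truth), class = "synsub_synth")
}

#' @export
print.synsub_synth <- function(x, ...) {
  cat(sprintf(
    "<synsub_synth> %d terms, %d planted overlaps, %d planted depth-1 candidates\n",
    x$truth$n_terms, nrow(x$truth$overlaps), nrow(x$truth$candidates)
  ))
  invisible(x)
}

#' Generate a seeded synthetic corpus with planted phrases
#'
#' Documents are streams of filler tokens drawn from a vocabulary disjoint
#' from every phrase token, so the planted phrases are the only matches
#' possible. Each phrase is inserted verbatim into `docs_per_phrase`
#' distinct documents (title or abstract); with probability `embed_rate`
#' the phrase is embedded inside a longer noun phrase (an extra token
#' directly appended), which must still count as an exact-phrase hit.
#'
#' @param phrases Character vector of phrases to plant (may be empty).
#' @param n_docs Number of documents; must be at least `docs_per_phrase`.
#' @param seed Integer seed.
#' @param docs_per_phrase Documents each phrase is planted in.
#' @param embed_rate Probability of embedding a planted occurrence inside a
#'   longer phrase.
#' @return A list with `corpus` (tibble `doc_id`, `title`, `abstract`) and
#'   `truth` (tibble `phrase`, `doc_id`, `field`, `embedded` recording every
#'   planted occurrence).
#' @export
synth_corpus <- function(phrases, n_docs = 20, seed = 1, docs_per_phrase = 1,
                         embed_rate = 0.25) {
  if (n_docs < docs_per_phrase) {
    abort("`n_docs` must be at least `docs_per_phrase`")
  }
  withr::with_seed(as.integer(seed), {
    filler_tokens <- function(n) sprintf("zfill%03d", sample(500, n, replace = TRUE))
    ids <- sprintf("DOC%04d", seq_len(n_docs))

    # draw every planting first, then build each field by interleaving
    # filler segments with the planted phrases as atomic units — a later
    # insertion can therefore never split an earlier phrase
    truth <- list()
    for (p in phrases) {
      for (d in sample(n_docs, docs_per_phrase)) {
        truth[[length(truth) + 1L]] <- tibble::tibble(
          phrase = p, doc_id = ids[d],
          field = sample(c("title", "abstract"), 1, prob = c(0.2, 0.8)),
          embedded = runif(1) < embed_rate
        )
      }
    }
    truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else
      tibble::tibble(phrase = character(), doc_id = character(),
                     field = character(), embedded = logical())

    build_field <- function(doc_id, n_filler, field) {
      plants <- truth[truth$doc_id == doc_id & truth$field == field, ]
      inserts <- ifelse(plants$embedded, paste(plants$phrase, "zembed"),
                        plants$phrase)
      toks <- filler_tokens(n_filler)
      if (length(inserts) == 0) return(paste(toks, collapse = " "))
      cuts <- sort(sample(0:length(toks), length(inserts), replace = TRUE))
      pieces <- character(0)
      prev <- 0L
      for (k in seq_along(inserts)) {
        if (cuts[k] > prev) pieces <- c(pieces, toks[(prev + 1):cuts[k]])
        pieces <- c(pieces, inserts[k])
        prev <- cuts[k]
      }
      if (prev < length(toks)) pieces <- c(pieces, toks[(prev + 1):length(toks)])
      paste(pieces, collapse = " ")
    }
    title_len <- sample(3:6, n_docs, replace = TRUE)
    abstract_len <- sample(15:30, n_docs, replace = TRUE)
    docs <- tibble::tibble(
      doc_id = ids,
      title = unname(purrr::map2_chr(ids, title_len, build_field,
                                     field = "title")),
      abstract = unname(purrr::map2_chr(ids, abstract_len, build_field,
                                        field = "abstract"))
    )
    list(corpus = docs, truth = truth)
  })
}
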