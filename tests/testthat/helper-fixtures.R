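# Shared fixtures and independent brute-force oracles.

# Mini hearing-loss ontology mirroring the classic phenotype example: an
# impairment term, its sensorineural child, and a high-frequency grandchild,
# with synonym sets chosen so the ancestor/child pair carries exactly three
# lexical overlaps.
hearing_ontology <- function() {
  ontology(
    terms = tibble::tibble(
      id = c("HP:0000365", "HP:0000407", "HP:0001757"),
      name = c("Hearing impairment",
               "Sensorineural hearing impairment",
               "High-frequency sensorineural hearing impairment")
    ),
    edges = tibble::tibble(
      id = c("HP:0000407", "HP:0001757"),
      parent = c("HP:0000365", "HP:0000407")
    ),
    synonyms = tibble::tibble(
      id = c("HP:0000365", "HP:0000365", "HP:0000365", "HP:0000365",
             "HP:0000407", "HP:0000407",
             "HP:0001757"),
      text = c("Hearing defect", "Deafness", "hearing loss",
               "congenital hearing loss",
               "sensorineural hearing loss", "Sensorineural deafness",
               "high-tone sensorineural hearing impairment"),
      scope = c("EXACT", "EXACT", "EXACT", "EXACT",
                "EXACT", "EXACT", "EXACT")
    )
  )
}

# Brute-force transitive closure by repeated edge relaxation (independent of
# the igraph-backed implementation).
oracle_closure <- function(edges) {
  if (nrow(edges) == 0) {
    return(tibble::tibble(ancestor_id = character(),
                          descendant_id = character(), min_depth = integer()))
  }
  direct <- data.frame(ancestor_id = edges$parent, descendant_id = edges$id,
                       min_depth = 1L, stringsAsFactors = FALSE)
  acc <- direct
  repeat {
    ext <- merge(acc,
                 data.frame(mid = edges$parent, child = edges$id,
                            stringsAsFactors = FALSE),
                 by.x = "descendant_id", by.y = "mid")
    if (nrow(ext) > 0) {
      ext <- data.frame(ancestor_id = ext$ancestor_id,
                        descendant_id = ext$child,
                        min_depth = ext$min_depth + 1L)
      acc2 <- rbind(acc, ext)
    } else {
      acc2 <- acc
    }
    acc2 <- stats::aggregate(min_depth ~ ancestor_id + descendant_id,
                             data = acc2, FUN = min)
    if (nrow(acc2) == nrow(acc) && sum(acc2$min_depth) == sum(acc$min_depth)) break
    acc <- acc2
  }
  dplyr::arrange(tibble::as_tibble(acc), ancestor_id, descendant_id)
}

# direct all-window token scan, the reference notion of containment
contains_bf <- function(big_tokens, small_tokens) {
  n <- length(big_tokens); m <- length(small_tokens)
  if (m == 0 || m > n) return(FALSE)
  for (s in 0:(n - m)) {
    if (all(big_tokens[(s + 1):(s + m)] == small_tokens)) return(TRUE)
  }
  FALSE
}

# Brute-force overlap scan: every closure pair x every synonym pair x every
# window position. Quadratic and loop-based on purpose.
oracle_overlaps <- function(onto, closure) {
  syn <- active_synonyms(onto)
  res <- list()
  for (r in seq_len(nrow(closure))) {
    a <- closure$ancestor_id[r]
    d <- closure$descendant_id[r]
    sa <- syn[syn$id == a, ]
    sd <- syn[syn$id == d, ]
    for (i in seq_len(nrow(sa))) {
      at <- strsplit(sa$norm[i], " ", fixed = TRUE)[[1]]
      for (j in seq_len(nrow(sd))) {
        dt <- strsplit(sd$norm[j], " ", fixed = TRUE)[[1]]
        if (length(dt) <= length(at)) next
        for (s in 0:(length(dt) - length(at))) {
          if (all(dt[(s + 1):(s + length(at))] == at)) {
            res[[length(res) + 1L]] <- tibble::tibble(
              ancestor_id = a, descendant_id = d,
              ancestor_norm = sa$norm[i], descendant_norm = sd$norm[j],
              start = s, n_tokens = length(at)
            )
          }
        }
      }
    }
  }
  out <- if (length(res) > 0) dplyr::bind_rows(res) else {
    tibble::tibble(ancestor_id = character(), descendant_id = character(),
                   ancestor_norm = character(), descendant_norm = character(),
                   start = integer(), n_tokens = integer())
  }
  dplyr::arrange(out, ancestor_id, descendant_id, ancestor_norm,
                 descendant_norm, start)
}

overlap_key_cols <- c("ancestor_id", "descendant_id", "ancestor_norm",
                      "descendant_norm", "start", "n_tokens")

as_overlap_keys <- function(x) {
  out <- dplyr::arrange(
    tibble::as_tibble(x)[overlap_key_cols],
    ancestor_id, descendant_id, ancestor_norm, descendant_norm, start
  )
  out$start <- as.integer(out$start)
  out$n_tokens <- as.integer(out$n_tokens)
  out
}

# random token phrases over a small alphabet (repeats allowed, so window
# scans see genuine partial matches)
random_phrase <- function(k, alphabet = letters[1:6]) {
  paste(sample(alphabet, k, replace = TRUE), collapse = " ")
}
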