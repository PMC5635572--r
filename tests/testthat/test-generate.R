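test_that("substitution splices the replacement into the overlapped span", {
  expect_equal(
    substitute_synonym("sensorineural hearing loss", "hearing loss",
                       "hearing defect"),
    "sensorineural hearing defect"
  )
  expect_equal(
    substitute_synonym("high-tone sensorineural hearing impairment",
                       "hearing impairment", "hearing loss"),
    "high tone sensorineural hearing loss"
  )
  expect_equal(substitute_synonym("Cortical cataract", "cataract",
                                  "Lens opacities"),
               "Cortical lens opacities")
  expect_error(substitute_synonym("sensorineural hearing loss",
                                  "hearing loss", "Hearing Loss"),
               "no-op")
  expect_error(substitute_synonym("hearing loss", "deafness", "x"),
               "does not contain")
})

test_that("substitution is reversible and token-length arithmetic holds", {
  set.seed(31)
  for (i in 1:50) {
    flank_l <- random_phrase(sample(0:3, 1), letters[1:4])
    flank_r <- random_phrase(sample(0:3, 1), letters[5:8])
    ov <- random_phrase(sample(1:3, 1), letters[9:12])
    repl <- random_phrase(sample(1:4, 1), letters[13:17])
    desc <- trimws(paste(flank_l, ov, flank_r))
    start <- if (nzchar(flank_l)) token_count(flank_l) else 0L
    cand <- substitute_synonym(desc, ov, repl, start = start)
    expect_equal(token_count(cand),
                 token_count(desc) - token_count(ov) + token_count(repl))
    back <- substitute_synonym(cand, repl, ov, start = start)
    expect_equal(normalize_phrase(back), normalize_phrase(desc))
  }
})

test_that("scope inference propagates the weakest claim", {
  expect_equal(infer_scope("EXACT", "EXACT", "RELATED"), "RELATED")
  expect_equal(infer_scope("EXACT", "EXACT", "EXACT"), "EXACT")
  expect_equal(infer_scope("EXACT", "UNSPECIFIED", "EXACT"), "UNSPECIFIED")
  expect_equal(infer_scope("NARROW", "EXACT", "BROAD"), "RELATED")
  expect_equal(infer_scope("NARROW", "EXACT", "NARROW"), "NARROW")

  # commutative, associative, with EXACT as the identity
  scopes <- SCOPE_LEVELS
  for (a in scopes) {
    expect_equal(scope_meet("EXACT", a), a)
    for (b in scopes) {
      expect_equal(scope_meet(a, b), scope_meet(b, a))
      for (c in scopes) {
        expect_equal(scope_meet(scope_meet(a, b), c),
                     scope_meet(a, scope_meet(b, c)))
      }
    }
  }
})

test_that("generation enumerates overlap x replacement and partitions against the ontology", {
  onto <- remove_redundant_synonyms(hearing_ontology())$ontology
  ov <- find_overlaps(onto)
  gen <- generate_candidates(onto, ov)
  cand <- gen$candidates

  # the overlap "hearing loss" in "sensorineural hearing loss" has three
  # eligible replacements (name + 2 other synonyms of the ancestor)
  from_hl <- cand[cand$descendant_synonym == "sensorineural hearing loss", ]
  expect_setequal(from_hl$text,
                  c("sensorineural hearing impairment",
                    "sensorineural hearing defect", "sensorineural deafness"))
  # two of those three already exist in the ontology
  expect_equal(sum(from_hl$existing), 2L)
  expect_equal(from_hl$text[!from_hl$existing], "sensorineural hearing defect")

  g <- glance(gen)
  expect_equal(g$n_generated, g$n_existing + g$n_novel)
  novel <- novel_candidates(gen)
  expect_false(any(novel$norm %in% onto$synonyms$norm))

  # token-length arithmetic holds for every generated row
  expect_equal(
    token_count(cand$text),
    token_count(cand$descendant_synonym) - token_count(cand$overlap_string) +
      token_count(cand$substituted_synonym)
  )
})

test_that("an ontology without overlaps generates nothing and depth must be positive", {
  fx <- synth_ontology(seed = 4, genus_differentia_rate = 0)
  ov <- find_overlaps(fx$ontology)
  gen <- generate_candidates(fx$ontology, ov)
  expect_equal(nrow(gen$candidates), 0L)
  expect_error(generate_candidates(fx$ontology, ov, max_depth = 0), "positive")
})

test_that("deeper recursion re-substitutes candidates and is monotone in depth", {
  # the replacement "sharp pain" still contains the overlap string "pain",
  # so a depth-1 candidate can be rewritten again at depth 2
  onto <- ontology(
    terms = tibble::tibble(id = c("g", "d"),
                           name = c("pain", "chronic pain")),
    edges = tibble::tibble(id = "d", parent = "g"),
    synonyms = tibble::tibble(id = c("g", "g"),
                              text = c("ache", "sharp pain"),
                              scope = c("EXACT", "NARROW"))
  )
  ov <- find_overlaps(onto)
  d1 <- generate_candidates(onto, ov, max_depth = 1)
  d2 <- generate_candidates(onto, ov, max_depth = 2)
  expect_setequal(unique(d1$candidates$norm),
                  c("chronic ache", "chronic sharp pain"))
  key <- function(g) unique(paste(g$candidates$term_id, g$candidates$norm))
  expect_true(all(key(d1) %in% key(d2)))
  d2_new <- d2$candidates[d2$candidates$depth == 2L, ]
  expect_true("chronic sharp ache" %in% d2_new$norm)
  expect_false("chronic sharp ache" %in% d1$candidates$norm)
  # the rewritten candidate keeps the weakest scope along its history
  expect_true(all(d2_new$scope[d2_new$norm == "chronic sharp ache"] == "NARROW"))
})
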