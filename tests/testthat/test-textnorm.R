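test_that("normalization splits hyphens, drops bracketed spans, lowercases", {
  expect_equal(phrase_tokens("criss-cross atrioventricular valves")[[1]],
               c("criss", "cross", "atrioventricular", "valves"))
  expect_equal(token_count("thyroid stimulating hormone receptor (tshr) defect"), 5L)
  expect_equal(phrase_tokens("Deafness")[[1]], "deafness")
  expect_equal(normalize_phrase("High-tone [old] {x} loss"), "high tone loss")
  # unmatched brackets stay literal
  expect_equal(normalize_phrase("open ( bracket"), "open ( bracket")
  expect_error(normalize_phrase("(all bracketed)"), "degenerate")
  expect_error(normalize_phrase("   "), "degenerate")
})

test_that("normalization is idempotent and case-insensitive", {
  set.seed(42)
  phrases <- c(
    "Criss-Cross (ACR) Valves", "high-tone sensorineural hearing impairment",
    "THYROID stimulating  hormone", "alpha-1 anti-trypsin [serum]",
    replicate(20, random_phrase(sample(1:8, 1), c(letters[1:5], "ab-cd", "(x)")))
  )
  norm <- normalize_phrase(phrases, allow_empty = TRUE)
  expect_equal(normalize_phrase(norm, allow_empty = TRUE), norm)
  expect_equal(normalize_phrase(toupper(phrases), allow_empty = TRUE), norm)
})

test_that("containment is token-level and agrees with a window-scan oracle", {
  expect_true(phrase_contains("sensorineural hearing loss", "hearing loss",
                              proper = TRUE))
  expect_false(phrase_contains("hearing loss", "hearing loss", proper = TRUE))
  expect_true(phrase_contains("hearing loss", "hearing loss", proper = FALSE))
  expect_false(phrase_contains("heart disease", "art", proper = TRUE))
  expect_false(phrase_contains("hearing loss", "sensorineural hearing loss",
                               proper = TRUE))

  set.seed(7)
  for (i in 1:200) {
    big <- random_phrase(sample(1:12, 1))
    small <- random_phrase(sample(1:4, 1))
    bt <- strsplit(big, " ")[[1]]
    st <- strsplit(small, " ")[[1]]
    expect_equal(
      phrase_contains(big, small, proper = TRUE),
      contains_bf(bt, st) && length(bt) > length(st),
      info = paste(big, "|", small)
    )
  }
})

test_that("redundant synonyms are removed, names are protected, and pruning is idempotent", {
  onto <- hearing_ontology()
  pruned <- remove_redundant_synonyms(onto)
  expect_equal(pruned$removed$text, "congenital hearing loss")
  expect_false("congenital hearing loss" %in% pruned$ontology$synonyms$text)
  expect_true(all(c("Hearing impairment", "hearing loss") %in%
                    pruned$ontology$synonyms$text))

  again <- remove_redundant_synonyms(pruned$ontology)
  expect_equal(nrow(again$removed), 0L)
  expect_equal(again$ontology$synonyms, pruned$ontology$synonyms)

  # chain a < a b < a b c: every superstring of a surviving synonym goes
  chain <- flag_redundant_synonyms(tibble::tibble(
    id = "T:1", text = c("a", "a b", "a b c"), is_name = c(TRUE, FALSE, FALSE)
  ))
  expect_equal(chain$redundant, c(FALSE, TRUE, TRUE))

  # names are never removed even when they contain a synonym
  prot <- flag_redundant_synonyms(tibble::tibble(
    id = "T:2", text = c("congenital hearing loss", "hearing loss"),
    is_name = c(TRUE, FALSE)
  ))
  expect_equal(prot$redundant, c(FALSE, FALSE))

  # pairwise non-containing sets are untouched
  free <- flag_redundant_synonyms(tibble::tibble(
    id = "T:3", text = c("alpha beta", "beta gamma", "delta"),
    is_name = c(TRUE, FALSE, FALSE)
  ))
  expect_false(any(free$redundant))
})

test_that("pruning only ever shrinks the synonym set", {
  for (seed in 1:5) {
    fx <- synth_ontology(seed = seed, redundant_rate = 0.3)
    before <- nrow(fx$ontology$synonyms)
    pruned <- remove_redundant_synonyms(fx$ontology)
    expect_lte(nrow(pruned$ontology$synonyms), before)
    expect_equal(nrow(pruned$ontology$synonyms) + nrow(pruned$removed), before)
  }
})
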