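write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("OBO parsing loads terms, synonym scopes, parents and obsolete flags", {
  path <- write_lines_tmp(c(
    "format-version: 1.2",
    "date: 13:01:2016 12:00",
    "",
    "[Term]",
    "id: HP:0001970",
    "name: Tubulointerstitial nephritis",
    "def: \"ignored\" [x]",
    "xref: UMLS:C0041349",
    "",
    "[Term]",
    "id: HP:0004729",
    "name: Acute tubulointerstitial nephritis",
    "synonym: \"Acute interstitial nephritis\" EXACT []",
    "synonym: \"AIN\" []",
    "is_a: HP:0001970 ! Tubulointerstitial nephritis",
    "",
    "[Term]",
    "id: HP:0009999",
    "name: Gone",
    "is_obsolete: true",
    "",
    "[Typedef]",
    "id: part_of",
    "name: part of"
  ))
  onto <- read_obo(path)
  expect_s3_class(onto, "synsub_ontology")
  expect_equal(nrow(onto$terms), 3L)
  expect_equal(sum(onto$terms$obsolete), 1L)
  expect_equal(onto$edges,
               tibble::tibble(id = "HP:0004729", parent = "HP:0001970"))
  syn <- onto$synonyms[onto$synonyms$id == "HP:0004729", ]
  # the name is folded in as an EXACT synonym
  expect_setequal(syn$text, c("Acute tubulointerstitial nephritis",
                              "Acute interstitial nephritis", "AIN"))
  expect_equal(syn$scope[syn$text == "AIN"], "UNSPECIFIED")
  expect_equal(syn$scope[syn$is_name], "EXACT")
})

test_that("a file with no [Term] stanzas yields an empty model", {
  path <- write_lines_tmp(c("format-version: 1.2", ""))
  onto <- read_obo(path)
  expect_equal(nrow(onto$terms), 0L)
  expect_equal(nrow(onto$synonyms), 0L)
})

test_that("parse errors name the offending line or reference", {
  bad_line <- write_lines_tmp(c("[Term]", "id: A:1", "name: a", "what even"))
  expect_error(read_obo(bad_line), "line 4")

  dup <- write_lines_tmp(c("[Term]", "id: A:1", "name: a", "",
                           "[Term]", "id: A:1", "name: b"))
  expect_error(read_obo(dup), "duplicate")

  dangling <- write_lines_tmp(c("[Term]", "id: A:1", "name: a",
                                "is_a: A:9", "is_a: A:8"))
  err <- expect_error(read_obo(dangling), "unknown id")
  expect_match(conditionMessage(err), "A:8")
  expect_match(conditionMessage(err), "A:9")

  cyc <- write_lines_tmp(c("[Term]", "id: A:1", "name: a", "is_a: A:2", "",
                           "[Term]", "id: A:2", "name: b", "is_a: A:1"))
  expect_error(read_obo(cyc), "cycle")
})

test_that("write/parse round-trips terms, parents, synonym texts and scopes", {
  for (seed in c(3, 11)) {
    fx <- synth_ontology(seed = seed, redundant_rate = 0.2)
    onto <- fx$ontology
    path <- withr::local_tempfile(fileext = ".obo")
    write_obo(onto, path)
    back <- read_obo(path)
    expect_equal(dplyr::arrange(back$terms, id), dplyr::arrange(onto$terms, id))
    expect_equal(dplyr::arrange(back$edges, id, parent),
                 dplyr::arrange(onto$edges, id, parent))
    key <- function(o) dplyr::arrange(
      o$synonyms[c("id", "text", "scope", "is_name")], id, text, scope)
    expect_equal(key(back), key(onto))

    # writing twice is byte-identical
    path2 <- withr::local_tempfile(fileext = ".obo")
    write_obo(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("an enriched file re-parses to the original model plus the accepted synonyms", {
  onto <- hearing_ontology()
  accepted <- tibble::tibble(term_id = "HP:0000407",
                             text = "sensorineural hearing defect",
                             scope = "EXACT")
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(onto, path, accepted = accepted)
  back <- read_obo(path)
  extra <- dplyr::anti_join(back$synonyms, onto$synonyms,
                            by = c("id", "text", "scope"))
  expect_equal(nrow(extra), 1L)
  expect_equal(extra$text, "sensorineural hearing defect")

  # no candidates: output equals a plain rewrite of the model
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_obo(onto, p1)
  write_obo(onto, p2, accepted = accepted[0, ])
  expect_identical(readLines(p1), readLines(p2))

  # duplicating an existing synonym (case-insensitively) is an error
  expect_error(
    write_obo(onto, path, accepted = tibble::tibble(
      term_id = "HP:0000365", text = "HEARING LOSS", scope = "EXACT")),
    "duplicat"
  )
  expect_error(
    write_obo(onto, path, accepted = tibble::tibble(
      term_id = "HP:9999999", text = "x", scope = "EXACT")),
    "unknown term"
  )
})

test_that("candidate reports are sorted, complete and header-stable", {
  cand <- tibble::tibble(
    term_id = c("HP:0012715", "HP:0000407", "HP:0012715"),
    term_name = c("Profound hearing impairment",
                  "Sensorineural hearing impairment",
                  "Profound hearing impairment"),
    text = c("Profound hearing loss", "sensorineural hearing defect",
             "Profound deafness"),
    scope = "EXACT",
    ancestor_id = "HP:0000365",
    substituted_synonym = c("hearing loss", "Hearing defect", "Deafness"),
    overlap_string = "Hearing impairment",
    corpus_validated = c(TRUE, TRUE, FALSE)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(cand, path)
  out <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(out),
               c("term_id", "term_name", "candidate_text", "scope",
                 "ancestor_term_id", "substituted_synonym", "overlap_string",
                 "corpus_validated"))
  expect_equal(out$candidate_text,
               c("sensorineural hearing defect", "Profound deafness",
                 "Profound hearing loss"))

  write_candidates(cand[0, ], path)
  empty <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(empty), 0L)
  expect_equal(ncol(empty), 8L)
})
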