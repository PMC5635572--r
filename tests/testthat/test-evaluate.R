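test_that("precision, recall and F follow the micro-averaged formulas", {
  gold <- tibble::tibble(doc_id = c("d1", "d1", "d2", "d3"),
                         term_id = c("a", "b", "a", "c"))
  perfect <- prf_scores(gold, gold)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f_measure),
               c(1, 1, 1))

  system <- tibble::tibble(doc_id = c("d1", "d1", "d2"),
                           term_id = c("a", "b", "x"))
  got <- prf_scores(system, gold)
  expect_equal(got[c("tp", "fp", "fn")],
               tibble::tibble(tp = 2L, fp = 1L, fn = 2L))
  expect_equal(got$precision, 2 / 3)
  expect_equal(got$recall, 1 / 2)
  expect_equal(got$f_measure, 4 / 7)

  nothing <- prf_scores(gold[0, ], gold)
  expect_equal(c(nothing$precision, nothing$recall, nothing$f_measure),
               c(0, 0, 0))
  expect_error(prf_scores(system, gold[0, ]), "empty")

  # duplicates do not inflate counts; F never exceeds max(P, R)
  dup <- prf_scores(system[c(1, 1, 2, 3), ], gold[c(1, 1:4), ])
  expect_equal(dup$tp, 2L)
  expect_lte(dup$f_measure, max(dup$precision, dup$recall))
})

test_that("the dictionary annotator matches exact phrases with longest-match-wins", {
  corpus <- tibble::tibble(
    doc_id = c("d1", "d2"),
    title = c("Sensorineural hearing loss in twins", "Unrelated title"),
    abstract = c("We report profound hearing loss and cataract.",
                 "Nothing phenotypic here.")
  )
  dict <- tibble::tibble(
    term_id = c("HP:0000365", "HP:0000407", "HP:0012715", "HP:0000518"),
    text = c("hearing loss", "sensorineural hearing loss",
             "profound hearing loss", "cataract")
  )
  ann <- annotate_corpus(corpus, dict)
  # the title match is claimed by the more detailed sensorineural term,
  # the abstract match by the profound term; plain "hearing loss" is nested
  # inside both and yields no annotation of its own
  expect_setequal(paste(ann$doc_id, ann$term_id),
                  c("d1 HP:0000407", "d1 HP:0012715", "d1 HP:0000518"))
})

test_that("retrieval increase reproduces the totals-row arithmetic and band layout", {
  # the printed totals: 134,367 baseline vs 142,041 enriched -> 6 percent
  expect_equal(round(synsub:::increase_rate(134367, 142041, "baseline")), 6)
  expect_equal(round(synsub:::increase_rate(134367, 142041, "enriched")), 5)
  expect_equal(synsub:::increase_rate(10, 10), 0)
  expect_equal(synsub:::increase_rate(0, 0), 0)

  ic <- information_content(
    tibble::tibble(term_id = c(rep("t1", 99), "t2")), c("t1", "t2", "t3"))
  # disjoint per-term doc sets so every aggregate is additive
  baseline <- tibble::tibble(
    term_id = c(rep("t1", 3), rep("t2", 2)),
    doc_id = c("a1", "a2", "a3", "b1", "b2")
  )
  enriched <- dplyr::bind_rows(
    baseline,
    tibble::tibble(term_id = c("t2", "t3"), doc_id = c("b3", "c1"))
  )
  expect_error(retrieval_increase(baseline, enriched, ic), "universe")
  rep_tbl <- retrieval_increase(baseline, enriched, ic,
                                terms = c("t1", "t2", "t3"))
  totals <- rep_tbl[rep_tbl$ic_bin == "Total" & rep_tbl$volume_band == "Total", ]
  expect_equal(totals$baseline_docs, 5L)
  expect_equal(totals$enriched_docs, 7L)
  expect_equal(totals$increase_rate, 100 * 2 / 5)

  # per-band cells sum to the grand total when doc sets are disjoint
  cells <- rep_tbl[rep_tbl$ic_bin != "Total" & rep_tbl$volume_band != "Total", ]
  expect_equal(sum(cells$baseline_docs), totals$baseline_docs)
  expect_equal(sum(cells$enriched_docs), totals$enriched_docs)

  same <- retrieval_increase(baseline, baseline, ic,
                             terms = c("t1", "t2", "t3"))
  expect_true(all(same$increase_rate == 0))

  # a term gaining m new documents shows them in its band row
  t3_row <- rep_tbl[rep_tbl$volume_band == "(0,100)" & rep_tbl$ic_bin == "undefined", ]
  expect_equal(t3_row$baseline_docs, 0L)
  expect_equal(t3_row$enriched_docs, 1L)
})
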