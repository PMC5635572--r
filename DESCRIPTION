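Package: synsub
Title: Synonym-Substitution Enrichment of Hierarchical Biomedical Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enriches hierarchical biomedical ontologies (such as the Human
    Phenotype Ontology) with new synonyms by exploiting their compositional
    naming structure. The method detects lexical overlaps between the
    synonyms of hierarchically related terms, generates candidate synonyms
    by substituting the overlapped fragment with other synonyms of the
    ancestor term, infers the scope (exact, broad, narrow, related) of each
    candidate, and rules out candidates lacking exact-phrase evidence in a
    document corpus. Includes information-content metrics from curated
    disease annotations, annotation- and retrieval-level evaluation against
    gold standards, seeded synthetic ontology and corpus generators, and
    OBO 1.2 flat-file input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
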