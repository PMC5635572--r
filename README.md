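# synsub

Synonym-substitution enrichment of hierarchical biomedical ontologies.

Dictionary-based concept recognition lives or dies by synonym coverage:
ontologies such as the Human Phenotype Ontology (HPO) name a concept once
and list a handful of synonyms, while the literature refers to it in many
more ways. `synsub` enriches an ontology with new synonyms automatically by
exploiting two of its own properties — the is-a hierarchy and the
genus–differentia style of term naming — and validates every generated
string against a document corpus. It is aimed at ontology engineers and
text-mining practitioners who need a richer lexicon without manual curation.

## The method

1. **Prune redundant synonyms.** A synonym whose token sequence properly
   contains another synonym of the same term (e.g. *congenital hearing
   loss* alongside *hearing loss*) adds nothing to recognition and is
   removed. Term names are protected.
2. **Lexical overlaps.** Over the transitive closure of the is-a DAG, find
   every pair of synonyms (*s_a*, *s_d*) of an ancestor/descendant term
   pair where *s_a* occurs as a proper contiguous token subsequence of
   *s_d* — e.g. *hearing loss* inside *sensorineural hearing loss*.
   Matching is token-level on normalized strings (lowercase, hyphens split,
   bracketed spans dropped).
3. **Substitution.** For each overlap and each other synonym *r* of the
   ancestor, emit the candidate *s_d* with the overlapped span replaced by
   *r*: replacing *hearing loss* with *hearing defect* in *sensorineural
   hearing loss* yields *sensorineural hearing defect*. The raw candidate
   multiset **A** is partitioned against the ontology's synonym set **B**;
   the set difference A∖B is the novel yield.
4. **Scope inference.** The candidate's scope (EXACT / NARROW / BROAD /
   RELATED / none) is the weakest claim among the three scopes involved,
   under EXACT > NARROW = BROAD > RELATED > UNSPECIFIED (NARROW and BROAD
   meet at RELATED).
5. **Corpus validation.** Candidates are searched as exact phrases in the
   title/abstract fields of a corpus (a local TSV/MEDLINE-XML scan, or
   live PubMed through an optional adapter); candidates found in no
   document are ruled out as nonsensical.

Impact is measured by information content, `IC(t) = -log10 p(t)` with
`p(t)` the term's share of a curated disease-annotation table, by
micro-averaged precision/recall/F against gold concept annotations, and by
per-term document-retrieval gains stratified by IC bin.

## A worked example

```r
library(synsub)
onto <- ontology(
  terms = tibble::tibble(
    id   = c("HP:0000365", "HP:0000407"),
    name = c("Hearing impairment", "Sensorineural hearing impairment")),
  edges = tibble::tibble(id = "HP:0000407", parent = "HP:0000365"),
  synonyms = tibble::tibble(
    id    = c("HP:0000365", "HP:0000365", "HP:0000365", "HP:0000407"),
    text  = c("Hearing defect", "Deafness", "hearing loss",
              "sensorineural hearing loss"),
    scope = "EXACT"))

find_overlaps(onto)
#> # A tibble: 2 × 4
#>   ancestor_norm      descendant_norm                  start n_tokens
#>   <chr>              <chr>                            <int>    <int>
#> 1 hearing impairment sensorineural hearing impairment     1        2
#> 2 hearing loss       sensorineural hearing loss           1        2

gen <- generate_candidates(onto, find_overlaps(onto))
gen
#> <synsub_generation> depth 1: 6 generated (4 distinct strings),
#>   2 already in ontology, 2 novel strings

novel_candidates(gen)[, c("term_id", "text", "scope", "substituted_synonym")]
#> # A tibble: 2 × 4
#>   term_id    text                         scope substituted_synonym
#> 1 HP:0000407 Sensorineural deafness       EXACT Deafness
#> 2 HP:0000407 Sensorineural hearing defect EXACT Hearing defect
```

Both ancestor synonyms overlap a descendant synonym (span columns are
0-based token coordinates); each overlap is rewritten with the remaining
ancestor synonyms, two of the six rewrites already exist in the ontology
(e.g. the name itself), and the two genuinely new strings are attached to
the descendant with their inferred scope. `enrich_ontology()` chains all of
this (plus pruning and corpus filtering) and `write_enrichment()` emits the
candidate TSV, the enriched OBO file and a stats summary;
`inst/cli/synsub` exposes the same steps as shell subcommands.

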