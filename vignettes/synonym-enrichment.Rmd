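---
title: "Synonym enrichment by hierarchical lexical-overlap substitution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synonym enrichment by hierarchical lexical-overlap substitution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synsub)
```

## The model and its assumptions

Hierarchical biomedical ontologies name many terms compositionally: a child
adds a differentiating modifier to (a synonym of) its ancestor, as in
*hearing loss* → *sensorineural hearing loss*. `synsub` turns this
convention into a synonym generator. Whenever a synonym of an ancestor term
occurs as a proper contiguous token subsequence inside a synonym of one of
its descendants (a *lexical overlap*), the overlapped span can be replaced
by any other synonym of the ancestor, producing a candidate synonym for the
descendant. The method therefore assumes that (i) the is-a hierarchy is
trustworthy, (ii) within an overlap the overlapped span really denotes the
ancestor concept, and (iii) phrase-level substitution preserves meaning.
Assumption (iii) fails often enough that a final evidence filter is
applied: a candidate must occur as an exact phrase in the title or abstract
of at least one document of a reference corpus, otherwise it is ruled out
as nonsensical. Restricting overlaps to hierarchically related pairs —
rather than arbitrary term pairs — is what keeps the homonym problem of
earlier word-level substitution systems at bay: the replacement is only
ever applied where the hierarchy asserts the overlapped phrase carries the
ancestor's meaning.

The pipeline is: prune redundant synonyms → transitive closure → overlap
detection → substitution with scope inference → corpus filtering →
enriched ontology. `enrich_ontology()` runs it end to end and keeps per-
stage counts so that any unexpected number can be attributed to one stage.

## Normalization and matching conventions

All matching happens on normalized strings: lowercase; hyphens between word
characters split into spaces (*criss-cross* → *criss cross*); matched
bracket spans `()`, `[]`, `{}` removed entirely, because in ontology labels
they hold acronyms or clarifications that are useless for text mining (so
*thyroid stimulating hormone receptor (tshr) defect* has five tokens);
whitespace collapsed. Normalization is idempotent. Containment is defined
on token sequences, never on raw characters — *art* is not inside *heart
disease* — because every compositional example in phenotype ontologies is
a whole-word overlap, and character-level matches would license unsafe
substitutions. Other punctuation stays attached to its token to preserve
exact-phrase fidelity. Unmatched brackets are kept as literal characters.

Case-insensitivity deserves a note: ontology synonyms are mixed-case, and
generated synonyms in the literature on this method are printed with the
descendant's leading capital but a lowercased replacement (*Cortical
cataract* + *Lens opacities* → *Cortical lens opacities*). The candidate
surface rule reproduces exactly that: the spliced token sequence is
lowercase, and a leading capital is restored if and only if the descendant
synonym began with one.

Documents are normalized with the same lowercasing and hyphen splitting,
but bracketed content is *kept* (brackets in running prose carry text) and
punctuation at token edges is stripped, so a phrase is found across
sentence punctuation. A phrase occurring inside a longer noun phrase
counts as a hit — *anterior spinal fusion* is found in *anterior spinal
fusion surgery* — mirroring how a bibliographic search engine treats
quoted phrases. This is deliberate even though it occasionally lets an
unidiomatic candidate survive filtering.

## Redundancy pruning

A synonym that properly contains another synonym of the same term is
redundant for recognition (any match of the longer string implies a match
of the shorter) and, worse, inflates overlap detection. Such synonyms are
removed before anything else; removal is checked against the *original*
synonym set, so in a chain {a, a b, a b c} both superstrings go. The
preferred name is never removed — deleting names would corrupt the
ontology, and pruning is a lexicon operation, not an editorial one.

## Closure, overlap identity, and counting

The transitive closure is computed per top-level category (the children of
the unique root, or the roots themselves if there are several) with
`igraph` shortest-path distances providing `min_depth`; a term under
several categories participates in each, and the global pair set is the
deduplicated union, which is what `term_closure()` without a category
returns directly. Obsolete terms are excluded everywhere.

"Unique overlap" counting needs an identity rule, and two are defensible:
the ordered pair of normalized strings (ancestor synonym, descendant
synonym), or the pair of term ids. `unique_overlaps()` adopts the string
pair as the reported statistic — it is the natural unit for the token-count
histogram, whose token axis refers to the overlapped (ancestor) string —
and `glance()` on an overlap set exposes both counts so either convention
can be checked. When one ancestor string occurs at several positions of a
descendant string, each position is a separate occurrence but one identity.

## Substitution, scope, and the A/B accounting

Replacements are all synonyms of the ancestor term except the overlapped
string itself (a no-op). The default recursion depth is 1: every published
example of the method is a single substitution, and deeper recursion mainly
re-rewrites replacements that themselves contain overlap strings.
`max_depth` raises it explicitly; candidate sets are monotone in depth and
deduplicated against previously seen (term, string) pairs, so recursion
always terminates.

Scope inference takes "the most restrictive type" to mean the *weakest
synonymy claim* among the three scopes involved (descendant synonym,
overlapped synonym, replacement) — that is the only reading consistent
with the worked example in which two exact strings and a related
replacement yield a related synonym. The ordering is
EXACT > NARROW = BROAD > RELATED > UNSPECIFIED; NARROW and BROAD are
incomparable and meet at RELATED. The meet is commutative and associative,
so multi-step recursion is order-independent.

The raw substitution output **A** is a multiset. The published accounting
compares it against the ontology's global synonym string set **B**, so
`generate_candidates()` flags a candidate as *existing* when its normalized
string occurs anywhere in the ontology, and reports both the multiset and
distinct-string sizes (the literature's printed totals are consistent with
multiset counting of A and A∩B). On top of the set difference, candidates
that would themselves be redundant for their term (properly containing
another synonym of the same term) are excluded from the *eligible* set, so
the enriched ontology stays consistent with the pruning stage.
`write_obo()` emits UNSPECIFIED-scope synonyms as scope-less synonym
lines, the OBO representation that round-trips exactly.

## Corpus filtering

`filter_candidates()` counts matching *documents* (not occurrences),
retains candidates with at least one hit, preserves order and never adds
candidates; filtering against an empty corpus is an error rather than a
silent mass discard. The live PubMed adapter (`pubmed_phrase_counts()`)
queries E-utilities `esearch` with the quoted phrase restricted to
title/abstract, caches every count with its query date because database
counts drift, and is excluded from the test suite; the local scanner is
the reproducible path and the two agree on planted fixtures by
construction. Whether a search engine's phrase index tokenizes exactly
like this scanner is unknowable from outside; divergences on live queries
are surfaced by the cached counts rather than hidden.

## Information content and evaluation

`p(t)` is estimated by direct counting: the term's share of the curated
annotation records, with the total record count as denominator — the
plainest reading of "probability of appearing in the annotations". No
ancestor propagation is applied (an annotation of a leaf does not count
toward its ancestors); that choice matches the flat wording of the source
definition, keeps `sum(p) = 1`, and is the variant all reported numbers
use. Terms absent from the annotations are *undefined* rather than
infinitely informative. Bins are half-open: ic = 1 falls in [1,2), and on
real annotation tables IC lands in (0,4); a [4,∞) bin appears only if data
demand it.

Annotation evaluation is micro-averaged over exact (document, term) pairs
— the decimal precision of the reference results implies pooling, and the
gold corpus is described by concept annotations without spans, so
span-level scoring is out of scope. An empty system output scores P = 0 by
convention. The bundled `annotate_corpus()` is a deliberately minimal
recognizer (exact normalized-phrase lookup, longest-match-wins) provided
so end-to-end fixtures are runnable; it omits the stemming and word-order
permutation of production annotators and is not an evaluation target
itself.

Retrieval gain compares per-term document sets of a baseline and an
enriched annotation run over the terms that received new synonyms. Each
cell counts *distinct* documents annotated by at least one term of the
group; because a document can be annotated by terms of two groups, band
rows can overlap and need not sum to the totals row on real data (the
reference table has the same property), though they do sum when per-band
document sets are disjoint, which is how the arithmetic is tested. The
increase rate is `(enriched − baseline) / baseline × 100`: of the two
candidate denominators, only this one reproduces the published totals-row
arithmetic (134,367 → 142,041 printed as 6). The `/enriched` variant is
available via an argument. Volume bands (>1000, [100,1000), (0,100)) are
assigned from the enriched run's per-term counts. One caveat worth naming:
under longest-match-wins, enriching a dictionary can *remove* a baseline
annotation (the shorter match becomes nested inside a new longer one), so
the per-term superset property holds for dictionary growth in general but
not for this recognizer; `retrieval_increase()` warns when it observes
lost pairs instead of failing.

## The synthetic study conditions

`synth_ontology()` emulates exactly the features the method exercises: a
single formal root; top-level categories; genus–differentia naming below
the categories (probability 0.6 per child, about the rate at which a
heavily compositional phenotype ontology reads); scoped variant synonyms
at 0.7 expected per term, giving ≈1.7 synonyms per term including names;
planted redundant synonyms at 3% of synonyms; ≈0.5% obsolete terms; and
10% extra cross edges making the graph a genuine DAG. Every token is drawn
fresh from disjoint vocabularies, so the planted structures are the *only*
containments possible and the generator can record its ground truth
(redundant synonyms, every overlap, every depth-1 candidate) exhaustively
at construction — that recorded truth, not a re-run of the pipeline, is
the oracle the tests compare against. `synth_corpus()` builds documents
from filler vocabulary disjoint from all phrase tokens and interleaves the
planted phrases as atomic units (so no insertion can split another), with
a fraction embedded inside longer phrases to exercise the noun-phrase
behavior.

What the generator does **not** model: morphological and word-order
variation, polysemy and homonymy, shared tokens between unrelated terms,
and real corpus language. Passing tests therefore demonstrate the
correctness of the machinery — closure, containment, substitution,
accounting, filtering — not the linguistic quality of candidates on a real
ontology; the latter is exactly what the corpus filter and the release-
level statistics are for.

Problem sizes: the acceptance script runs a 5-category, depth-4,
branching-3 ontology (606 active terms), a 600-document corpus with 60% of
candidate strings planted, and synthetic curated annotations covering 75%
of terms with a Zipf-like usage profile (a long tail of rare terms, as
curated phenotype annotations have); the oracle-equivalence suite runs 20
seeded fixtures of at most 100 terms each against brute-force reachability
and quadratic all-pairs overlap scans. These sizes were chosen to exercise
every code path several times over while keeping a full run comfortably
interactive.

## Numerical and degenerate-input choices

Empty or bracket-only phrases are degenerate-phrase errors rather than
silent empties. Duplicate ids, dangling is-a references (all listed) and
is-a cycles among non-obsolete terms (one cycle named) are constructor
errors. Candidate reports are sorted by (term, candidate text); OBO output
sorts stanzas by id and synonyms by text, so writing is deterministic and
re-writing a parsed file is byte-stable. An increase rate with a zero
denominator is 0 when nothing changed and NA otherwise. Scope keywords
missing from an OBO synonym line parse as UNSPECIFIED, the state meaning
"no relatedness information", and 12%-style shares of such synonyms
propagate through generation as UNSPECIFIED rather than being coerced to
RELATED.

## Known limitations

Release-scale reproduction requires the archived ontology release file,
which is too large to ship inside the package; the corresponding
acceptance test reports its absence rather than silently passing. The
bundled recognizer is intentionally minimal, so absolute P/R/F values on
synthetic corpora are not comparable to production annotators — only the
baseline-versus-enriched contrast is meaningful. Live PubMed validation is
inherently date-dependent; cached query dates make that drift visible but
cannot remove it.
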