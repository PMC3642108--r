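---
title: "Validating ontology-mapped entity annotations by semantic similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating ontology-mapped entity annotations by semantic similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semsimval)
```

## The problem

Named-entity recognition and resolution tools map text mentions to ontology
concepts — for chemistry, typically ChEBI identifiers — and their precision
is limited: dictionary lookup and statistical recognisers alike produce
many annotations that are not genuine chemical entities, or are grounded to
the wrong concept. `semsimval` is a tool-agnostic post-filter. It consumes
the annotations any such pipeline produces (a TSV of document, window,
offsets, surface text, concept id) and asks, for every mention: *is there
at least one semantically related concept co-mentioned in the same text
window?* Genuine mentions usually have one; spurious ones usually do not.

## Model and assumptions

**Ontology backbone.** The ontology is reduced to a DAG over a whitelist of
relation types, `"is_a"` by default. This step is not optional for ChEBI,
which ships symmetric relation types ("is enantiomer of", "is tautomer of")
that create 2-cycles; `filterRelations()` verifies acyclicity and names a
cycle when the whitelist admits one. Obsolete terms are kept only for
identifier resolution; alternative ids resolve transparently everywhere.

**Intrinsic information content.** Corpus-frequency IC would tie the scores
to a particular corpus, so term specificity is derived from the graph
itself: `p(c) = (desc(c) + 1) / N` per weakly connected component, and
`IC(c) = -log p(c)`. Counting *all* proper descendants (rather than direct
children) is the standard intrinsic reading and guarantees IC is
anti-monotone along every edge; the `+1` keeps leaf probabilities non-zero
so every non-root term has strictly positive IC. Direct-children counting
remains available (`mode = "children"`), as does the log base
(`logBase`, natural log by default — Resnik scales with it, simUI and
simGIC are invariant).

**Components.** ChEBI-like ontologies have several roots (Chemical Entity,
Role, Subatomic Particle). IC is normalised per component, and
cross-component pairs share no ancestors, so all three measures return 0
for them rather than failing — mixed annotations must not crash scoring.

**Similarity measures.** Resnik (IC of the most informative common
ancestor; MICA ties broken by smallest term id so results are
deterministic), simUI (Jaccard of reflexive ancestor sets) and simGIC
(IC-weighted Jaccard). Ancestor sets include the term itself, which makes
self-similarity maximal (1 for simUI/simGIC, IC(c) for Resnik). Resnik is
left unnormalised by default because thresholding is rank-based; a
normalised variant (divided by the component's maximum IC) is available
for users who want [0,1]-comparable scores. The simGIC 0/0 corner (two
zero-IC roots) is defined as 1 when the ancestor sets coincide and 0
otherwise, by continuity with the identical-set case.

**Validation score.** Within a window, each mention is compared with every
*other* mention; the score is the aggregate of those similarities — the
maximum by default ("is anything related here?"), with `mean` and
`top3_mean` as alternatives for contexts where a single lucky neighbour
should not suffice. Two deliberate choices:

* *Singleton windows score 0.* The method needs a related neighbour to
  express confidence; a lone mention provides no evidence either way, and 0
  sends it to the outliers unless the user thresholds at 0.
* *Repeated concepts count.* A concept mentioned twice in one window
  scores maximally against its twin — repetition is itself evidence of a
  genuine entity. `excludeSameConcept = TRUE` switches this off.

**Thresholding.** The absolute threshold is strict (`score > t`). The
fraction mode sidesteps boundary ties entirely: records are totally
ordered (score descending, then concept id, document id, start offset) and
exactly `round(f·N)` are validated — half-up rounding, implemented
explicitly since base R rounds half-to-even. This guarantees
`|validated| = round(f·N)` under any tie structure.

**Evaluation.** Gold-standard matching is exact: identical offsets and
identical canonical concept id; partial overlap never counts. Reported
quantities: precision and recall of the subset, the TP ratio (percentage
of the full set's true positives retained) and the precision increase
relative to the full set. The recall denominator is the gold entries over
the documents of the evaluated annotation set. The random-selection
reference — constant precision, TP ratio `100·f` — is emitted alongside
every validation curve, and `randomBaselineSimulation()` estimates it by
Monte Carlo (its expectation for `f = 0.75` is a 25% TP loss). Quantiles
in `scoreDistributionSummary()` are type-7 (linear interpolation).

## What the synthetic generator emulates

`generateToyOntology()` grows a rooted DAG top-down (each term attaches to
one uniform random predecessor, a second parent with probability
`multiParentProb`), which is acyclic by construction and loosely mimics an
ontology's broad-near-the-root shape. `generateCorpus()` emulates the
premise of the method: per window a seed term is drawn and the window's
true-positive mentions take concepts from the seed's sibling/descendant
neighbourhood (its parents' subtrees), while false positives are uniform
over the whole ontology — NER errors have no systematic semantic relation
to their context, which uniform sampling approximates. True positives are
entered into the gold standard with their exact offsets. An adverse mode
(`tpRelated = FALSE`) places mutually unrelated true mentions in a window,
the documented failure case of the method (mixture-listing sentences such
as excipient enumerations), where validation scores of genuine entities
are low.

Defaults are chosen to resemble a small but non-trivial corpus: 300 terms,
30 documents × 5 windows × 8 mentions (1,200 annotations), 45% true
positives. With 8 mentions per window the half-up rounding makes 4 of 8
mentions gold-backed, so the full-set precision of the default corpus is
50%.

What passing tests on this test-bed do **not** show: real NER error
distributions are not uniform (lookup errors are often *systematically*
related to context, e.g. a wrong salt form of the right compound), real
gold standards contain boundary disagreements that exact matching scores
as errors, and real window segmentation is noisy. The synthetic dominance
result (validated subsets beating random selection at every fraction) is a
property of the generator's construction and demonstrates the machinery,
not corpus-level performance.

## Numerical and design choices

* No randomness anywhere in parsing, scoring or thresholding; the only
  seeded components are the synthetic generator and the Monte-Carlo
  baseline, both taking explicit seeds and producing byte-identical
  outputs on reuse.
* Scores are serialised at 6 decimals in TSVs; in-memory comparisons use
  full precision.
* Unmapped concept ids abort scoring with the offending mention named;
  `skipUnmapped = TRUE` (CLI `--skip-unmapped`) drops them with a message
  instead, since upstream tools routinely emit identifiers from newer
  ontology releases.
* Window membership is never computed here — sentence segmentation belongs
  to the caller's NLP stack; the tool only groups by the provided
  `window_id` (or whole documents).
* Degenerate inputs: empty mention tables flow through scoring and return
  empty record sets; an empty validated subset yields an evaluation report
  with counts 0 and precision flagged undefined (`NA`); an empty ontology
  is rejected.

## Problem sizes

The test suite exercises the oracle equivalences on 200 random DAGs of up
to 50 terms (every term pair, all three measures against brute-force
set-based oracles), the end-to-end dominance property on the default
1,200-annotation synthetic corpus under all three measures, and the
Monte-Carlo baseline at 10,000 annotations × 1,000 replicates. These sizes
keep a full run within a few minutes on one CPU while leaving the
properties no room to pass by accident.

## Known limitations

* Only OBO 1.2 flat files are read; no OWL.
* Resnik/simGIC depend on the IC convention; published IC values for
  specific ChEBI releases are not bit-reproducible unless the same
  smoothing and log base are used.
* The method cannot validate a correct mention whose window contains
  nothing related (singletons, mixture listings) — such mentions need
  either a lower threshold or contextual cues outside this package's
  scope.
* Groupwise protein-style measures (best-match averages) and other
  pairwise measures (Lin, Jiang–Conrath, Wang) are out of scope.

## A compact end-to-end run

```{r example, eval = FALSE}
sp     <- syntheticSpec(nTerms = 120, nDocs = 8, seed = 7)
onto   <- generateToyOntology(sp)
corpus <- generateCorpus(sp, onto)
ic     <- computeIC(onto)
rec    <- scoreCorpus(corpus$mentions, onto, ic, measure = "simgic",
                      granularity = "window_field")
lab    <- labelExact(rec, corpus$gold, onto)
sel    <- thresholdForFraction(lab, 0.75)
evaluateSubset(sel$validated, lab, corpus$gold)
curve  <- validationCurve(lab, corpus$gold, nPoints = 20)
```
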