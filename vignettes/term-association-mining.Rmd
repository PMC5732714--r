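---
title: "Mining sentence-level term associations from abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining sentence-level term associations from abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooclink)
```

## The model

`cooclink` treats a co-mention of two ontology terms in one sentence of an
abstract as weak evidence of association, and aggregates that evidence over
a corpus. The pipeline is a chain of small, replaceable stages:

1. **Corpus** — abstracts from MEDLINE XML or JSONL, one document per
   article; a document's text is the space-joined concatenation of its
   abstract sections.
2. **Segmentation** — deterministic rule-based sentence splitting.
3. **Term recognition** — dictionary matching of ontology names and
   synonyms, leftmost-longest.
4. **Filtering** — sentences with fewer than two distinct recognized terms
   carry no pair evidence and are dropped.
5. **Counting** — binary occurrence per sentence/document; pair counts at
   both granularities.
6. **Scoring** — RSS over sentence counts, NMD over document counts.
7. **Validation** — correlation of scores against DAG-based (Wang) and
   gene-annotation similarity.
8. **Network** — thresholded association graph and its diagnostics.

The key modelling commitment is granularity: a sentence-level co-mention is
a much stronger signal than co-mention anywhere in an abstract, at the cost
of recall. Both granularities are counted — the sentence level drives RSS,
the document level drives NMD — so the two scores are not redundant.

## Scores and their behaviour

With `COV(t1, t2)` the number of sentences containing both terms and
`COV(t, t)` a term's own sentence count,

$$\mathrm{RSS}(t_1,t_2) = \log_{10}
  \frac{\mathrm{COV}(t_1,t_2)}{\mathrm{COV}(t_1,t_1)\,\mathrm{COV}(t_2,t_2)}$$

is a pointwise-mutual-information-style statistic: it rewards joint
occurrence and penalizes ubiquitous terms. Raw values are rescaled linearly
onto $[1, 100]$ over the table being scored
($\mathrm{RSS}_N = 1 + 99(\mathrm{RSS}-\mathrm{RSS}_{\min})/(\mathrm{RSS}_{\max}-\mathrm{RSS}_{\min})$).
Because the bounds are per-table, the normalization scope matters: scoring
DO pairs alone and scoring all pairs give different normalized values for
the same pair. The scope is therefore whatever pair set `score_all()` was
given, and the observed bounds are recorded in the table's metadata so any
table can be re-derived.

The Normalized MEDLINE Distance is the Normalized-Google-Distance form over
document counts $D_1$, $D_2$, $D_{12}$ in a corpus of $M$ documents:

$$\mathrm{NMD}(t_1,t_2) = \frac{\max(\log D_1,\log D_2) - \log D_{12}}
 {\log M - \min(\log D_1,\log D_2)}$$

All three counts enter through logarithms; the log base cancels. The
similarity transform is $\max(0, 1-\mathrm{NMD})$ — the bounded standard
choice; the raw distance is returned by `nmd()` so an alternative transform
is one function away. Pairs that never co-occur are *unscored* (`NA`,
excluded from tables) rather than pushed to $-\infty$: only extracted
co-occurring pairs are scored.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_token_length` (dictionary) | 3 characters | single-token surface forms shorter than this are dropped; guards against promiscuous labels such as "all" |
| `synonym_scopes` | all scopes | restrict to, e.g., `EXACT` synonyms |
| `min_cov` (scoring) | 1 sentence | minimum joint count for a pair to be scored |
| `w_isa` (Wang similarity) | 0.8 | per-edge semantic decay along `is_a`; the standard contribution factor |
| `threshold` (network) | e.g. 60 | minimum score for an edge, on the scale of the score method (RSS_N here); edges kept at `score >= threshold` |
| `n_replicates` (significance) | 10,000 | random G(n, m) networks for the giant-component test |
| `drop_iea`, `dedupe` (annotations) | `TRUE` | remove electronically inferred annotations and duplicate (term, gene) records |

## Numerical and procedural choices

**Sentence segmentation.** Rather than a learned model, segmentation is a
deterministic contract: split after `.`, `!` or `?` when followed by
whitespace and an uppercase letter or digit, or at end of text; never split
when a period closes a listed abbreviation ("e.g.", "et al.", "Fig.", ...)
or a single-uppercase-letter token, which protects species abbreviations
like "E. coli"; decimal points are never followed by whitespace and so
never split. The contract is idempotent, and joining a document's sentences
with single spaces reproduces its whitespace-collapsed text — both are
enforced as property tests.

**Matching.** Surface forms are normalized by lowercasing and splitting on
non-alphanumeric runs — no stemming, no plural folding, favouring precision.
Matching is leftmost-longest and non-overlapping over token windows, with
entries in a hashed token-sequence table; one surface form may map to
several term ids (no disambiguation is attempted — one mention per id is
emitted). The matcher is verified against a brute-force window-enumeration
oracle on random fixtures.

**Counting.** Occurrence is binary per sentence and per document: repeated
mentions count once. `M` counts every document read, including those
without recognized terms, since NMD's denominator depends on corpus size.
Pair keys are unordered and stored canonically (`t1 < t2`), making symmetry
structural.

**Wang similarity.** With a single edge type, the maximal product of decay
factors along paths from a term to an ancestor reduces to
$w^{d}$ with $d$ the shortest `is_a` path length, so S-values come from
shortest-path distances; similarity is the usual normalized sum of common
ancestors' contributions from both sides. Terms in disjoint components get
similarity 0; obsolete terms are refused.

**Gene-annotation similarity.** Cosine (default) or Jaccard overlap of
annotated gene sets, with annotations used as given (no up-propagation to
ancestors) since published annotation counts are direct per-term counts.
Jaccard never exceeds cosine; both are available for sensitivity.

**Giant-component significance.** The null model is G(n, m) with matched
node and edge counts — the simplest null consistent with "random networks";
degree-preserving rewiring is available behind `null_model = "rewire"` for
sensitivity analysis. The empirical p-value uses the add-one estimator
$(r+1)/(n+1)$, whose floor with 10,000 replicates is $1/10001$.

**Power-law diagnostic.** Ordinary least squares of $\log_{10} P(k)$ on
$\log_{10} k$ over degrees with nonzero counts. This is a descriptive
goodness-of-fit on the histogram (the conventional $R^2$-style report for
scale-free checks), deliberately not a maximum-likelihood exponent
estimate.

**Degenerate inputs.** A score table with a single distinct raw RSS value
normalizes to 100 everywhere with a warning; correlation requires at least
3 shared pairs and non-zero variance; NMD requires the corpus to exceed
every marginal document count; an empty dictionary or empty pair list is an
error or warning, never silence.

## The synthetic world

`generate_world()` builds, from one seed, a reproducible bundle emulating
the pipeline's real inputs: per-namespace random `is_a` DAGs with
multi-token names and synonyms, a gene-annotation table, and a corpus of
short abstracts. Its defaults — 2 namespaces x 20 terms, 500 documents of
5 sentences, background mention rate 0.02 per term per sentence, planted
co-mention probability scale 0.3, 8 term-disjoint planted pairs per
namespace, 100 genes with 8 per term, coupling 0.8 — are the package's
fixed study conditions for the end-to-end tests.

Three couplings give the world recoverable structure:

* every within-namespace pair is co-mentioned per document with probability
  `planted_prob * weight^2`, where `weight` is the pair's Wang similarity
  (damped by 0.5 for background pairs, floored at 0.6 for planted ones) —
  so co-mention intensity tracks DAG proximity, with planted pairs clearly
  elevated above the proximity background;
* gene sets are inherited along the DAG (a child keeps each parental gene
  with probability 0.6), so annotation overlap also decays with DAG
  distance, and planted pairs are additionally forced to share
  `round(coupling * weight * genes_per_term)` genes;
* solo mentions top every term up to the busiest term's expected pair
  activity, so marginal frequencies are comparable across terms and score
  differences reflect joint counts rather than marginal imbalance.

Term tokens are four-letter pseudo-words drawn without replacement from a
fixed pool (so surfaces never collide and multi-token matching is
exercised); filler words are English function words chosen to be
un-generatable by the pseudo-word scheme, so they can never shadow a term.

What the world does *not* emulate: linguistically realistic prose,
ambiguous or nested surface forms shared between terms, obsolete-term noise
in corpora, MeSH-style indexing effects, or the heavy-tailed term-frequency
distributions of real PubMed. Passing tests on this world therefore
demonstrate that the machinery recovers planted signal under controlled
conditions — not that real-corpus correlations will have any particular
magnitude. Published full-scale correlation magnitudes depend on the corpus
snapshot and ontology versions and are deliberately out of scope here.

Problem sizes used in the test suite are desk-scale by design: worlds of
10–20 terms per namespace and 30–500 documents, 50 random corpora of at
most 200 sentences for the counting oracle, 100 random fixtures for the
matcher oracle, and 10,000 network replicates only where the significance
floor itself is under test.

## Known limitations

* The matcher does no approximate matching, abbreviation expansion or
  disambiguation; precision is favoured over recall, as is conventional for
  dictionary-based recognizers.
* RSS normalization is relative to the scored table, so normalized scores
  are not comparable across runs with different pair sets (raw RSS is).
* The rule-based segmenter will split wrongly on unlisted abbreviations
  followed by capitalized words; the abbreviation list is user-extensible.
* The power-law fit is descriptive; use a likelihood-based estimator for
  inferential claims about degree exponents.
* Network node counts are defined over edge-incident terms only; isolated
  terms are absent by construction.
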