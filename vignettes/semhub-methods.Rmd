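---
title: "Methods: mining drug adverse-event signals from text and knowledge graphs"
author: "semhub authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining drug adverse-event signals from text and knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semhub)
```

## The problem

Newer targeted drugs — the motivating case is tyrosine kinase inhibitors
(TKIs) taken indefinitely by chronic myeloid leukemia (CML) patients — lack
the long-horizon cohort studies needed to characterize rare, delayed or
under-reported adverse events (AEs). `semhub` implements two complementary
text-mining strategies for this situation:

1. **Corpus arm.** Within the disease-specific literature, cluster abstracts
   and read off which AE terms are over-represented in each drug's cluster.
2. **Knowledge-graph arm.** Across a much larger predication graph
   (subject–PREDICATE–object triples extracted from biomedical text, typed
   with UMLS-style semantic codes), rank candidate conditions by metapath
   relevance to a target concept, propose unpublished links with a
   translational embedding, and extend reach through *hub-node
   neighborhoods* so that conditions two or more hops from the target can
   still be found and ranked.

Both arms are exercised end to end against synthetic data with planted
ground truth (`gen_corpus()`, `gen_kg()`), so the whole pipeline is testable
without any external download.

## Corpus arm

### Preprocessing and vectorization

Abstracts are lowercased, split on non-alphanumerics, stripped of a fixed
English stopword list (shipped, overridable) and lemmatized with the
package's pinned rule set (`semhub-rules v1`): an irregular-plural table
plus three suffix rules. The rule set deliberately only normalizes noun
plurals — verb inflections are left alone — because AE vocabulary is
noun-dominated and an aggressive stemmer would merge clinically distinct
terms. The lemmatizer identity is recorded on the output so processed
corpora are self-describing.

`build_tfidf()` keeps terms whose document frequency lies in the inclusive
band [`min_df`, `max_df`] = [0.01, 0.85] by default: terms in fewer than 1%
of documents are too rare to compare across clusters, terms in more than
85% carry no contrast. Weights are raw counts times the smoothed inverse
document frequency `ln((1 + N) / (1 + df)) + 1`, with L2 row normalization,
stated explicitly so toy corpora can be checked by hand to 1e-9. Columns
are lexicographic, so the matrix is bit-reproducible.

### Reduction, clustering, profiling

`reduce_dimensions()` is an exact truncated SVD (default 50 components)
with a fixed sign convention, so identical inputs give identical outputs
regardless of seed; requesting more components than `min(docs, terms)` is
an error rather than a silent clamp. `cluster_docs()` runs k-means with 10
restarts under an explicit seed; `k` defaults to 30, the working
granularity appropriate for a few thousand abstracts, but is a free
parameter — there is no selection criterion built in, and the synthetic
recovery tests use `k` equal to the number of planted drugs.

Cluster→drug mapping uses in-cluster document frequency of the drug terms;
ties are reported and flagged ambiguous, never resolved silently. AE-term
profiles are *document-level presence fractions* (a term counts once per
abstract), which is also the interpretation under which fold changes
(cluster frequency over corpus frequency) are comparable across terms.
Pairwise cluster comparisons use Pearson's chi-square of independence on
the AE-term × cluster presence-count table, with no continuity correction
(so the closed form `sum((O - E)^2 / E)` is exact), and a Bonferroni-
corrected alpha `0.05 / choose(m, 2)`. The contingency construction
(document counts, not token counts) is an interpretation the package fixes
and documents, since either reading is defensible; term rows with zero
counts in both clusters are dropped with a warning.

The optional `embed_2d()` is a deterministic projection onto the two
leading principal axes of the reduced matrix — a linear view meant only for
plotting cluster structure, not a neighborhood-preserving embedding.

## Knowledge-graph arm

### Graph model

`knowledge_graph()` stores typed nodes (opaque concept id as identity,
display name, semantic-type code) and directed predication edges with
positive occurrence-count weights; duplicate triples merge by summing.
Generic concepts ("protein", "disease", ...) whose connectivity is a
granularity artifact are removed by `kg_remove_generic()` before any
ranking; the shipped stoplist is user-extensible.

### Metapath relevance (HeteSim form)

Relevance between a source `s` and target `t` is computed over *length-2
schema metapaths*: a typed step from `s` into a middle layer and a typed
step from the middle layer to `t`. For one metapath the similarity is the
cosine between the forward transition-probability vector of `s` and the
backward transition-probability vector of `t` over the middle nodes — the
standard meeting-probability construction for even-length metapaths, which
is invariant to uniform edge-weight rescaling. `mean_hetesim()` averages
over every metapath on which both endpoints have support; a pair with no
supported metapath is *unranked*, not scored zero, because zero means
"maximally dissimilar" while absence means "no evidence".

Reported scores follow the lower-is-stronger convention: `score = 1 -
similarity`, with both values exposed. The novelty score divides similarity
by `1 + ln(1 + w)` where `w` is the node's total weighted degree — a
monotone literature-volume discount of the package's own design (only its
qualitative behaviour, relevance discounted by publication volume, is
externally specified), so under-published but relevant nodes surface when
ordering by novelty.

Two aggregation choices were genuinely open and are fixed as follows.
Multi-target relevance is the arithmetic mean across targets with at least
one supported metapath. Self-pairs (a candidate that is itself in the
target set) are excluded from that mean: a node trivially resembles
itself, and hub simulations routinely place disease nodes in the target
set, so counting self-similarity would inflate exactly the candidates the
simulation is meant to test. Longer metapaths are deliberately out of
scope — hub neighborhoods, not path length, are the mechanism for reaching
distant nodes.

### Link prediction (TransE)

`train_transe()` learns entity and relation vectors such that `h + r ≈ t`
for observed triples, by mini-batch SGD on the margin-ranking loss with one
uniformly corrupted negative per positive and entity renormalization each
epoch. Defaults (`dim = 32`, `margin = 1`, `lr = 0.05`, 100 epochs) are
sized for graphs of a few hundred entities and recorded in the model.
Training is bitwise deterministic per seed. `predict_entities()` ranks
unobserved tails (filtered setting: the head and already-observed tails are
excluded) of the five entity types and six predicates used for AE
prediction, and attaches a degree-normalized strength
`exp(-distance) / (1 + ln(1 + deg(tail)))`, min-max rescaled per candidate
list. The exponential-distance/log-degree form is the package's concrete
realization of "degree-normalized predicted strength": bounded, strictly
decreasing in both distance and tail publication volume, so hub
neighborhoods are not swamped by promiscuous high-degree concepts. A
single-candidate list normalizes to 1 (the sole candidate is the best
available).

### Hub-node network analysis

`select_hubs()` intersects the two anchor concepts' neighborhoods and keeps
the `n = 6` highest weighted-degree members. Per hub,
`build_hub_neighborhood()` unions entity predictions over the six
predicates, deduplicates keeping each node's best weight, and caps the
neighborhood (default 25). `run_hub_simulation()` then ranks disease
candidates against the focal concept plus the neighborhood, min-max
normalizing scores to [0, 1] per simulation (lower still stronger; a
single-candidate or all-tied simulation normalizes to 0, the conservative
"strongest" choice, which is logged by documentation here rather than
guessed silently).

`aggregate_hub_sims()` combines simulations by `composite =
occurrence_rate × (1 - mean_score)`. The two stated ingredients are the
occurrence rate and the normalized scores; their combination was open, and
this product is the simplest form that is bounded in [0, 1], increasing in
prevalence across hubs, increasing in per-hub strength, and exactly 1 only
for a candidate present in every simulation at the strongest score.
`assign_tiers()` cuts the ranking at the top 1% / 5% / 10% using ceilings,
so no tier is empty for any N ≥ 1 (for tiny N the nested tiers collapse
onto the top ranks). Foci labels are applied from a curated two-column
file — automating foci discovery would misrepresent a step that is
ontology- and human-curated — and `export_curation_template()` /
`read_curation_template()` provide the agrees/disagrees/missing
human-in-the-loop review loop as a strict-validation table.

## What the synthetic data emulates — and what it does not

`gen_corpus()` draws each abstract's tokens from a mixture of a Zipf-like
background multinomial and AE terms boosted by `enrichment` (default 5)
for the abstract's own drug; each abstract carries `1 + Poisson(2)` copies
of its drug name, reflecting repeated title/body mentions in drug-focused
papers. At `enrichment = 1` AE terms are independent of the drug label,
giving an exact null for the chi-square machinery. The default corpus is
5 drugs × 50 abstracts with 10 AE terms per drug drawn from realistic
clinical vocabulary (chosen to be fixed points of the lemmatizer so planted
truth survives preprocessing).

`gen_kg()` builds: two anchors (disease and kinase); six hub disease nodes
linked heavily to both anchors; a 12-member community per hub with a
4-member densely co-cited core (every member cites each core member; the
kinase anchor cites all cores) and a characteristic predicate per
community, which is what makes held-out community edges learnable by the
translational embedding; ten planted "relevant" disease nodes citing the
cores of the communities, hence sharing middle-layer neighbors with
community members across all hubs (relevance that is *mutual* across hub
neighborhoods is precisely what the aggregation rewards); two low-degree
decoy shared neighbors; and background nodes with Poisson-distributed
random links (mean 3 for disease nodes — very sparse one-link nodes would
produce degenerate one-hot cosine artifacts no real multi-predication
concept exhibits). Edge weights are `1 + Geometric(0.5)`, echoing the
skew of literature co-occurrence counts.

What passing tests on these generators shows: the pipeline's machinery —
vectorization, clustering, statistics, metapath scoring, embedding
training, aggregation, tiering — recovers planted structure of the kind
the method assumes, at desk scale. What it does not show: performance on
real text (ambiguity, synonymy, negation, section structure), on a
SemMedDB-scale graph (tens of millions of predications; this implementation
is exact, not approximate, and scales to thousands of nodes), or the
correctness of any specific clinical conclusion. Corpus-dependent numbers
from any particular study (vocabulary sizes, specific condition rankings)
are not reproduction targets.

## Numerical choices and degenerate inputs

* All stochastic steps take an explicit integer seed; exact SVD and the
  2D projection are deterministic by construction (sign fixed by the
  largest loading).
* Ordering ties break lexicographically by term or node id everywhere, so
  every ranking is total and reproducible.
* Empty abstracts are skipped with a warning; an empty vocabulary after
  document-frequency filtering is an error naming the bounds; an empty
  cluster yields an empty term list with a warning; a chi-square pair with
  a degenerate table returns `NA` rather than a fabricated statistic.
* `evaluate_hits()` (filtered hits@k) refuses held-out sets that overlap
  the training edges.
* Problem sizes used by the test-suite and the acceptance script — corpora
  of 250 abstracts, graphs of ~340 nodes (200 disease nodes), 10 seeds per
  stochastic claim, 100 random graphs against the exhaustive metapath
  oracle — were chosen as the smallest scales at which the planted
  structure is unambiguous.

## Known limitations

* The rule lemmatizer under-normalizes heavily inflected text; swapping in
  a full lemmatizer only requires reproducing the `preprocess_abstract()`
  contract.
* HeteSim is restricted to length-2 metapaths by design; relevance beyond
  two hops is reachable only through hub neighborhoods.
* The novelty and composite formulas are reasoned conventions, not
  externally validated estimators; both underlying ingredients are always
  reported alongside.
* TransE cannot model symmetric or one-to-many relations well; for the
  six causal/temporal predicates used here that limitation is acceptable,
  and alternative embedding models are out of scope.
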