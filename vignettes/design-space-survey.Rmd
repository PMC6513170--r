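---
title: "Surveying a visualization design space: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying a visualization design space: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gevit)
```

# The problem

Research communities develop characteristic habits in how they visualize
data, but those habits are hard to see without a systematic survey. This
package implements such a survey as two connected phases. A
*literature-analysis* phase derives the **why** of visualizations: it
clusters a corpus of article titles and abstracts into topics, links
articles to analyst-defined *a priori* concepts, and draws a stratified
sample of articles for manual figure coding. A *visualization-analysis*
phase supplies the **how**: a machine-readable typology of chart types,
chart combinations and chart enhancements, validation of human figure
annotations against it, descriptive statistics of the resulting design
space, and a static gallery for exploring it. The package targets
infectious-disease genomic epidemiology — its bundled concept vocabulary
and typology come from that domain — but every stage is parameterized and
the schema is extensible by overlay.

# The literature-analysis model

## Document term matrix

Titles and abstracts are lowercased, stripped of punctuation and
standalone numbers, filtered against the bundled Snowball-style English
stop-word list, reduced to tokens of at least three characters and
Porter-stemmed (`preprocessText()`). The stemmer is implemented in the
package because no stemming library ships with the target runtime; it
follows the classic 1980 algorithm with the author's later `bli`→`ble`
and `logi`→`log` revisions, and its output matches the truncated forms
that surface in automatic cluster names ("viru", "genom", "sequenc").

The document–term matrix stores raw counts and tf-idf weights

$$w_{dt} = \mathrm{tf}_{dt} \cdot \ln\frac{N}{\mathrm{df}_t},$$

with raw-count tf and no smoothing. This variant was chosen because the
upstream description fixes only "tf-idf", and the unsmoothed form has the
cleanest testable consequence: a term present in every document carries
weight exactly zero. Terms occurring in fewer than `min_df = 2` documents
are dropped by default; singleton terms add noise to the embedding
without affecting any downstream statistic. MeSH terms are excluded from
the matrix by default (topics are derived from titles and abstracts);
`include_mesh = TRUE` restores them.

A separate bigram index is built over lowercased, stop-word-filtered but
*unstemmed* adjacent token pairs. Bigrams are used only to link articles
to a priori concepts, and the concept-mapping workflow is manual, so the
human-readable surface form ("vancomycin resistance") must be preserved.

## Embedding and clustering

The tf-idf matrix is embedded in 2-D with Barnes–Hut t-SNE at perplexity
100 (the established setting for corpora of this size; it is lowered
automatically with a warning when the corpus has fewer than
`3·perplexity + 1` documents) and otherwise default parameters of the
underlying implementation. Two numerical choices matter for
reproducibility:

* the initial layout is drawn from the seeded RNG and passed to the
  backend explicitly, with a single compute thread — in this build the
  Barnes–Hut backend is only bit-reproducible under an explicit
  initialization;
* every stochastic operation takes a `seed` argument (default 42) and
  restores the caller's RNG state afterwards.

Density clustering runs on the t-SNE coordinates with HDBSCAN.
No HDBSCAN implementation is available in the target runtime, so the
package carries its own: mutual-reachability distances with the core
distance at the `minPts`-th neighbour (the point itself included), an
exact Prim minimum spanning tree, single linkage, tree condensation at
minimum cluster size `minPts`, and excess-of-mass cluster selection with
single-cluster solutions disallowed. `min samples` is tied to `minPts`,
the classical single-parameter form. The implementation is validated in
the test suite against a frozen labeling from an independent reference
implementation on a fixed fixture (exact agreement, including the noise
set) and on planted-blob recovery. It is O(n²) in time and memory, which
is ample for embeddings of a few thousand documents; it is not intended
for raw high-dimensional data.

## The stability sweep and consolidation

Cluster composition is sensitive to `minPts`, so the pipeline sweeps the
ladder 50, 75, 100, 125, 150, 250, 500, 1000 and keeps every labeling.
Documents that are noise under *every* setting are "never-clustered";
documents that merely fall out of the final settings are
"currently-unclustered". The final labeling combines the minPts 75 and
150 results. How the two settings were originally combined is not
specified anywhere, so the package defines a deterministic rule and
records it per cluster:

1. a document clustered at the primary (fine) setting keeps that cluster;
2. otherwise, a document clustered at the secondary (coarse) setting is
   assigned its secondary cluster, namespaced after the primary ids;
3. otherwise it is currently-unclustered, or never-clustered if it was
   noise throughout the sweep.

This preserves the fine structure of the primary setting while rescuing
documents only the coarser setting captures, and the three categories
provably partition the corpus (a validity invariant of the class).
Clusters are named by their two most frequent terms (summed raw counts
over member documents, hyphen-joined, ties broken lexicographically,
duplicate names disambiguated with a numeric suffix).

## Cluster validation, simplification and concept linking

`matchExternalVocabulary()` scans raw title+abstract text for
case-insensitive whole-phrase occurrences of an external controlled
vocabulary (e.g. human pathogen names) and tallies matches per cluster;
terms below 40 total matching articles are dropped by default. Matching
is done on unstemmed text because pathogen names are multi-word proper
nouns that stemming would corrupt. `simplifyClusters()` retains clusters
with at least 100 documents under their names and pools the remainder
into a single "other" cluster, conserving document counts.

Candidate concept bigrams must occur in at least 10 articles within some
cluster and be present in at least 10% of the *other* clusters. The
second clause is ambiguous in prose (mere presence versus a repeated
10-article requirement); the package reads it as presence
(document frequency ≥ 1) in at least `ceiling(0.10 · (C − 1))` other
clusters, because the sentence contrasts a strong within-cluster count
with mere spread across clusters. Both thresholds are exposed
(`min_within`, `min_between_frac`) and the filter is provably monotone in
both. Bigram→concept assignment itself stays manual: the bundled map
contains only the documented exemplar ("vancomycin resistance" → "drug
resistance") plus whatever the analyst loads, and unmapped candidates are
reported for curation rather than guessed.

The bundled a priori vocabulary has 23 concepts in three groups. The
enumerated prose yields 22 when the three outbreak levels replace the
plain "outbreaks" entry, contradicting the stated total of 23 with 11
epidemiology concepts; the package resolves this by shipping a general
"outbreaks" concept alongside the three level-specific variants.

## Stratified sampling

Strata are the populated (cluster × concept) cells. One document is drawn
uniformly per stratum; draws are deterministic per seed, and the entire
event log (draws, human accept/reject decisions with controlled reason
codes, replacement candidates) serializes and replays exactly. Documents
carrying several concepts are eligible for several strata — concepts are
tags, not a partition. A fresh draw enters the log with status
"pending" rather than "accepted": the tool never auto-accepts or
auto-rejects, and the accepted/rejected statuses are reserved for the
recorded human decision. After a rejection, two replacement candidates
are drawn without replacement from the stratum's remaining documents.
A second round can require publication year ≥ 2011 (documents with a
missing year are excluded from year-constrained rounds) and orders strata
so that concepts under-represented among round-1 acceptances come first —
the under-representation intent is operationalized as a priority
ordering, not a hard constraint.

# The typology and design-space analytics

The bundled schema carries eight chart classes, the chart types the
domain survey documents explicitly (with special cases such as epidemic
curve ← bar chart and gel image ← image), exactly six combination
categories, the mark vocabulary (connection as a specialized line mark,
containment as a specialized area mark, the pie chart as the only bundled
glyph), four aesthetics, and the enhancement vocabularies. The complete
published 23-type inventory is not recoverable from text alone, so the
schema deliberately ships only documented types and is completed through
the strictly additive overlay mechanism — an overlay may add codes but
never redefine or remove a core one. Axis text, titles and data labels
are never coded as marks.

Two classification helpers encode the published decision rules.
`classifyCombination()` resolves a figure-structure descriptor in the
order Single → Small Multiples → Composite → Many Types Linked → Many
Types General, classifies figures where two categories apply as Complex
Combination (recording the two constituents), and resolves an ambiguous
linked-versus-general distinction in favor of Many Types General.
`classifyEnhancement()` distinguishes structured enhancements from
one-off annotations and resolves ambiguity as structured. Both rules are
checked in the tests against an independently written rule table over the
full descriptor lattice.

`computeStats()` reports every percentage together with the count it was
computed from, under explicitly distinguished denominators: chart-type
*instance share* is over all chart instances, *presence* is over figures
(so a class can be present in more figures than any member type's
instance share suggests), the combination distribution is over figures
and provably sums to 100%, and enhancement rates are over chart
instances. `crosstabWhyHow()` crosses the why axis (topic or concept)
with the how axis (chart type or combination), with margins conserved
against the univariate counts. `exportGallery()` emits a sorted
line-delimited index plus standalone hypertext pages with client-side
facet filters; output is byte-deterministic, missing image assets degrade
to metadata-only cards, and the subjective quality tags are surfaced as
facets but never computed.

# The synthetic world

`generateCorpus()` emulates exactly the statistical structure the
pipeline assumes, no more: K topics with disjoint pseudo-word
vocabularies over a shared background, tokens drawn from a two-component
mixture (topic weight 0.7), geometric abstract lengths with mean 120
tokens, 10% pure-background noise documents, and planted concept-linked
bigrams inserted to hit their within-topic counts and cross-topic spread
exactly. Defaults (K = 5, 200 documents per topic, 30-term topic
vocabularies, 120-term background) are the package's stated test world.
Pseudo-words are deterministic consonant-vowel strings with unique
Porter stems, filtered against the stop-word list, so preprocessing is
exercised without being confounded. What the generator does *not*
emulate: real English, correlated topics, MeSH metadata, or documents
whose topical signal lives in syntax rather than vocabulary. A green
topic-recovery test therefore establishes that the pipeline recovers
term-distinct topics (adjusted Rand index ≥ 0.8 on the stated world), not
that it would recover any particular real corpus's structure.

`generateAnnotations()` draws i.i.d. schema-valid annotations with known
category probabilities. Combination categories follow the supplied
probabilities exactly, one draw per figure; the realistic preset uses the
observed field frequencies (Single 0.401, Composite 0.203, Small
Multiples 0.173, Many Types Linked 0.135, Many Types General 0.088) as
generator *inputs*. Each instance independently receives an add-marks
enhancement, a re-encoding, and/or a one-off annotation, so the expected
"any-enhancement" and "add-marks" rates are derived unions of those
Bernoulli probabilities. One subtlety matters for the frequency-recovery
check: a Small Multiples figure repeats a single chart-type draw across
its instances, so chart-type instance shares are cluster-inflated
relative to an i.i.d. binomial; the acceptance check therefore uses the
number of figures, not instances, as the conservative binomial
denominator for chart-type shares, while combination shares and
enhancement rates use their exact denominators.

# Reproducibility and the command line

Every stage is callable from `gevitCLI()` (or the installed `gevit`
script): `simulate`, `ingest`, `dtm`, `cluster`, `validate-clusters`,
`link-concepts`, `sample`, `annotate-validate`, `stats`, `gallery`.
Each stage reads prior-stage artifacts by path, fails with a "run stage X
first" diagnostic when one is missing, and writes a manifest with its
parameters, seed and MD5 digests of all inputs and outputs. Artifacts are
plain text (line-delimited records and tagged JSON); doubles are
serialized at 17 significant digits so every artifact round-trips
bit-exactly, and identical commands produce byte-identical artifacts and
digests. The two historical literature-search query strings are shipped
as documented constants (`pubmedQueries()`); the package performs no live
querying.

# Known limitations

* The headline corpus-scale results of the original survey (tens of
  thousands of articles, 32 clusters, a 770-figure coded corpus and its
  frequency table) require the original corpus and manual coding and are
  not reproducible here; the package reproduces the *method* and verifies
  it on synthetic ground truth.
* The in-house HDBSCAN is exact but quadratic; embeddings beyond ~10⁴
  points would need an indexed implementation.
* Language detection is out of scope; "not-English" is a human rejection
  code, not a computed one.
* The bundled concept map is intentionally minimal; concept linking at
  scale requires the analyst's curated map.
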