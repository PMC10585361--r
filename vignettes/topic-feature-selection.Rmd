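---
title: "Topic-based feature selection for short-text classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic-based feature selection for short-text classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmtopics)
```

## The problem

Short texts — article titles, abstracts of a few sentences, social-media
posts — defeat ordinary bag-of-words classifiers because each document
contains only a handful of terms: the document-term matrix is extremely
sparse, word co-occurrence statistics are unreliable, and most features are
irrelevant to any one document. `gsmtopics` implements a
grouping–scoring–modeling (G-S-M) strategy for this setting: group words
into topics with a topic model suited to short texts, score each topic by
how well its words alone separate the two classes, and build the final
classifier from the accumulated top-ranked topics, optionally fused with
each document's topic-distribution vector.

## The topic model

The grouping step uses a Dirichlet-multinomial mixture (DMM): every
document is generated by exactly one latent topic, in contrast to LDA's
per-word topic admixture. The one-topic-per-document assumption is the
standard response to short-text sparsity — a title simply does not contain
enough words to estimate a per-document topic mixture.

The sampler (`fit_gsdmm()`) is the collapsed Gibbs sampler for this model
(GSDMM). With symmetric priors $\alpha$ on the $K$ mixture weights and
$\beta$ on the $V$-dimensional topic-word distributions, the collapsed
conditional for reassigning document $d$ is

$$
p(z_d = k \mid \mathbf{z}_{-d}, \mathbf{w}) \;\propto\;
(m_k^{-d} + \alpha)\,
\frac{\prod_{w \in d}\prod_{j=1}^{c_{dw}} \left(n_{kw}^{-d} + \beta + j - 1\right)}
     {\prod_{i=1}^{N_d} \left(n_k^{-d} + V\beta + i - 1\right)},
$$

where $m_k$ counts documents in cluster $k$, $n_{kw}$ tokens of word $w$ in
cluster $k$, $n_k$ all tokens in cluster $k$, and the $-d$ superscript means
the document's own counts are removed first. The products are evaluated in
log space (sums of `log`, with a max-subtraction before exponentiation);
document lengths around 8 tokens make the direct product underflow-prone
but the log-space form exact to machine precision. Sweeps visit documents
in index order for reproducibility; the final-sweep state is the point
estimate (no burn-in discard or averaging), so a fit is a deterministic
function of the seed.

Two byproducts feed the selector:

* **TW**, the topic–word matrix: per topic, the posterior-mean word
  probabilities $\phi_{kw} = (n_{kw} + \beta)/(n_k + V\beta)$, truncated to
  the top $m$ terms (ties broken by vocabulary index; an empty cluster is
  uniform, $1/V$).
* **TD**, the document–topic matrix: the normalized collapsed conditional
  evaluated per document. The one-topic-per-document model has no intrinsic
  soft TD, so the package uses the posterior probability vector rather than
  a one-hot assignment — it is the model's own measure of "proportion of
  each topic present", and it degrades gracefully for ambiguous documents.
  For training documents the document's own counts are removed first
  (`held_in = TRUE`), which avoids the self-reinforcement of scoring a
  document against statistics it dominates; unseen documents are scored
  against the counts as they stand.

Externally trained topic models (biterm, pseudo-document and word-network
models, etc.) can be used instead of the native sampler through
`import_topic_artifacts()`, which reads the same two byproducts from text
files.

## Validating the sampler

`gsdmm_exact_posterior()` enumerates all $K^D$ assignments of a miniature
corpus and computes the exact posterior from the Dirichlet-multinomial
marginal likelihood — an independent brute-force oracle.
`validate_sampler_exactness()` compares the sampler's empirical assignment
distribution against it by total variation distance.

One subtlety is essential: the mixture likelihood is invariant under
permutation of cluster labels, so the assignment posterior is only
identified up to label permutation, and a finite chain visits the $K!$
mirror modes unevenly — with $\beta = 0.01$ a 20,000-sweep chain often
stays in one mirror mode throughout, which would dominate a naive total
variation even though the sampler is targeting exactly the right
distribution (the naive distance does shrink toward zero with chain
length). The comparison is therefore taken over label-permutation
equivalence classes (for $K = 2$, each assignment folded with its
complement). Folded total variation isolates sampler correctness from
label-switching frequency; on the default 20-corpus suite it is about two
orders of magnitude below the naive figure.

## Scoring, ranking, accumulating

For each topic the **G** step slices the training bag-of-words down to the
topic's terms (`build_topic_subdatasets()`); the **S** step runs stratified
5-fold cross-validation of a random forest on that slice and scores the
topic by mean fold accuracy (`score_topic()`; AUC is available as an
alternative criterion). Topics whose terms all fell out of the training
vocabulary are scored as the majority-class proportion rather than dropped,
so ranks always form a permutation. Ranking is by score descending with
topic-id tie-break. Sub-dataset columns are put in a canonical order before
fitting so a topic's score cannot depend on term layout.

The **C** step accumulates: for $i = 1 \dots r$ the union of the top-$i$
topics' terms (ranked traversal order, duplicates dropped — so term sets
are nested in $i$) forms the feature set $C_i$; in fused mode the $K$ TD
columns are appended. The **M** step trains the final random forest on each
$C_i$ and evaluates it on test documents projected into the training
feature space (unseen terms ignored; test TD rows from the collapsed
posterior with full counts).

## The evaluation protocol

`run_pipeline()` wraps the whole procedure in stratified Monte-Carlo
cross-validation: by default 10 independent 90/10 splits, per-class
training counts rounded per class. Within each repetition the vocabulary
and the topic model are fitted on the training split only, so no test
information can reach any stage; a `fit_on_full_corpus` flag reproduces the
simpler protocol that fits the topic model once on everything, which is
common practice but leaks unlabeled test text into the topic model.
Metrics (accuracy, recall, specificity, precision, F1, rank-based AUC with
half credit for ties, Cohen's kappa) are averaged per accumulation level
into the performance table; ratios with zero denominators are reported as
0 and flagged rather than propagated as NaN.

`select_best_subset()` picks the level maximizing a chosen criterion
(default F1), preferring fewer topics on ties. Note the performance table
is computed on the evaluation splits themselves, so the maximum over
levels is an optimistic estimate; honest selection of the operating point
requires a nested or held-out validation split. The package reports the
full table precisely so that this choice stays visible.

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| topics $K$ | 20 | standard operating point for title-length corpora |
| words per topic $m$ | 20 | keeps each sub-dataset low-dimensional |
| $\alpha$ | 0.1 | weak preference for balanced clusters |
| $\beta$ | 0.01 | sparse topic-word distributions for short texts |
| Gibbs sweeps | 1,000 | comfortable convergence at these sizes |
| MCCV | 10 × 90/10, stratified | stable means on 2,000-document corpora |
| internal CV | stratified 5-fold | cheap, standard; seeded per (run, topic) |
| scorer / final model | random forest, 100 trees | robust on small sparse slices; seeded, single-threaded for bit reproducibility |
| min corpus frequency | 20 (words-only) / 1 (fused) | rare-term cutoff helps a lexical-only model; the fused model benefits from keeping every term |

The frequency cutoff counts total corpus term occurrences by default;
"occurrences in how many documents" is a defensible alternative reading
and is available as `freq_count = "document"`.

Preprocessing follows the conventional normalization chain for biomedical
titles: case folding, replacement of every non-alphabetic character with a
space, whitespace tokenization, removal of tokens shorter than three
characters and of stopwords, then Snowball (Porter2) stemming, implemented
natively in `snowball_stem()`. The length filter applies before stemming,
so stems that come out short ("agre") survive. Relative term frequencies
divide by the document's in-vocabulary token count, so every non-empty row
sums to exactly 1 even after vocabulary filtering; dividing by the raw
length instead is available as an option.

## The synthetic generator

`generate_dmm_corpus()` samples from the DMM itself with class-linked
topics: class from a Bernoulli prior, topic from a class-conditional topic
distribution, length from a Poisson truncated at one (mean 8, matching
title-length statistics), tokens i.i.d. from the topic's word
distribution. `make_separable_preset()` fixes the test-bed used throughout
the test suite: 2,000 documents, 6 topics over 600 terms with disjoint
per-topic vocabularies; topics 1–2 occur only under class 0 and topics 3–4
only under class 1 (mass 0.45 each within their class), topics 5–6 are
shared noise (mass 0.05 each under both classes). The Bayes error is half
the shared mass, so near-perfect classification is attainable and any
leakage is visible against a label-permutation null. A `realistic` mode
wraps the synthetic terms in stopwords, digits, punctuation and random
capitalization so the full preprocessing chain is exercised end to end.

What the generator does *not* emulate: Zipfian word frequencies, topic
vocabularies that overlap, polysemy, correlated term usage within a
document, or class imbalance beyond the Bernoulli prior. Passing tests on
this corpus therefore demonstrate that the machinery is correct and that
the pipeline recovers planted structure without leaking labels — not that
any particular performance level transfers to real corpora.

One consequence deserves emphasis: because every token is drawn from the
document's single topic, the fitted document-topic vector is a
deterministic function of the document's words, so on this corpus the
fused (words + TD) mode carries no information that the words alone do
not. Its only systematic edge over the words-only mode is that the latter
applies the frequency cutoff and loses rare terms; the measured gap
between the two modes is accordingly within Monte-Carlo noise (on the
order of one F1 point either way, depending on seed). The situation on
real corpora, where topic distributions summarize corpus-level
co-occurrence that individual short documents cannot express, is exactly
what this generator cannot reproduce.

A consequence worth stating explicitly, because it bounds what topic
scores can reach on the preset: a topic's sub-dataset carries information
only for documents that contain the topic's words. Under
one-topic-per-document generation with disjoint vocabularies, a topic
covering a fraction $p$ of its class makes all other rows identically
zero, so the Bayes accuracy of its sub-dataset is $p/2 + 1/2$. With two
exclusive topics sharing a class ($p = 0.45$ each) the ceiling is about
0.725 per topic — well above the 0.5 of the shared-noise topics, which is
what the ranking needs, but no scoring rule can push a single topic's
accuracy toward 1 on this design.

## Numerical and degenerate-input choices

* Collapsed conditionals and the enumeration oracle both work in
  log-gamma space; the sampler's inner loop uses plain log sums (token
  counts are tiny).
* Documents with no in-vocabulary tokens: assigned by the cluster-size
  prior, with a warning; their BOW rows are all zero and their TD rows are
  the normalized prior.
* Empty clusters are allowed to empty and repopulate naturally; no
  resurrection heuristic.
* All randomness flows from one master seed through a deterministic
  seed-derivation chain (splits, sampler, per-topic scoring, per-level
  forests), so two runs with the same seed produce byte-identical
  performance tables.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
the 2,000-document preset for full-scale pipeline runs, a 300-document
version for fast unit checks, 20 corpora of at most 8 documents for the
enumeration comparison, and 5 refits of a 2,000-document, 5-topic corpus
for recovery (normalized mutual information against the planted topics).

## Limitations

* Binary classification only; multi-class scoring is out of scope.
* The native topic model is GSDMM; other short-text topic models enter
  through the artifact importer, not as samplers.
* Topic count $K$ is user-set; there is no automatic selection.
* Stemming is English-only (Porter2).
* The performance table invites selecting $i$ on test performance; see
  the caveat above about nested validation.
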