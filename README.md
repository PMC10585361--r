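# gsmtopics

Topic-based feature selection for binary classification of **short texts**
— article titles, brief abstracts, any corpus whose documents are a
handful of words. It is aimed at literature-triage tasks (the motivating
case is flagging drug-induced-liver-injury papers from their titles) and
at anyone who needs an interpretable, compact feature set rather than a
black-box text classifier.

## The method

Short texts make plain bag-of-words classifiers fragile: the document-term
matrix is extremely sparse and almost every term is irrelevant to any one
document. `gsmtopics` applies a grouping–scoring–modeling (G-S-M) scheme:

1. **T** — fit a Dirichlet-multinomial mixture topic model (GSDMM, a
   collapsed Gibbs sampler in which each document belongs to exactly one
   latent topic) and extract its two byproducts: the topic–word matrix
   *TW* (top *m* terms per topic, with posterior-mean probabilities
   $\phi_{kw} = (n_{kw}+\beta)/(n_k+V\beta)$) and the document–topic
   matrix *TD* (the normalized collapsed posterior per document).
2. **G** — for each of the *K* topics, slice the training bag-of-words
   down to that topic's terms.
3. **S** — score each topic by stratified 5-fold cross-validation of a
   random forest on its slice (mean accuracy), and rank topics.
4. **C** — accumulate the top-ranked topics: for each *i*, the union of
   the top-*i* topics' terms, optionally concatenated with the *K* TD
   columns ("fused" mode).
5. **M** — train the final random forest on each accumulated set under
   stratified 10 × 90/10 Monte-Carlo cross-validation and report
   accuracy, recall, specificity, precision, F1, AUC and Cohen's kappa
   per accumulation level.

The selected level gives a small, readable term list plus (in fused mode)
the topic-distribution features — typically a few dozen features in place
of the full vocabulary. Externally trained topic models can be plugged in
through text-file artifacts (`import_topic_artifacts()`), and a synthetic
corpus generator with class-linked topics provides ground truth for
testing every stage offline.

## Worked example

```r
library(gsmtopics)

# a synthetic title-length corpus: 6 planted topics, 2 linked to each class,
# 2 shared noise; disjoint topic vocabularies
synth <- make_separable_preset(seed = 7, D = 600)

cfg <- pipeline_config(K = 8, m = 15, gibbs_iterations = 300, mccv_reps = 5,
                       preprocess = FALSE, seed = 42)
res <- run_pipeline(synth$documents, cfg)
res
#> <gsm_result> tw_plus_td, 5 repetition(s), 8 accumulation level(s)
#>   best mean F1 0.9496 at i = 6 (~72 terms)

round(head(res$table[, c("i", "n_terms_mean", "accuracy", "f1", "auc", "kappa")], 4), 3)
#>   i n_terms_mean accuracy    f1   auc kappa
#> 1 1           15    0.940 0.934 0.995 0.879
#> 2 2           30    0.940 0.934 0.996 0.879
#> 3 3           45    0.943 0.938 0.996 0.886
#> 4 4           60    0.943 0.938 0.997 0.886
```

Each row is one accumulation level: `i` topics kept, the mean number of
distinct terms their union contributes, and the mean of each metric over
the Monte-Carlo repetitions. Here one topic's 15 words (plus the 8
topic-distribution columns) already reach F1 ≈ 0.93 because the planted
topics are class-linked; accumulating more topics adds the vocabulary of
the remaining class-linked clusters. `select_best_subset(res, "f1")`
returns the best level and its term union — with the caveat (see the
vignette) that selecting on the evaluation table itself is optimistic.

Real corpora in TSV form (`id`, `text`, `label`) go through the same
functions with `preprocess = TRUE` (the default), which applies case
folding, punctuation/digit removal, length-3 and stopword filters and
native Snowball (Porter2) stemming.

There is also a command-line front end:

```sh
Rscript inst/cli/gsmtopics.R simulate --preset separable --seed 7 --out-dir demo
Rscript inst/cli/gsmtopics.R run --input demo/corpus.tsv --no-preprocess \
    --topics 8 --words 15 --iterations 300 --reps 5 --out-dir demo
Rscript inst/cli/gsmtopics.R overlap --tw-a a_topics.txt --tw-b b_topics.txt
```

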