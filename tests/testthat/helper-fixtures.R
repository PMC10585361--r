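# shared fixtures and a memo cache so expensive pipeline runs are computed
# once per test session

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache, inherits = FALSE)
}

# tiny deterministic corpus used across gsdmm unit tests
tiny_bow <- function(weighting = "count") {
  toks <- list(c("a", "a", "b"), c("a", "b"), c("c", "d"),
               c("c", "c"), c("d"), c("a", "d"))
  vocab <- build_vocabulary(toks, 1)
  build_bow(toks, vocab, weighting)
}

# random tokenized corpus for property tests
random_tokens <- function(D, V, max_len = 6, seed = 1) {
  set.seed(seed)
  lapply(seq_len(D), function(d) {
    sprintf("t%02d", sample.int(V, sample.int(max_len, 1), replace = TRUE))
  })
}

write_tmp_corpus <- function(df, sep = "\t") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# benchmark corpus + full-scale pipeline runs shared by acceptance checks
acc_preset <- function() cached("preset", make_separable_preset(seed = 11))

acc_run_pro <- function() cached("run_pro", {
  run_pipeline(acc_preset()$documents,
               pipeline_config(mode = "tw_plus_td", preprocess = FALSE,
                               seed = 5))
})

acc_run_tw_only <- function() cached("run_tw_only", {
  run_pipeline(acc_preset()$documents,
               pipeline_config(mode = "tw_only", preprocess = FALSE,
                               seed = 5))
})

acc_run_null <- function() cached("run_null", {
  docs <- acc_preset()$documents
  set.seed(99)
  docs$label <- sample(docs$label)
  run_pipeline(docs, pipeline_config(mode = "tw_plus_td", preprocess = FALSE,
                                     seed = 5))
})

# ground-truth topic-word matrix of the benchmark corpus (top terms by phi)
acc_true_tw <- function(m = 20) {
  synth <- acc_preset()
  topics_from_terms(lapply(seq_len(nrow(synth$true_phi)), function(k) {
    synth$terms[order(-synth$true_phi[k, ])[seq_len(m)]]
  }))
}
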