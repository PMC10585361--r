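test_that("document normalization follows the pipeline order", {
  expect_equal(preprocess_document("Drug-Induced Liver Injury: 2 Case Reports"),
               c("drug", "induc", "liver", "injuri", "case", "report"))
  expect_equal(preprocess_document("A 1 2 3 of"), character(0))
  expect_equal(preprocess_document(""), character(0))
  expect_equal(preprocess_document("THE the The"), character(0))
  # length filter is pre-stem: short stems survive
  expect_equal(preprocess_document("agreed"), "agre")
})

test_that("token filtering is idempotent on its own output", {
  texts <- c("Short-text topic models; 2023 review!",
             "Noisy 123 input with STOPWORDS and the rest",
             "alpha beta gamma delta")
  for (tx in texts) {
    once <- preprocess_document(tx, stem = FALSE)
    again <- preprocess_document(paste(once, collapse = " "), stem = FALSE)
    expect_equal(again, once)
  }
})

test_that("read_corpus parses, maps labels and validates", {
  df <- data.frame(id = c("a", "b", "c"),
                   text = c("one doc", "two doc", "three doc"),
                   label = c("DILI", "non-DILI", "DILI"))
  path <- write_tmp_corpus(df)
  corp <- read_corpus(path, label_map = c("DILI" = 1, "non-DILI" = 0))
  expect_equal(corp$label, c(1L, 0L, 1L))
  expect_equal(corp$doc_id, c("a", "b", "c"))

  empty <- write_tmp_corpus(df[0, ])
  expect_warning(out <- read_corpus(empty), "no documents")
  expect_equal(nrow(out), 0)

  bad3 <- write_tmp_corpus(transform(df, label = c("x", "y", "z")))
  expect_error(read_corpus(bad3), "not binary")

  dup <- write_tmp_corpus(transform(df, id = c("a", "a", "b")))
  expect_error(read_corpus(dup, label_map = c("DILI" = 1, "non-DILI" = 0)),
               "duplicate")

  nocol <- write_tmp_corpus(data.frame(id = "a", text = "t"))
  expect_error(read_corpus(nocol), "label")
})

test_that("vocabulary cutoff keeps terms at or above the threshold", {
  toks <- list(rep("a", 25), c(rep("b", 19), rep("c", 20)))
  v <- build_vocabulary(toks, 20)
  expect_equal(v$terms, c("a", "c"))
  v1 <- build_vocabulary(toks, 1)
  expect_equal(v1$terms, c("a", "b", "c"))
  # determinism: first-occurrence order, stable across runs
  expect_identical(build_vocabulary(toks, 1)$terms,
                   build_vocabulary(toks, 1)$terms)
  expect_warning(build_vocabulary(list(), 1), "empty")
})

test_that("higher cutoffs give nested vocabularies", {
  toks <- random_tokens(D = 60, V = 30, seed = 4)
  prev <- build_vocabulary(toks, 1)$terms
  for (t in c(2, 4, 8, 16)) {
    cur <- build_vocabulary(toks, t)$terms
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("document-frequency counting differs from term frequency", {
  toks <- list(rep("a", 10), c("b"), c("b"))
  expect_equal(build_vocabulary(toks, 2, count = "term")$terms, c("a", "b"))
  expect_equal(build_vocabulary(toks, 2, count = "document")$terms, "b")
})

test_that("bag-of-words weighting and out-of-vocabulary handling", {
  vocab <- build_vocabulary(list(c("a", "b", "c")), 1)
  rel <- build_bow(list(c("a", "a", "b", "c")), vocab, "relative_tf")
  expect_equal(as.numeric(rel$values[1, ]), c(0.5, 0.25, 0.25))

  oov <- build_bow(list(c("x")), vocab, "relative_tf")
  expect_equal(as.numeric(oov$values[1, ]), c(0, 0, 0))

  # in-vocabulary denominator: OOV tokens are excluded from the total
  va <- build_vocabulary(list(c("a")), 1)
  mixed <- build_bow(list(c("a", "x", "a")), va, "relative_tf")
  expect_equal(as.numeric(mixed$values[1, ]), 1.0)
  cnt <- build_bow(list(c("a", "x", "a")), va, "count")
  expect_equal(as.numeric(cnt$values[1, ]), 2)
  # raw-length denominator option
  raw <- build_bow(list(c("a", "x", "a")), va, "relative_tf",
                   denominator = "raw")
  expect_equal(as.numeric(raw$values[1, ]), 2 / 3)
})

test_that("relative rows sum to one and counts are conserved", {
  for (seed in 1:5) {
    toks <- random_tokens(D = 40, V = 25, seed = seed)
    vocab <- build_vocabulary(toks, 2)
    rel <- build_bow(toks, vocab, "relative_tf")
    rs <- Matrix::rowSums(rel$values)
    nonzero <- rs > 0
    expect_true(all(abs(rs[nonzero] - 1) < 1e-9))

    cnt <- build_bow(toks, vocab, "count")
    in_vocab_total <- sum(unlist(toks) %in% vocab$terms)
    expect_equal(sum(cnt$values), in_vocab_total)
  }
})

test_that("vocabulary and bow writers round-trip", {
  toks <- random_tokens(D = 10, V = 8, seed = 2)
  vocab <- build_vocabulary(toks, 1)
  vpath <- withr::local_tempfile()
  write_vocabulary(vocab, vpath)
  expect_equal(readLines(vpath), vocab$terms)

  bow <- build_bow(toks, vocab, "count")
  bpath <- withr::local_tempfile()
  write_bow(bow, bpath)
  tri <- utils::read.delim(bpath)
  expect_equal(sum(tri$value), sum(bow$values))
})
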