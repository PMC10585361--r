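test_that("degenerate sampler settings behave as contracts say", {
  bow <- tiny_bow()
  # single cluster: everything assigned to it
  fit1 <- fit_gsdmm(bow, K = 1, iterations = 10, seed = 3)
  expect_true(all(fit1$z == 1))
  expect_equal(fit1$m, 6)

  # zero iterations: seeded random initialization with consistent counts
  fit0 <- fit_gsdmm(bow, K = 3, iterations = 0, seed = 3)
  expect_equal(sum(fit0$m), fit0$D)
  expect_equal(rowSums(fit0$n_kw), fit0$n_k, ignore_attr = TRUE)
  expect_equal(sum(fit0$n_k), sum(bow$values))

  expect_error(fit_gsdmm(tiny_bow("relative_tf"), K = 2), "count-mode")
})

test_that("identical seeds give identical fits", {
  bow <- tiny_bow()
  f1 <- fit_gsdmm(bow, K = 3, iterations = 50, seed = 42)
  f2 <- fit_gsdmm(bow, K = 3, iterations = 50, seed = 42)
  expect_identical(f1$z, f2$z)
  expect_identical(f1$n_kw, f2$n_kw)
  f3 <- fit_gsdmm(bow, K = 3, iterations = 50, seed = 43)
  expect_false(identical(f1$z, f3$z) && identical(f1$n_kw, f3$n_kw))
})

test_that("count invariants hold after every sweep", {
  bow <- tiny_bow()
  fit <- fit_gsdmm(bow, K = 3, iterations = 200, seed = 9,
                   check_invariants = TRUE)
  expect_equal(fit$invariant_violations, 0)
})

test_that("documents with no in-vocabulary tokens use the size prior", {
  toks <- list(c("a", "b"), c("a"), character(0))
  vocab <- build_vocabulary(list(c("a", "b")), 1)
  bow <- build_bow(toks, vocab, "count")
  expect_warning(fit <- fit_gsdmm(bow, K = 2, iterations = 20, seed = 1),
                 "no in-vocabulary")
  expect_equal(sum(fit$m), 3)
})

test_that("topic-word extraction applies the posterior-mean formula", {
  state <- structure(list(K = 2, V = 2, alpha = 0.1, beta = 0.01,
                          m = c(1, 0), n_k = c(10, 0),
                          n_kw = matrix(c(10, 0, 0, 0), 2, 2, byrow = TRUE),
                          terms = c("liver", "kidney")),
                     class = "gsdmm_fit")
  tw <- extract_topic_word(state, m = 1)
  expect_equal(tw$topics[[1]]$term, "liver")
  expect_equal(tw$topics[[1]]$phi, 10.01 / 10.02)
  # empty cluster: uniform 1/V, first vocabulary terms win
  tw2 <- extract_topic_word(state, m = 2)
  expect_equal(tw2$topics[[2]]$term, c("liver", "kidney"))
  expect_equal(tw2$topics[[2]]$phi, c(0.5, 0.5))
})

test_that("phi over the full vocabulary sums to one per topic", {
  bow <- tiny_bow()
  fit <- fit_gsdmm(bow, K = 3, iterations = 30, seed = 5)
  phi <- sweep(fit$n_kw + fit$beta, 1, fit$n_k + fit$V * fit$beta, "/")
  expect_true(all(abs(rowSums(phi) - 1) < 1e-9))
})

test_that("equal-count ties resolve by vocabulary order", {
  state <- structure(list(K = 1, V = 3, alpha = 0.1, beta = 0.01,
                          m = 1, n_k = 4,
                          n_kw = matrix(c(2, 2, 0), 1, 3),
                          terms = c("zeta", "alpha", "mid")),
                     class = "gsdmm_fit")
  tw <- extract_topic_word(state, m = 2)
  expect_equal(tw$topics[[1]]$term, c("zeta", "alpha"))
})

test_that("document-topic posterior matches hand evaluation", {
  state <- structure(list(K = 2, V = 2, alpha = 0.1, beta = 0.01,
                          m = c(3, 1), n_k = c(4, 2),
                          n_kw = matrix(c(4, 0, 0, 2), 2, 2, byrow = TRUE),
                          terms = c("w1", "w2"), z = c(1, 1, 1, 2)),
                     class = "gsdmm_fit")
  p <- doc_topic_posterior(state, c(1, 0))
  un <- c(3.1 * 4.01 / 4.02, 1.1 * 0.01 / 2.02)
  expect_equal(p, un / sum(un))
  expect_equal(sum(p), 1)
  # term-name input agrees with the count-vector input
  expect_equal(doc_topic_posterior(state, "w1"), p)
  # K = 1 degenerate
  s1 <- structure(list(K = 1, V = 2, alpha = 0.1, beta = 0.01, m = 2,
                       n_k = 3, n_kw = matrix(c(2, 1), 1, 2),
                       terms = c("w1", "w2")), class = "gsdmm_fit")
  expect_equal(doc_topic_posterior(s1, c(1, 0)), 1)
})

test_that("symmetric states give uniform posteriors", {
  state <- structure(list(K = 2, V = 1, alpha = 0.1, beta = 0.01,
                          m = c(2, 2), n_k = c(3, 3),
                          n_kw = matrix(c(3, 3), 2, 1),
                          terms = "w"), class = "gsdmm_fit")
  expect_equal(doc_topic_posterior(state, 2), c(0.5, 0.5))
})

test_that("all-OOV documents fall back to the size prior with a warning", {
  state <- structure(list(K = 2, V = 1, alpha = 0.1, beta = 0.01,
                          m = c(3, 1), n_k = c(3, 1),
                          n_kw = matrix(c(3, 1), 2, 1),
                          terms = "w"), class = "gsdmm_fit")
  expect_warning(p <- doc_topic_posterior(state, "unseen"), "no in-vocabulary")
  expect_equal(p, c(3.1, 1.1) / 4.2)
})

test_that("document-topic matrix rows sum to one over random fits", {
  for (seed in 1:8) {
    toks <- random_tokens(D = 15, V = 10, seed = seed)
    vocab <- build_vocabulary(toks, 1)
    bow <- build_bow(toks, vocab, "count")
    fit <- fit_gsdmm(bow, K = 4, iterations = 20, seed = seed)
    td_in <- extract_doc_topic(fit, bow, held_in = TRUE)
    td_out <- extract_doc_topic(fit, bow, held_in = FALSE)
    expect_true(all(abs(rowSums(td_in) - 1) < 1e-9))
    expect_true(all(abs(rowSums(td_out) - 1) < 1e-9))
  }
})

test_that("training rows concentrate on the document's own cluster", {
  # two well-separated clusters with disjoint vocabularies
  synth <- generate_dmm_corpus(generator_config(
    K_true = 2, V = 60, D = 200, doc_length_lambda = 8,
    topic_given_class = rbind(c(1, 0), c(0, 1)),
    exclusive_vocab = TRUE, seed = 8))
  toks <- tokenize_corpus(synth$documents, preprocess = FALSE)
  vocab <- build_vocabulary(toks, 1)
  bow <- build_bow(toks, vocab, "count")
  fit <- fit_gsdmm(bow, K = 2, iterations = 100, seed = 2)
  td <- extract_doc_topic(fit, bow, held_in = TRUE)
  agree <- mean(max.col(td) == fit$z)
  expect_gte(agree, 0.95)
})

test_that("sampler matches the enumerated posterior on small corpora", {
  res <- validate_sampler_exactness(n_corpora = 3, burnin = 1000,
                                    sweeps = 10000, seed = 77)
  expect_true(all(res$tv < 0.05))
})
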