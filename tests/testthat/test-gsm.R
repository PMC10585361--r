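make_sub <- function(x, labels, topic_id = 1, degenerate = FALSE) {
  structure(list(topic_id = topic_id, terms = colnames(x),
                 dropped_terms = character(0), x = x, labels = labels,
                 degenerate = degenerate),
            class = "gsm_subdataset")
}

test_that("sub-datasets slice the BOW to in-vocabulary topic terms", {
  toks <- list(c("a", "b"), c("b", "c"), c("a", "c"), c("c", "c"))
  vocab <- build_vocabulary(toks, 1)
  bow <- build_bow(toks, vocab, "relative_tf")
  tw <- topics_from_terms(list(c("a", "b"), c("x", "y"), c("c", "x")))
  subs <- build_topic_subdatasets(bow, tw, labels = c(0, 0, 1, 1))
  expect_equal(colnames(subs[[1]]$x), c("a", "b"))
  expect_true(subs[[2]]$degenerate)
  expect_equal(subs[[3]]$terms, "c")
  expect_equal(subs[[3]]$dropped_terms, "x")
  expect_equal(nrow(subs[[1]]$x), 4)
})

test_that("class-separating topics score high, uninformative ones near chance", {
  set.seed(31)
  n <- 300
  y <- rep(c(0, 1), each = n / 2)
  # terms occur only in class-1 documents
  x_sep <- cbind(t1 = ifelse(y == 1, runif(n, 0.2, 0.8), 0),
                 t2 = ifelse(y == 1, runif(n, 0.1, 0.5), 0))
  s_sep <- score_topic(make_sub(x_sep, y), seed = 7)
  expect_gte(s_sep$score, 0.95)

  # label-independent features on balanced classes
  set.seed(32)
  x_null <- cbind(t1 = runif(600), t2 = runif(600))
  y_null <- rep(c(0, 1), 300)
  s_null <- score_topic(make_sub(x_null, y_null), seed = 7)
  expect_gte(s_null$score, 0.45)
  expect_lte(s_null$score, 0.55)
})

test_that("degenerate sub-datasets score as the majority proportion", {
  y <- c(rep(1, 60), rep(0, 40))
  sub <- make_sub(matrix(0, 100, 0), y, degenerate = TRUE)
  s <- score_topic(sub, folds = 5, seed = 1)
  expect_equal(s$score, 0.6)
  expect_true(s$degenerate)
  expect_equal(s$fold_scores, rep(0.6, 5))
})

test_that("scoring is deterministic and invariant to column order", {
  set.seed(12)
  x <- cbind(a = runif(80), b = runif(80), c = runif(80))
  y <- rep(c(0, 1), 40)
  s1 <- score_topic(make_sub(x, y), seed = 5)
  s2 <- score_topic(make_sub(x, y), seed = 5)
  expect_identical(s1$fold_scores, s2$fold_scores)
  s3 <- score_topic(make_sub(x[, c("c", "a", "b")], y), seed = 5)
  expect_equal(s1$score, s3$score)
})

test_that("ranking is descending with id tie-break and order-invariant", {
  sc <- function(id, s) structure(list(topic_id = id, score = s,
                                       fold_scores = s, degenerate = FALSE,
                                       rank = NA_integer_),
                                  class = "gsm_topic_score")
  scores <- list(sc(1, 0.9), sc(2, 0.7), sc(3, 0.8))
  ranked <- rank_topics(scores)
  expect_equal(vapply(ranked, `[[`, 0, "topic_id"), c(1, 3, 2))
  expect_equal(vapply(ranked, `[[`, 0, "rank"), 1:3)

  tied <- list(sc(4, 0.8), sc(2, 0.8), sc(9, 0.9))
  expect_equal(vapply(rank_topics(tied), `[[`, 0, "topic_id"), c(9, 2, 4))

  perm <- rank_topics(scores[c(3, 1, 2)])
  expect_equal(vapply(perm, `[[`, 0, "topic_id"),
               vapply(ranked, `[[`, 0, "topic_id"))
})

test_that("accumulated feature sets union terms and append TD columns", {
  toks <- lapply(1:6, function(i) c("a", "b", "c", "d", "e")[1:(i %% 5 + 1)])
  vocab <- build_vocabulary(toks, 1)
  bow <- build_bow(toks, vocab, "relative_tf")
  tw <- topics_from_terms(list(c("a", "b"), c("b", "c"), c("d")))
  sc <- function(id) structure(list(topic_id = id, score = 1 - id / 10,
                                    fold_scores = 1, degenerate = FALSE,
                                    rank = id), class = "gsm_topic_score")
  ranked <- list(sc(1), sc(2), sc(3))
  labels <- rep(c(0, 1), 3)

  a1 <- accumulate_features(bow, tw, ranked, 1, labels = labels)
  expect_equal(a1$terms, c("a", "b"))
  expect_equal(a1$mode, "tw_only")

  a2 <- accumulate_features(bow, tw, ranked, 2, labels = labels)
  expect_equal(a2$terms, c("a", "b", "c"))  # shared term deduplicated

  a3 <- accumulate_features(bow, tw, ranked, 3, labels = labels)
  expect_equal(a3$terms, c("a", "b", "c", "d"))

  # nesting
  expect_true(all(a1$terms %in% a2$terms))
  expect_true(all(a2$terms %in% a3$terms))

  td <- matrix(1 / 3, 6, 3)
  a2td <- accumulate_features(bow, tw, ranked, 2, td = td, labels = labels)
  expect_equal(a2td$mode, "tw_plus_td")
  expect_equal(ncol(a2td$x), ncol(a2$x) + 3)
  expect_error(accumulate_features(bow, tw, ranked, 2, td = td[1:3, ]),
               "do not match")
  expect_error(accumulate_features(bow, tw, ranked, 9), "out of range")
})

test_that("overlap percentages count shared unique terms", {
  twA <- topics_from_terms(list(c("a", "b"), c("c", "d")))
  twB <- topics_from_terms(list(c("a", "b")))
  ov <- compute_topic_overlap(twA, twB)
  expect_equal(ov$overlap_ab, 50)
  expect_equal(ov$overlap_ba, 100)
  expect_equal(ov$n_shared, 2)

  same <- compute_topic_overlap(twA, twA)
  expect_equal(same$overlap_ab, 100)
  disj <- compute_topic_overlap(twA, topics_from_terms(list(c("x", "y"))))
  expect_equal(disj$overlap_ab, 0)
  empty <- topics_from_terms(list(character(0)))
  expect_error(compute_topic_overlap(empty, twA), "undefined")
})

test_that("asymmetric overlaps reconcile through the shared-term identity", {
  set.seed(9)
  pool <- sprintf("t%03d", 1:120)
  for (case in 1:30) {
    twA <- topics_from_terms(list(sample(pool, sample(5:40, 1))))
    twB <- topics_from_terms(list(sample(pool, sample(5:40, 1))))
    ov <- compute_topic_overlap(twA, twB)
    expect_equal(ov$overlap_ab * ov$n_a, 100 * ov$n_shared, tolerance = 1e-12)
    expect_equal(ov$overlap_ba * ov$n_b, 100 * ov$n_shared, tolerance = 1e-12)
  }
})
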