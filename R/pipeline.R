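#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline with the framework's
#' defaults: 20 topics of 20 words, Dirichlet priors alpha = 0.1 and
#' beta = 0.01, 1,000 Gibbs sweeps, 10 stratified Monte-Carlo 90/10
#' repetitions and 5-fold internal scoring. The minimum-frequency cutoff
#' defaults to 20 in `tw_only` mode and to 1 (disabled) in `tw_plus_td`
#' mode, where keeping rare terms preserves more of the short texts.
#'
#' @param K number of topics.
#' @param m words per topic.
#' @param alpha,beta Dirichlet priors of the topic model.
#' @param gibbs_iterations Gibbs sweeps per fit.
#' @param mccv_reps Monte-Carlo cross-validation repetitions.
#' @param train_fraction per-class training fraction of each split.
#' @param internal_cv_folds folds of the topic-scoring cross-validation.
#' @param mode `"tw_plus_td"` (topical words fused with the document-topic
#'   distribution) or `"tw_only"` (topical words alone).
#' @param min_corpus_frequency vocabulary cutoff; NULL picks the mode
#'   default (20 for `tw_only`, 1 for `tw_plus_td`).
#' @param freq_count `"term"` (corpus term frequency) or `"document"`
#'   (document frequency) interpretation of the cutoff.
#' @param topic_model_source `"native_gsdmm"` or `"import"`.
#' @param tw,td imported topic artifacts (a `gsm_topics` and a full-corpus
#'   document-topic matrix), required when `topic_model_source = "import"`.
#' @param r number of accumulation levels (default K).
#' @param num_trees random-forest size for scoring and the final model.
#' @param score_metric topic-scoring criterion, `"accuracy"` or `"auc"`.
#' @param preprocess apply the text normalization pipeline (set FALSE for
#'   corpora whose tokens are already normalized, e.g. synthetic terms).
#' @param fit_on_full_corpus fit vocabulary and topic model once on the
#'   whole corpus instead of per training split. The default (FALSE)
#'   refits inside each repetition so no test information reaches the
#'   topic model.
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `gsm_config`.
#' @export
pipeline_config <- function(K = 20L, m = 20L, alpha = 0.1, beta = 0.01,
                            gibbs_iterations = 1000L, mccv_reps = 10L,
                            train_fraction = 0.9, internal_cv_folds = 5L,
                            mode = c("tw_plus_td", "tw_only"),
                            min_corpus_frequency = NULL,
                            freq_count = c("term", "document"),
                            topic_model_source = c("native_gsdmm", "import"),
                            tw = NULL, td = NULL, r = NULL,
                            num_trees = 100L,
                            score_metric = c("accuracy", "auc"),
                            preprocess = TRUE,
                            fit_on_full_corpus = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  freq_count <- match.arg(freq_count)
  topic_model_source <- match.arg(topic_model_source)
  score_metric <- match.arg(score_metric)
  if (is.null(min_corpus_frequency)) {
    min_corpus_frequency <- if (mode == "tw_only") 20L else 1L
  }
  problems <- character(0)
  if (K < 1) problems <- c(problems, "K must be >= 1")
  if (m < 1) problems <- c(problems, "m must be >= 1")
  if (alpha <= 0) problems <- c(problems, "alpha must be > 0")
  if (beta <= 0) problems <- c(problems, "beta must be > 0")
  if (gibbs_iterations < 0) problems <- c(problems, "gibbs_iterations must be >= 0")
  if (mccv_reps < 1) problems <- c(problems, "mccv_reps must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1) {
    problems <- c(problems, "train_fraction must be in (0, 1)")
  }
  if (internal_cv_folds < 2) problems <- c(problems, "internal_cv_folds must be >= 2")
  if (min_corpus_frequency < 1) problems <- c(problems, "min_corpus_frequency must be >= 1")
  if (topic_model_source == "import" && (is.null(tw) || is.null(td))) {
    problems <- c(problems, "import source requires tw and td artifacts")
  }
  if (length(problems) > 0) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  if (is.null(r)) r <- if (topic_model_source == "import") length(tw$topics) else K
  structure(list(K = as.integer(K), m = as.integer(m), alpha = alpha,
                 beta = beta, gibbs_iterations = as.integer(gibbs_iterations),
                 mccv_reps = as.integer(mccv_reps),
                 train_fraction = train_fraction,
                 internal_cv_folds = as.integer(internal_cv_folds),
                 mode = mode, min_corpus_frequency = as.integer(min_corpus_frequency),
                 freq_count = freq_count,
                 topic_model_source = topic_model_source, tw = tw, td = td,
                 r = as.integer(r), num_trees = as.integer(num_trees),
                 score_metric = score_metric, preprocess = preprocess,
                 fit_on_full_corpus = fit_on_full_corpus,
                 seed = as.integer(seed)),
            class = "gsm_config")
}

#' Run the full topic-selection pipeline
#'
#' Executes, for every Monte-Carlo repetition: vocabulary construction and
#' topic-model fitting on the training split (unless
#' `fit_on_full_corpus`); topic sub-dataset construction, scoring and
#' ranking on the training rows; then, for each accumulation level
#' `i = 1..r`, training of the final random-forest classifier on the
#' accumulated term union (fused with the document-topic columns in
#' `tw_plus_td` mode), projection of the test documents into the training
#' feature space (unseen terms ignored; test document-topic rows from the
#' collapsed posterior) and metric computation. Metric means per level are
#' collected into the performance table.
#'
#' @param corpus a corpus data frame (`doc_id`, `text`, `label`).
#' @param config a `gsm_config` from [pipeline_config()].
#' @return an object of class `gsm_result`: list with `table` (the
#'   performance table: per level, the mean term count and mean of each of
#'   the seven metrics over completed repetitions), `per_rep` (list of
#'   per-repetition metric matrices), `terms_per_rep`, `topic_scores`
#'   (per repetition), `completed_reps`, `config`.
#' @export
run_pipeline <- function(corpus, config = pipeline_config()) {
  stopifnot(all(c("doc_id", "text", "label") %in% names(corpus)))
  labels <- as.integer(corpus$label)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)

  toks <- tokenize_corpus(corpus, preprocess = config$preprocess)
  splits <- mccv_split(labels, reps = config$mccv_reps,
                       train_fraction = config$train_fraction,
                       seed = derive_seed(config$seed, 1))

  full_fit <- NULL
  full_vocab <- NULL
  full_td <- NULL
  if (config$topic_model_source == "import") {
    if (nrow(config$td) != length(labels)) {
      stop("imported document-topic matrix rows do not match the corpus",
           call. = FALSE)
    }
  } else if (config$fit_on_full_corpus) {
    full_vocab <- build_vocabulary(toks, config$min_corpus_frequency,
                                   count = config$freq_count)
    bow_all <- build_bow(toks, full_vocab, weighting = "count")
    bow_all$labels <- labels
    full_fit <- fit_gsdmm(bow_all, K = config$K, alpha = config$alpha,
                          beta = config$beta,
                          iterations = config$gibbs_iterations,
                          seed = derive_seed(config$seed, 2))
    full_td <- suppressWarnings(
      extract_doc_topic(full_fit, bow_all, held_in = TRUE))
  }

  metric_names <- c("accuracy", "recall", "specificity", "precision",
                    "f1", "auc", "kappa")
  per_rep <- list()
  terms_per_rep <- list()
  scores_per_rep <- list()
  completed <- integer(0)

  for (rep in seq_len(config$mccv_reps)) {
    sp <- splits[[rep]]
    y_tr <- labels[sp$train]
    y_te <- labels[sp$test]
    if (length(unique(y_te)) < 2 || length(unique(y_tr)) < 2) {
      warning("repetition ", rep, " lacks a class in a split; skipped")
      next
    }
    tr_toks <- structure(list(doc_id = toks$doc_id[sp$train],
                              tokens = toks$tokens[sp$train],
                              label = y_tr), class = "gsm_tokens")
    te_toks <- structure(list(doc_id = toks$doc_id[sp$test],
                              tokens = toks$tokens[sp$test],
                              label = y_te), class = "gsm_tokens")

    if (config$topic_model_source == "import") {
      vocab <- build_vocabulary(tr_toks, config$min_corpus_frequency,
                                count = config$freq_count)
      tw <- config$tw
      td_tr <- config$td[sp$train, , drop = FALSE]
      td_te <- config$td[sp$test, , drop = FALSE]
    } else if (config$fit_on_full_corpus) {
      vocab <- full_vocab
      tw <- extract_topic_word(full_fit, m = config$m)
      td_tr <- full_td[sp$train, , drop = FALSE]
      td_te <- full_td[sp$test, , drop = FALSE]
    } else {
      vocab <- build_vocabulary(tr_toks, config$min_corpus_frequency,
                                count = config$freq_count)
      if (length(vocab$terms) == 0) {
        warning("repetition ", rep, " has an empty training vocabulary; skipped")
        next
      }
      bow_tr_cnt <- suppressWarnings(build_bow(tr_toks, vocab, weighting = "count"))
      fit <- suppressWarnings(
        fit_gsdmm(bow_tr_cnt, K = config$K, alpha = config$alpha,
                  beta = config$beta, iterations = config$gibbs_iterations,
                  seed = derive_seed(config$seed, 2, rep)))
      tw <- extract_topic_word(fit, m = config$m)
      td_tr <- suppressWarnings(extract_doc_topic(fit, bow_tr_cnt, held_in = TRUE))
      bow_te_cnt <- suppressWarnings(build_bow(te_toks, vocab, weighting = "count"))
      td_te <- suppressWarnings(extract_doc_topic(fit, bow_te_cnt, held_in = FALSE))
    }

    bow_tr <- suppressWarnings(build_bow(tr_toks, vocab, weighting = "relative_tf"))
    bow_te <- suppressWarnings(build_bow(te_toks, vocab, weighting = "relative_tf"))

    scores <- score_topics(bow_tr, tw, labels = y_tr,
                           folds = config$internal_cv_folds,
                           seed = derive_seed(config$seed, 3, rep),
                           metric = config$score_metric,
                           num_trees = config$num_trees)
    ranked <- rank_topics(scores)

    use_td <- config$mode == "tw_plus_td"
    r <- min(config$r, length(ranked))
    rep_metrics <- matrix(NA_real_, r, length(metric_names) + 1,
                          dimnames = list(NULL, c("n_terms", metric_names)))
    rep_terms <- vector("list", r)
    for (i in seq_len(r)) {
      acc <- accumulate_features(bow_tr, tw, ranked, i,
                                 td = if (use_td) td_tr else NULL,
                                 labels = y_tr)
      x_te <- as.matrix(bow_te$values[, acc$terms, drop = FALSE])
      if (use_td) {
        td_cols <- td_te
        colnames(td_cols) <- paste0("td_", seq_len(ncol(td_cols)))
        x_te <- cbind(x_te, td_cols)
      }
      fit_rf <- rf_fit(acc$x, acc$labels,
                       seed = derive_seed(config$seed, 4, rep, i),
                       num_trees = config$num_trees, probability = TRUE)
      prob <- rf_predict(fit_rf, x_te, probability = TRUE)
      pred <- as.integer(prob >= 0.5)
      mt <- compute_metrics(y_te, pred, prob)
      rep_metrics[i, ] <- c(length(acc$terms), as.numeric(mt))
      rep_terms[[i]] <- acc$terms
    }
    per_rep[[length(per_rep) + 1]] <- rep_metrics
    terms_per_rep[[length(terms_per_rep) + 1]] <- rep_terms
    scores_per_rep[[length(scores_per_rep) + 1]] <- topic_score_table(ranked)
    completed <- c(completed, rep)
  }

  if (length(per_rep) == 0) stop("no repetition completed", call. = FALSE)
  r <- nrow(per_rep[[1]])
  means <- Reduce(`+`, per_rep) / length(per_rep)
  table <- data.frame(i = seq_len(r), means, check.names = FALSE)
  names(table)[2] <- "n_terms_mean"

  structure(list(table = table, per_rep = per_rep,
                 terms_per_rep = terms_per_rep,
                 topic_scores = scores_per_rep,
                 completed_reps = completed, config = config),
            class = "gsm_result")
}

#' @exportS3Method base::print
print.gsm_result <- function(x, ...) {
  cat("<gsm_result> ", x$config$mode, ", ", length(x$completed_reps),
      " repetition(s), ", nrow(x$table), " accumulation level(s)\n", sep = "")
  best <- select_best_subset(x)
  cat("  best mean F1 ", sprintf("%.4f", best$value), " at i = ", best$i,
      " (~", round(x$table$n_terms_mean[best$i]), " terms)\n", sep = "")
  invisible(x)
}

#' Select the best accumulation level from a performance table
#'
#' Picks the level maximizing the mean of the chosen criterion; ties go to
#' the smallest level (fewest features). Note the table is computed on the
#' evaluation splits, so selecting on it is optimistic; honest selection of
#' the operating point requires a nested or held-out validation split.
#'
#' @param result a `gsm_result`, or a performance table data frame.
#' @param criterion one of `"accuracy"`, `"recall"`, `"specificity"`,
#'   `"precision"`, `"f1"`, `"auc"`, `"kappa"`.
#' @return list with `i` (selected level), `value` (criterion mean at
#'   `i`), `terms` (union of training-term sets at that level across
#'   repetitions; NULL when called on a bare table).
#' @export
select_best_subset <- function(result, criterion = "f1") {
  table <- if (inherits(result, "gsm_result")) result$table else result
  if (!criterion %in% names(table)) {
    stop("unknown criterion '", criterion, "'", call. = FALSE)
  }
  if (nrow(table) == 0) stop("empty performance table", call. = FALSE)
  v <- table[[criterion]]
  i <- which(v == max(v))[1]
  terms <- NULL
  if (inherits(result, "gsm_result")) {
    terms <- unique(unlist(lapply(result$terms_per_rep, `[[`, i),
                           use.names = FALSE))
  }
  list(i = table$i[i], value = v[i], terms = terms)
}

#' Write a performance table as TSV (percentages)
#'
#' Columns follow the conventional report layout: accumulation level, mean
#' term count, then Accuracy, Recall, Specificity, F-measure, AUC,
#' Precision and Cohen's kappa as percentages with two decimals.
#'
#' @param result a `gsm_result` or its `table`.
#' @param path output file path.
#' @export
write_performance_table <- function(result, path) {
  tab <- if (inherits(result, "gsm_result")) result$table else result
  out <- data.frame(
    `# of Accumulated_Topics` = tab$i,
    `# of terms (mean)` = sprintf("%.2f", tab$n_terms_mean),
    `Accuracy` = sprintf("%.2f", 100 * tab$accuracy),
    `Recall` = sprintf("%.2f", 100 * tab$recall),
    `Specificity` = sprintf("%.2f", 100 * tab$specificity),
    `F-measure` = sprintf("%.2f", 100 * tab$f1),
    `AUC` = sprintf("%.2f", 100 * tab$auc),
    `Precision` = sprintf("%.2f", 100 * tab$precision),
    `Cohen's kappa` = sprintf("%.2f", 100 * tab$kappa),
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
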