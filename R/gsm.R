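#' Build per-topic sub-datasets from the training bag-of-words (G component)
#'
#' For every topic, slices the training BOW down to the topic's terms that
#' are present in the training vocabulary. A topic with no in-vocabulary
#' terms yields a degenerate sub-dataset (zero columns, flagged); it is
#' scored as the majority-class baseline downstream so ranks remain a
#' permutation.
#'
#' @param bow a `gsm_bow` over the training rows (relative term frequency).
#' @param tw a `gsm_topics`.
#' @param labels binary labels aligned with the BOW rows (defaults to
#'   `bow$labels`).
#' @return list of `gsm_subdataset` objects: `topic_id` (1-based), `terms`,
#'   `x` (dense matrix rows x terms), `labels`, `degenerate`.
#' @export
build_topic_subdatasets <- function(bow, tw, labels = bow$labels) {
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  if (length(labels) != nrow(bow$values)) {
    stop("labels length does not match BOW rows", call. = FALSE)
  }
  lapply(seq_len(tw$K), function(k) {
    terms <- tw$topics[[k]]$term
    keep <- terms[terms %in% bow$vocab$terms]
    dropped <- setdiff(terms, keep)
    x <- as.matrix(bow$values[, keep, drop = FALSE])
    structure(list(topic_id = k, terms = keep, dropped_terms = dropped,
                   x = x, labels = labels,
                   degenerate = length(keep) == 0),
              class = "gsm_subdataset")
  })
}

# stratified fold assignment: within each class, shuffle then deal round-robin
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

rf_fit <- function(x, y, seed, num_trees = 100L, probability = FALSE) {
  df <- data.frame(x, check.names = FALSE)
  df$.y <- factor(y, levels = c(0, 1))
  ranger::ranger(dependent.variable.name = ".y", data = df,
                 num.trees = num_trees, probability = probability,
                 seed = seed, num.threads = 1L, verbose = FALSE)
}

rf_predict <- function(fit, x, probability = FALSE, seed = 1L) {
  df <- data.frame(x, check.names = FALSE)
  # an explicit seed keeps classification vote tie-breaking deterministic
  # (predict.ranger otherwise draws one from the global RNG)
  pred <- stats::predict(fit, data = df, num.threads = 1L, seed = seed,
                         verbose = FALSE)$predictions
  if (probability) pred[, "1"] else as.integer(as.character(pred))
}

#' Score one topic by internal cross-validation (S component)
#'
#' Runs stratified k-fold cross-validation of a random-forest classifier on
#' the topic's term slice and scores the topic by the mean fold accuracy
#' (or AUC). A degenerate sub-dataset is scored as the majority-class
#' proportion rather than raising an error.
#'
#' @param sub a `gsm_subdataset`.
#' @param folds number of folds (>= 2, default 5).
#' @param seed integer seed; scoring is deterministic given the seed.
#' @param metric `"accuracy"` (default) or `"auc"`.
#' @param num_trees random-forest size (default 100).
#' @return a `gsm_topic_score`: list with `topic_id`, `score`,
#'   `fold_scores`, `degenerate`, `rank` (NA until ranked).
#' @export
score_topic <- function(sub, folds = 5L, seed = 1L,
                        metric = c("accuracy", "auc"), num_trees = 100L) {
  metric <- match.arg(metric)
  y <- sub$labels
  if (sub$degenerate) {
    maj <- max(mean(y == 1), mean(y == 0))
    return(structure(list(topic_id = sub$topic_id, score = maj,
                          fold_scores = rep(maj, folds), degenerate = TRUE,
                          rank = NA_integer_),
                     class = "gsm_topic_score"))
  }
  if (min(table(y)) < 2) stop("need >= 2 examples per class", call. = FALSE)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  # canonical column order so the score does not depend on term layout
  sub$x <- sub$x[, order(colnames(sub$x)), drop = FALSE]
  fold_id <- stratified_folds(y, folds, seed)
  fold_scores <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    fit <- rf_fit(sub$x[tr, , drop = FALSE], y[tr], seed = seed + f,
                  num_trees = num_trees, probability = metric == "auc")
    if (metric == "accuracy") {
      pred <- rf_predict(fit, sub$x[!tr, , drop = FALSE])
      mean(pred == y[!tr])
    } else {
      pr <- rf_predict(fit, sub$x[!tr, , drop = FALSE], probability = TRUE)
      auc_mann_whitney(y[!tr], pr)
    }
  }, numeric(1))
  structure(list(topic_id = sub$topic_id, score = mean(fold_scores),
                 fold_scores = fold_scores, degenerate = FALSE,
                 rank = NA_integer_),
            class = "gsm_topic_score")
}

#' Score every topic of a topic-word matrix
#'
#' Convenience wrapper: builds the sub-datasets and scores each topic with a
#' per-topic seed derived from the global seed and the topic id, so results
#' do not depend on scoring order.
#'
#' @param bow,tw,labels as in [build_topic_subdatasets()].
#' @param folds,metric,num_trees as in [score_topic()].
#' @param seed global seed.
#' @return list of `gsm_topic_score`.
#' @export
score_topics <- function(bow, tw, labels = bow$labels, folds = 5L,
                         seed = 1L, metric = "accuracy", num_trees = 100L) {
  subs <- build_topic_subdatasets(bow, tw, labels)
  lapply(subs, function(s) {
    score_topic(s, folds = folds, seed = derive_seed(seed, s$topic_id),
                metric = metric, num_trees = num_trees)
  })
}

derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  s <- 0
  for (p in parts) s <- (s * 7919 + p) %% 2147483629
  as.integer(s)
}

#' Rank topics by score
#'
#' Orders topic scores descending; ties are broken by topic id ascending.
#' The `rank` field is filled with positions 1..K.
#'
#' @param scores list of `gsm_topic_score`.
#' @return the same list, reordered, with ranks assigned.
#' @export
rank_topics <- function(scores) {
  sc <- vapply(scores, function(s) s$score, numeric(1))
  id <- vapply(scores, function(s) s$topic_id, numeric(1))
  ord <- order(-sc, id)
  out <- scores[ord]
  for (r in seq_along(out)) out[[r]]$rank <- r
  out
}

#' Topic score table
#'
#' @param scores a (ranked or unranked) list of `gsm_topic_score`.
#' @return data frame with columns `topic_id`, `rank`, `score`,
#'   `n_terms_in_vocab` (NA when built without sub-datasets), `degenerate`.
#' @export
topic_score_table <- function(scores) {
  data.frame(
    topic_id = vapply(scores, function(s) s$topic_id, numeric(1)),
    rank = vapply(scores, function(s) as.numeric(s$rank), numeric(1)),
    score = vapply(scores, function(s) s$score, numeric(1)),
    degenerate = vapply(scores, function(s) s$degenerate, logical(1))
  )
}

#' Write a topic score table as TSV
#' @param scores list of `gsm_topic_score`.
#' @param subs matching list of `gsm_subdataset` (for term counts), or NULL.
#' @param path output file path.
#' @export
write_topic_scores <- function(scores, path, subs = NULL) {
  df <- topic_score_table(scores)
  df$n_terms_in_vocab <- if (!is.null(subs)) {
    nt <- vapply(subs, function(s) length(s$terms), integer(1))
    nt[df$topic_id]
  } else NA_integer_
  utils::write.table(df[, c("topic_id", "rank", "score", "n_terms_in_vocab")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the i-th accumulated feature set (C component)
#'
#' Takes the union of the top-`i` ranked topics' in-vocabulary terms (in
#' ranked traversal order, duplicates dropped) and slices the BOW to those
#' columns. When a document-topic matrix is supplied (fused mode) its K
#' columns are appended, named `td_1..td_K`.
#'
#' @param bow a `gsm_bow` (relative term frequency).
#' @param tw a `gsm_topics`.
#' @param ranked ranked list of `gsm_topic_score` from [rank_topics()].
#' @param i number of top topics to accumulate (1..K).
#' @param td optional document-topic matrix whose rows match `bow` rows.
#' @param labels binary labels (defaults to `bow$labels`).
#' @return a `gsm_accumulated`: list with `i`, `terms`, `x` (dense matrix),
#'   `labels`, `mode` (`"tw_only"` or `"tw_plus_td"`).
#' @export
accumulate_features <- function(bow, tw, ranked, i, td = NULL,
                                labels = bow$labels) {
  if (i < 1 || i > length(ranked)) stop("i out of range", call. = FALSE)
  terms <- unlist(lapply(ranked[seq_len(i)], function(s) {
    tw$topics[[s$topic_id]]$term
  }), use.names = FALSE)
  terms <- unique(terms[terms %in% bow$vocab$terms])
  x <- as.matrix(bow$values[, terms, drop = FALSE])
  mode <- "tw_only"
  if (!is.null(td)) {
    if (nrow(td) != nrow(x)) {
      stop("document-topic rows do not match BOW rows", call. = FALSE)
    }
    colnames(td) <- paste0("td_", seq_len(ncol(td)))
    x <- cbind(x, td)
    mode <- "tw_plus_td"
  }
  structure(list(i = i, terms = terms, x = x, labels = labels, mode = mode),
            class = "gsm_accumulated")
}

#' Shared-term percentage between two topic-word matrices
#'
#' With A the set of unique terms across all topics of `twA` and B likewise
#' for `twB`, returns `100 * |A intersect B| / |A|`. The measure is
#' asymmetric by design; both directions satisfy
#' `overlap(A,B) * |A| = overlap(B,A) * |B| = 100 * |A intersect B|`.
#'
#' @param twA,twB `gsm_topics` objects.
#' @return list with `n_a`, `n_b`, `n_shared`, `overlap_ab`, `overlap_ba`
#'   (percentages).
#' @export
compute_topic_overlap <- function(twA, twB) {
  a <- unique(unlist(topic_terms(twA), use.names = FALSE))
  b <- unique(unlist(topic_terms(twB), use.names = FALSE))
  if (length(a) == 0) {
    stop("first topic-word matrix has no terms; overlap undefined",
         call. = FALSE)
  }
  shared <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_shared = shared,
       overlap_ab = 100 * shared / length(a),
       overlap_ba = if (length(b) > 0) 100 * shared / length(b) else NA_real_)
}
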