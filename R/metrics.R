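#' Stratified Monte-Carlo cross-validation splits
#'
#' Generates `reps` independent stratified random train/test splits. Per
#' class, the training count is `round(train_fraction * class size)`; the
#' remainder goes to the test set.
#'
#' @param labels binary vector (0/1).
#' @param reps number of repetitions (>= 1).
#' @param train_fraction fraction of each class used for training
#'   (0 < f < 1).
#' @param seed integer seed; splits are reproducible.
#' @return list of length `reps`; each element is a list with integer
#'   vectors `train` and `test`.
#' @export
mccv_split <- function(labels, reps = 10L, train_fraction = 0.9, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab < 2)) {
    stop("each class needs at least 2 members (have ",
         paste(tab, collapse = "/"), ")", call. = FALSE)
  }
  with_local_seed(seed, {
    lapply(seq_len(reps), function(r) {
      train <- integer(0)
      for (cl in c(0, 1)) {
        idx <- which(labels == cl)
        n_tr <- round(train_fraction * length(idx))
        train <- c(train, idx[sample.int(length(idx), n_tr)])
      }
      train <- sort(train)
      list(train = train, test = setdiff(seq_along(labels), train))
    })
  })
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Rank-based AUC of positive-class scores; tied scores receive half
#' credit.
#'
#' @param truth binary vector (0/1).
#' @param scores numeric scores for the positive class.
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
auc_mann_whitney <- function(truth, scores) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' Computes accuracy, recall (sensitivity), specificity, precision, F1,
#' AUC (Mann-Whitney) and Cohen's kappa from truth, hard predictions and
#' positive-class scores. Ratios with zero denominators are reported as 0
#' and listed in the `undefined` attribute instead of propagating NaN.
#'
#' @param truth binary vector (0/1).
#' @param predicted binary vector (0/1), same length.
#' @param positive_scores numeric scores aligned with `predicted`
#'   (defaults to `predicted`, which yields a degenerate two-point AUC).
#' @return named numeric vector of class `gsm_metrics` with elements
#'   `accuracy`, `recall`, `specificity`, `precision`, `f1`, `auc`,
#'   `kappa`; the confusion counts are in the `confusion` attribute.
#' @export
compute_metrics <- function(truth, predicted, positive_scores = predicted) {
  if (length(truth) != length(predicted) ||
      length(truth) != length(positive_scores)) {
    stop("truth, predicted and positive_scores must have equal length",
         call. = FALSE)
  }
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  tn <- sum(truth == 0 & predicted == 0)
  fn <- sum(truth == 1 & predicted == 0)
  n <- tp + fp + tn + fn

  undefined <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      return(0)
    }
    num / den
  }

  accuracy <- safe_div(tp + tn, n, "accuracy")
  recall <- safe_div(tp, tp + fn, "recall")
  specificity <- safe_div(tn, tn + fp, "specificity")
  precision <- safe_div(tp, tp + fp, "precision")
  f1 <- safe_div(2 * precision * recall, precision + recall, "f1")

  p_o <- accuracy
  p_e <- ((tp + fp) / n) * ((tp + fn) / n) + ((tn + fn) / n) * ((tn + fp) / n)
  kappa <- if (p_e == 1) { undefined <- c(undefined, "kappa"); 0 }
           else (p_o - p_e) / (1 - p_e)

  auc <- auc_mann_whitney(truth, positive_scores)
  if (is.na(auc)) { undefined <- c(undefined, "auc"); auc <- 0 }

  out <- c(accuracy = accuracy, recall = recall, specificity = specificity,
           precision = precision, f1 = f1, auc = auc, kappa = kappa)
  attr(out, "confusion") <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  attr(out, "undefined") <- undefined
  class(out) <- "gsm_metrics"
  out
}

#' @exportS3Method base::print
print.gsm_metrics <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(round(v, 4))
  invisible(x)
}

#' Normalized mutual information between two partitions
#'
#' `2 * I(X; Y) / (H(X) + H(Y))` (arithmetic-mean normalization). Used to
#' measure recovery of ground-truth topics by fitted clusters. Two trivial
#' identical partitions score 1.
#'
#' @param x,y integer/character vectors of cluster labels, same length.
#' @return NMI in `[0, 1]`.
#' @export
cluster_nmi <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  tab <- table(x, y)
  p_xy <- tab / n
  p_x <- rowSums(p_xy)
  p_y <- colSums(p_xy)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- h(p_x)
  hy <- h(p_y)
  nz <- p_xy > 0
  mi <- sum(p_xy[nz] * log(p_xy[nz] / outer(p_x, p_y)[nz]))
  if (hx + hy == 0) return(if (identical(as.vector(x), as.vector(y))) 1 else 0)
  2 * mi / (hx + hy)
}
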