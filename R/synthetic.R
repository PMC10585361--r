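#' Configuration of the synthetic short-text generator
#'
#' Describes a Dirichlet-multinomial mixture with class-linked topics: each
#' document carries a binary class, draws one topic from the class-specific
#' topic distribution, a length from a Poisson truncated at 1 (mean 8 by
#' default, emulating article-title lengths), and tokens i.i.d. from the
#' topic's word distribution.
#'
#' @param K_true number of true topics.
#' @param V vocabulary size.
#' @param D number of documents.
#' @param class_prior P(class = 1).
#' @param topic_given_class 2 x K_true stochastic matrix; row 1 is class 0.
#' @param doc_length_lambda Poisson mean of document length (tokens).
#' @param topic_word_concentration symmetric Dirichlet parameter of the
#'   true per-topic word distributions.
#' @param exclusive_vocab partition the vocabulary into disjoint per-topic
#'   blocks so no term appears under two topics.
#' @param realistic decorate documents with stopwords, punctuation, digits
#'   and capitalization, and use alphabetic term names, so the corpus
#'   exercises the full preprocessing pipeline. Plain mode emits
#'   already-normalized terms `w0000..` meant to bypass preprocessing.
#' @param seed integer seed.
#' @return list of class `gsm_generator_config`.
#' @export
generator_config <- function(K_true, V, D, class_prior = 0.5,
                             topic_given_class = NULL,
                             doc_length_lambda = 8,
                             topic_word_concentration = 1,
                             exclusive_vocab = FALSE,
                             realistic = FALSE, seed = 1L) {
  if (is.null(topic_given_class)) {
    topic_given_class <- matrix(1 / K_true, 2, K_true)
  }
  stopifnot(nrow(topic_given_class) == 2, ncol(topic_given_class) == K_true,
            all(topic_given_class >= 0),
            max(abs(rowSums(topic_given_class) - 1)) < 1e-9,
            K_true >= 1, V >= K_true, D >= 1,
            class_prior > 0, class_prior < 1, doc_length_lambda > 0)
  structure(list(K_true = as.integer(K_true), V = as.integer(V),
                 D = as.integer(D), class_prior = class_prior,
                 topic_given_class = topic_given_class,
                 doc_length_lambda = doc_length_lambda,
                 topic_word_concentration = topic_word_concentration,
                 exclusive_vocab = exclusive_vocab,
                 realistic = realistic, seed = as.integer(seed)),
            class = "gsm_generator_config")
}

synthetic_term_names <- function(V, realistic) {
  if (!realistic) return(sprintf("w%04d", seq_len(V) - 1L))
  # alphabetic names that survive tokenization/length filters
  a <- (seq_len(V) - 1L) %/% 676L
  b <- ((seq_len(V) - 1L) %/% 26L) %% 26L
  c <- (seq_len(V) - 1L) %% 26L
  paste0("w", letters[a + 1L], letters[b + 1L], letters[c + 1L])
}

.decoys <- c("the", "and", "with", "from", "this", "that", "was", "were",
             "for", "are", "been", "into", "of", "a", "an", "in", "on")

#' Generate a synthetic labeled short-text corpus
#'
#' Samples documents from the mixture described by a
#' [generator_config()]. Fully reproducible from the config seed.
#'
#' @param config a `gsm_generator_config`.
#' @return an object of class `gsm_synthetic`: list with `documents` (a
#'   corpus data frame: `doc_id`, `text`, `label`), `true_topic` (1-based
#'   topic per document), `true_phi` (K_true x V), `terms`, `tokens` (the
#'   undecorated sampled terms per document), `config`.
#' @export
generate_dmm_corpus <- function(config) {
  terms <- synthetic_term_names(config$V, config$realistic)
  with_local_seed(config$seed, {
    K <- config$K_true
    V <- config$V
    phi <- matrix(0, K, V, dimnames = list(NULL, terms))
    if (config$exclusive_vocab) {
      block <- split(seq_len(V), cut(seq_len(V), K, labels = FALSE))
      for (k in seq_len(K)) {
        g <- stats::rgamma(length(block[[k]]), config$topic_word_concentration)
        phi[k, block[[k]]] <- g / sum(g)
      }
    } else {
      for (k in seq_len(K)) {
        g <- stats::rgamma(V, config$topic_word_concentration)
        phi[k, ] <- g / sum(g)
      }
    }
    label <- stats::rbinom(config$D, 1, config$class_prior)
    topic <- vapply(label, function(cl) {
      sample.int(K, 1, prob = config$topic_given_class[cl + 1L, ])
    }, integer(1))
    len <- pmax(1L, stats::rpois(config$D, config$doc_length_lambda))
    texts <- character(config$D)
    tokens <- vector("list", config$D)
    for (d in seq_len(config$D)) {
      toks <- terms[sample.int(V, len[d], replace = TRUE, prob = phi[topic[d], ])]
      tokens[[d]] <- toks
      if (config$realistic) toks <- decorate_tokens(toks)
      texts[d] <- paste(toks, collapse = " ")
    }
    docs <- as_corpus(data.frame(doc_id = sprintf("d%05d", seq_len(config$D)),
                                 text = texts, label = label,
                                 stringsAsFactors = FALSE))
    structure(list(documents = docs, true_topic = topic, true_phi = phi,
                   terms = terms, tokens = tokens, config = config),
              class = "gsm_synthetic")
  })
}

# sprinkle stopwords, punctuation, digits and capitalization between the
# informative tokens; all decoys are removed again by preprocessing
decorate_tokens <- function(toks) {
  n_extra <- stats::rpois(1, 2)
  extra <- sample(.decoys, n_extra, replace = TRUE)
  out <- sample(c(toks, extra))
  caps <- stats::runif(length(out)) < 0.2
  out[caps] <- paste0(toupper(substr(out[caps], 1, 1)),
                      substr(out[caps], 2, nchar(out[caps])))
  if (stats::runif(1) < 0.5) out <- c(out, sample(0:99, 1))
  paste0(out, ifelse(stats::runif(length(out)) < 0.1, ",", ""))
}

#' Separable benchmark corpus
#'
#' The standard test-bed: 6 true topics over a 600-term vocabulary with
#' disjoint per-topic vocabularies, 2,000 documents, balanced classes.
#' Topics 1-2 occur only under class 0 and topics 3-4 only under class 1
#' (0.45 mass each within the class); topics 5-6 are shared noise with
#' equal mass 0.05 under both classes. Class membership is therefore almost
#' determined by the topic vocabulary a document draws from, and the Bayes
#' error equals half the shared-noise mass.
#'
#' @param seed integer seed.
#' @param D number of documents (default 2000).
#' @param realistic see [generator_config()].
#' @return a `gsm_synthetic`.
#' @export
make_separable_preset <- function(seed = 1L, D = 2000L, realistic = FALSE) {
  tgc <- rbind(c(0.45, 0.45, 0, 0, 0.05, 0.05),
               c(0, 0, 0.45, 0.45, 0.05, 0.05))
  generate_dmm_corpus(generator_config(
    K_true = 6L, V = 600L, D = D, class_prior = 0.5,
    topic_given_class = tgc, doc_length_lambda = 8,
    topic_word_concentration = 1, exclusive_vocab = TRUE,
    realistic = realistic, seed = seed))
}

#' Log-likelihood of a synthetic corpus under given parameters
#'
#' Token log-likelihood `sum_d sum_{w in d} log phi[topic_d, w]`, with a
#' small smoothing floor so that mismatched parameters yield a finite
#' (very negative) value instead of -Inf. Used to sanity-check that the
#' generator's declared ground truth actually fits its output better than
#' a perturbed one.
#'
#' @param synth a `gsm_synthetic`.
#' @param phi topic-word matrix to evaluate (default: the true one).
#' @param topics per-document topic assignment (default: the true one).
#' @param smooth probability floor.
#' @return scalar log-likelihood.
#' @export
synthetic_loglik <- function(synth, phi = synth$true_phi,
                             topics = synth$true_topic, smooth = 1e-12) {
  tok <- strsplit(synth$documents$text, " ", fixed = TRUE)
  ll <- 0
  for (d in seq_along(tok)) {
    j <- match(tok[[d]], synth$terms)
    j <- j[!is.na(j)]
    ll <- ll + sum(log(pmax(phi[topics[d], j], smooth)))
  }
  ll
}

#' Write a corpus (and ground truth) to disk
#'
#' Writes the corpus in the same TSV dialect [read_corpus()] consumes
#' (columns `id`, `text`, `label`), plus an optional ground-truth sidecar
#' (`doc_id`, `class`, `true_topic`) for synthetic corpora.
#'
#' @param corpus a corpus data frame or a `gsm_synthetic`.
#' @param path output TSV path.
#' @param ground_truth_path optional sidecar path (synthetic input only).
#' @export
write_corpus <- function(corpus, path, ground_truth_path = NULL) {
  synth <- NULL
  if (inherits(corpus, "gsm_synthetic")) {
    synth <- corpus
    corpus <- corpus$documents
  }
  df <- data.frame(id = corpus$doc_id, text = corpus$text,
                   label = corpus$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ground_truth_path)) {
    if (is.null(synth)) {
      stop("ground truth is only available for synthetic corpora",
           call. = FALSE)
    }
    gt <- data.frame(doc_id = synth$documents$doc_id,
                     class = synth$documents$label,
                     true_topic = synth$true_topic)
    utils::write.table(gt, ground_truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
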