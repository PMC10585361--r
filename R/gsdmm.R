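#' Fit a Dirichlet-multinomial mixture by collapsed Gibbs sampling (GSDMM)
#'
#' Each document is assigned to exactly one latent topic (mixture of
#' unigrams). Starting from a seeded uniform-random assignment, every sweep
#' visits documents in index order, removes the document's counts from its
#' cluster and resamples the cluster from the collapsed conditional
#' \deqn{p(z_d = k \mid \cdot) \propto (m_k^{-d} + \alpha)
#'   \frac{\prod_{w \in d} \prod_{j=1}^{c_{dw}} (n_{kw}^{-d} + \beta + j - 1)}
#'        {\prod_{i=1}^{N_d} (n_k^{-d} + V\beta + i - 1)},}
#' evaluated in log space. The final-sweep state is the point estimate.
#'
#' @param bow a `gsm_bow` in `"count"` weighting.
#' @param K number of topics (clusters), >= 1.
#' @param alpha Dirichlet prior on cluster proportions (> 0).
#' @param beta Dirichlet prior on cluster word distributions (> 0).
#' @param iterations number of full Gibbs sweeps (>= 0).
#' @param seed integer seed; identical seeds give identical fits.
#' @param check_invariants verify the count identities after every sweep
#'   (sum of cluster document counts = D; per-cluster word counts sum to the
#'   cluster token total; token totals conserved).
#' @param record_sweeps after `iterations` sweeps, run this many additional
#'   recorded sweeps and keep the assignment configuration code after each
#'   (for sampler validation; requires `K^D` below 2^31).
#' @return an object of class `gsdmm_fit`: list with `K`, `alpha`, `beta`,
#'   `V`, `D`, `z` (1-based cluster per document), `m`, `n_k`, `n_kw`
#'   (K x V count matrix), `terms`, `doc_ids`, `seed`,
#'   `invariant_violations`, `codes`.
#' @export
fit_gsdmm <- function(bow, K, alpha = 0.1, beta = 0.01, iterations = 1000L,
                      seed = 1L, check_invariants = FALSE,
                      record_sweeps = 0L) {
  if (!inherits(bow, "gsm_bow") || bow$weighting != "count") {
    stop("fit_gsdmm requires a count-mode gsm_bow", call. = FALSE)
  }
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0", call. = FALSE)
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)

  docs <- bow_to_doclists(bow)
  D <- length(docs$ids)
  V <- ncol(bow$values)
  n_empty <- sum(vapply(docs$ids, length, integer(1)) == 0)
  if (n_empty > 0) {
    warning(n_empty, " document(s) have no in-vocabulary tokens; ",
            "they are assigned by the cluster-size prior only")
  }
  if (record_sweeps > 0 && K^D >= 2^31) {
    stop("record_sweeps requires K^D < 2^31", call. = FALSE)
  }

  res <- with_local_seed(seed, {
    z0 <- sample.int(K, D, replace = TRUE) - 1L
    gsdmm_gibbs_cpp(docs$ids, docs$cnts, V, K, alpha, beta,
                    as.integer(iterations), z0,
                    isTRUE(check_invariants), as.integer(record_sweeps))
  })

  n_kw <- res$n_kw
  dimnames(n_kw) <- list(paste0("topic_", seq_len(K)), bow$vocab$terms)
  structure(list(K = K, alpha = alpha, beta = beta, V = V, D = D,
                 z = res$z + 1L, m = res$m, n_k = res$n_k, n_kw = n_kw,
                 terms = bow$vocab$terms, doc_ids = bow$doc_ids,
                 labels = bow$labels, seed = seed,
                 invariant_violations = res$invariant_violations,
                 codes = res$codes),
            class = "gsdmm_fit")
}

#' @exportS3Method base::print
print.gsdmm_fit <- function(x, ...) {
  cat("<gsdmm_fit> K=", x$K, " D=", x$D, " V=", x$V,
      " alpha=", x$alpha, " beta=", x$beta, "\n", sep = "")
  cat("  cluster sizes: ", paste(x$m, collapse = " "), "\n", sep = "")
  invisible(x)
}

# sparse count matrix -> per-document 0-based term-id and count lists
bow_to_doclists <- function(bow) {
  tr <- Matrix::summary(bow$values)
  D <- nrow(bow$values)
  ids <- vector("list", D)
  cnts <- vector("list", D)
  for (d in seq_len(D)) { ids[[d]] <- integer(0); cnts[[d]] <- integer(0) }
  if (nrow(tr) > 0) {
    sp_i <- split(tr$j, tr$i)
    sp_x <- split(tr$x, tr$i)
    for (nm in names(sp_i)) {
      d <- as.integer(nm)
      ids[[d]] <- as.integer(sp_i[[nm]]) - 1L
      cnts[[d]] <- as.integer(sp_x[[nm]])
    }
  }
  list(ids = ids, cnts = cnts)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Extract the topic-word matrix (top terms per topic)
#'
#' The posterior-mean word distribution of cluster k is
#' `phi[k, w] = (n_kw + beta) / (n_k + V beta)`; for each topic the `m`
#' highest-phi terms are returned, ties broken by vocabulary index. An empty
#' cluster yields the uniform distribution `1/V`, so its top terms are the
#' first `m` vocabulary terms.
#'
#' @param state a `gsdmm_fit`.
#' @param m number of words per topic (>= 1).
#' @return an object of class `gsm_topics`: list with `topics` (list of
#'   data frames `term`, `phi`, ordered by phi descending), `K`, `m`.
#' @export
extract_topic_word <- function(state, m = 20L) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  phi <- sweep(state$n_kw + state$beta, 1,
               state$n_k + state$V * state$beta, "/")
  topics <- lapply(seq_len(state$K), function(k) {
    ord <- order(-phi[k, ], seq_len(state$V))[seq_len(min(m, state$V))]
    data.frame(term = state$terms[ord], phi = phi[k, ord],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  structure(list(topics = topics, K = state$K, m = as.integer(m)),
            class = "gsm_topics")
}

#' @exportS3Method base::print
print.gsm_topics <- function(x, n = 5, ...) {
  cat("<gsm_topics> K=", x$K, ", up to ", x$m, " terms per topic\n", sep = "")
  for (k in seq_len(min(n, x$K))) {
    cat("  topic ", k, ": ",
        paste(utils::head(x$topics[[k]]$term, 8), collapse = " "), "\n",
        sep = "")
  }
  if (x$K > n) cat("  ...\n")
  invisible(x)
}

#' Per-topic term lists of a topic-word matrix
#' @param tw a `gsm_topics`.
#' @return list of character vectors, one per topic.
#' @export
topic_terms <- function(tw) lapply(tw$topics, function(t) t$term)

#' Posterior topic distribution of one document
#'
#' Evaluates the collapsed conditional used by the sampler and normalizes it
#' into a probability vector. For a training document (`held_in = TRUE`) the
#' document's own counts are first removed from its cluster, which requires
#' `doc_index`; an unseen document (`held_in = FALSE`) is scored against the
#' counts as they stand. A document with no in-vocabulary terms falls back to
#' the cluster-size prior `(m_k + alpha)`, normalized.
#'
#' @param state a `gsdmm_fit`.
#' @param doc either a numeric count vector of length `V` or a character
#'   vector of terms (out-of-vocabulary terms dropped).
#' @param held_in logical; remove the document's own counts first.
#' @param doc_index training-document row index, required when
#'   `held_in = TRUE`.
#' @return numeric probability vector of length `K` (sums to 1).
#' @export
doc_topic_posterior <- function(state, doc, held_in = FALSE,
                                doc_index = NULL) {
  if (is.character(doc)) {
    idx <- match(doc, state$terms)
    idx <- idx[!is.na(idx)]
    cnt <- table(idx)
    ids <- as.integer(names(cnt))
    cv <- as.numeric(cnt)
  } else {
    if (length(doc) != state$V) {
      stop("count vector length must equal V", call. = FALSE)
    }
    ids <- which(doc > 0)
    cv <- as.numeric(doc[ids])
  }

  m <- state$m
  n_k <- state$n_k
  n_kw_d <- if (length(ids) > 0) state$n_kw[, ids, drop = FALSE] else NULL

  if (held_in) {
    if (is.null(doc_index)) {
      stop("held_in = TRUE requires doc_index", call. = FALSE)
    }
    k0 <- state$z[doc_index]
    m[k0] <- m[k0] - 1
    n_k[k0] <- n_k[k0] - sum(cv)
    if (length(ids) > 0) n_kw_d[k0, ] <- n_kw_d[k0, ] - cv
  }

  if (length(ids) == 0) {
    warning("document has no in-vocabulary terms; using cluster-size prior")
    p <- m + state$alpha
    return(p / sum(p))
  }

  N <- sum(cv)
  vb <- state$V * state$beta
  # log of prod_j (n_kw + beta + j - 1) via lgamma ratios, per cluster
  num <- rowSums(lgamma(sweep(n_kw_d + state$beta, 2, cv, "+")) -
                   lgamma(n_kw_d + state$beta))
  den <- lgamma(n_k + vb + N) - lgamma(n_k + vb)
  lw <- log(m + state$alpha) + num - den
  p <- exp(lw - max(lw))
  p / sum(p)
}

#' Document-topic distribution matrix
#'
#' Applies [doc_topic_posterior()] to every row of a bag-of-words matrix.
#' With `held_in = TRUE` the rows must be the training documents of `state`,
#' in training order.
#'
#' @param state a `gsdmm_fit`.
#' @param bow a `gsm_bow` in count mode over the training vocabulary.
#' @param held_in logical, see [doc_topic_posterior()].
#' @return numeric matrix (documents x K), rows summing to 1; row names are
#'   document ids, columns `topic_1..topic_K`.
#' @export
extract_doc_topic <- function(state, bow, held_in = FALSE) {
  if (!inherits(bow, "gsm_bow")) stop("bow must be a gsm_bow", call. = FALSE)
  if (ncol(bow$values) != state$V) {
    stop("bow vocabulary does not match the fitted model", call. = FALSE)
  }
  D <- nrow(bow$values)
  if (held_in && D != state$D) {
    stop("held_in = TRUE requires the training rows of the fitted model",
         call. = FALSE)
  }
  x <- as.matrix(bow$values)
  td <- matrix(0, D, state$K,
               dimnames = list(bow$doc_ids, paste0("topic_", seq_len(state$K))))
  n_oov <- 0L
  for (d in seq_len(D)) {
    td[d, ] <- withCallingHandlers(
      doc_topic_posterior(state, x[d, ], held_in = held_in,
                          doc_index = if (held_in) d else NULL),
      warning = function(w) {
        n_oov <<- n_oov + 1L
        invokeRestart("muffleWarning")
      })
  }
  if (n_oov > 0) {
    warning(n_oov, " document(s) had no in-vocabulary terms; ",
            "their rows use the cluster-size prior")
  }
  td
}

#' Exact assignment posterior by enumeration
#'
#' Enumerates all `K^D` cluster assignments of a small corpus and computes
#' the exact posterior from the Dirichlet-multinomial marginal likelihood
#' \deqn{p(z) \propto \prod_k \Gamma(m_k + \alpha)
#'   \prod_k \frac{\Gamma(V\beta)}{\Gamma(n_k + V\beta)}
#'   \prod_w \frac{\Gamma(n_{kw} + \beta)}{\Gamma(\beta)}.}
#' This brute-force enumeration is independent of the Gibbs sampler and
#' serves to validate it on corpora small enough to enumerate.
#'
#' @param bow a `gsm_bow` in count mode with few documents (`K^D` must be
#'   manageable).
#' @param K,alpha,beta model parameters as in [fit_gsdmm()].
#' @return numeric probability vector of length `K^D`; entry `i` is the
#'   posterior mass of the assignment with code `i - 1`, where a code is
#'   `sum_d z_d K^d` over 0-based cluster labels.
#' @export
gsdmm_exact_posterior <- function(bow, K, alpha = 0.1, beta = 0.01) {
  if (!inherits(bow, "gsm_bow") || bow$weighting != "count") {
    stop("gsdmm_exact_posterior requires a count-mode gsm_bow", call. = FALSE)
  }
  x <- as.matrix(bow$values)
  D <- nrow(x)
  V <- ncol(x)
  ncfg <- K^D
  if (ncfg > 2^20) stop("K^D too large to enumerate", call. = FALSE)
  logp <- numeric(ncfg)
  for (code in 0:(ncfg - 1)) {
    rest <- code
    z <- integer(D)
    for (d in seq_len(D)) {
      z[d] <- rest %% K
      rest <- rest %/% K
    }
    lp <- 0
    for (k in 0:(K - 1)) {
      rows <- which(z == k)
      m_k <- length(rows)
      n_kw <- if (m_k > 0) colSums(x[rows, , drop = FALSE]) else numeric(V)
      n_k <- sum(n_kw)
      lp <- lp + lgamma(m_k + alpha) +
        lgamma(V * beta) - lgamma(n_k + V * beta) +
        sum(lgamma(n_kw + beta) - lgamma(beta))
    }
    logp[code + 1] <- lp
  }
  p <- exp(logp - max(logp))
  p / sum(p)
}

#' Validate the Gibbs sampler against the enumerated posterior
#'
#' Generates a suite of random miniature corpora (few documents over a tiny
#' vocabulary), runs the sampler on each with a long recorded chain and
#' compares the empirical assignment distribution with the exact enumerated
#' posterior from [gsdmm_exact_posterior()], as total variation distance.
#'
#' Because the mixture likelihood is invariant under permutation of the
#' cluster labels, the assignment posterior is only identified up to label
#' permutation, and a finite chain swaps between the K! mirror modes rarely.
#' The comparison is therefore taken over label-permutation equivalence
#' classes (for K = 2, assignment codes folded with their complements);
#' the folded total variation measures sampler correctness without being
#' dominated by label-switching frequency.
#'
#' @param n_corpora number of random corpora in the suite.
#' @param K number of clusters (2 keeps enumeration and folding cheap).
#' @param alpha,beta priors used for both sampler and enumeration.
#' @param burnin discarded initial sweeps per corpus.
#' @param sweeps recorded post-burn-in sweeps per corpus.
#' @param max_docs,max_vocab,max_len corpus size caps for the generator.
#' @param seed integer seed for the whole suite.
#' @return data frame with one row per corpus: `D`, `V`, `tv` (folded
#'   total variation).
#' @export
validate_sampler_exactness <- function(n_corpora = 20L, K = 2L,
                                       alpha = 0.1, beta = 0.01,
                                       burnin = 2000L, sweeps = 20000L,
                                       max_docs = 8L, max_vocab = 6L,
                                       max_len = 4L, seed = 1L) {
  if (K != 2L) stop("folding is implemented for K = 2", call. = FALSE)
  out <- data.frame(D = integer(n_corpora), V = integer(n_corpora),
                    tv = numeric(n_corpora))
  for (i in seq_len(n_corpora)) {
    cseed <- derive_seed(seed, i)
    toks <- with_local_seed(cseed, {
      D <- sample(4:max_docs, 1)
      V <- sample(3:max_vocab, 1)
      lapply(seq_len(D), function(d) {
        sprintf("t%d", sample.int(V, sample.int(max_len, 1), replace = TRUE))
      })
    })
    vocab <- build_vocabulary(toks, 1)
    bow <- build_bow(toks, vocab, "count")
    D <- length(toks)
    exact <- gsdmm_exact_posterior(bow, K = K, alpha = alpha, beta = beta)
    fit <- fit_gsdmm(bow, K = K, alpha = alpha, beta = beta,
                     iterations = burnin, seed = derive_seed(seed, i, 2),
                     record_sweeps = sweeps)
    emp <- tabulate(fit$codes + 1L, nbins = length(exact)) / sweeps
    n <- length(exact)
    class_id <- pmin(seq_len(n), n:1)
    fold <- function(p) tapply(p, class_id, sum)
    out$D[i] <- D
    out$V[i] <- length(vocab$terms)
    out$tv[i] <- 0.5 * sum(abs(fold(emp) - fold(exact)))
  }
  out
}
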