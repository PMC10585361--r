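#' Construct a topic-word matrix from term lists
#'
#' Builds a `gsm_topics` object directly from per-topic term vectors, e.g.
#' ground-truth topics of a synthetic corpus or externally selected term
#' sets. Probabilities may be omitted.
#'
#' @param term_lists list of character vectors, one per topic.
#' @param phi_lists optional list of numeric vectors aligned with
#'   `term_lists`.
#' @return a `gsm_topics` object.
#' @export
topics_from_terms <- function(term_lists, phi_lists = NULL) {
  K <- length(term_lists)
  topics <- lapply(seq_len(K), function(k) {
    terms <- as.character(term_lists[[k]])
    phi <- if (is.null(phi_lists)) rep(NA_real_, length(terms))
           else as.numeric(phi_lists[[k]])
    data.frame(term = terms, phi = phi, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  m <- max(vapply(topics, nrow, integer(1)), 0L)
  structure(list(topics = topics, K = K, m = as.integer(m)),
            class = "gsm_topics")
}

#' Write a topic-word matrix as text
#'
#' One line per topic: `k<TAB>term1:phi1 term2:phi2 ...` (probabilities
#' omitted when unknown, giving `k<TAB>term1 term2 ...`). Round-trips with
#' [import_topic_artifacts()].
#'
#' @param tw a `gsm_topics`.
#' @param path output file path.
#' @param probs include `term:prob` annotations when available.
#' @export
write_topic_word <- function(tw, path, probs = TRUE) {
  lines <- vapply(seq_len(tw$K), function(k) {
    t <- tw$topics[[k]]
    body <- if (probs && !all(is.na(t$phi))) {
      paste(sprintf("%s:%.10g", t$term, t$phi), collapse = " ")
    } else {
      paste(t$term, collapse = " ")
    }
    paste0(k - 1L, "\t", body)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a document-topic matrix as text
#'
#' Whitespace-delimited dense matrix, optionally with the document id as
#' first column.
#'
#' @param td numeric matrix (documents x K) with document-id row names.
#' @param path output file path.
#' @param doc_id_column write row names as a first column.
#' @export
write_doc_topic <- function(td, path, doc_id_column = FALSE) {
  if (doc_id_column) {
    df <- data.frame(doc_id = rownames(td), td, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(td, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Import externally computed topic-model artifacts
#'
#' Reads a topic-word file (one topic per line, `k<TAB>term term ...` or
#' `k<TAB>term:prob ...`; a `k:` prefix with a colon is also accepted) and a
#' document-topic file (whitespace-delimited D x K matrix, optionally with a
#' document-id first column). This is the interoperability hook for topic
#' models trained outside the package (e.g. BTM, PTM, WNTM toolkits): the
#' selector only needs the two byproducts TW and TD, not the sampler.
#'
#' TD rows must be nonnegative; rows whose sum is within `1e-3` of 1 are
#' renormalized, anything further off is an error. TW terms missing from the
#' supplied vocabulary are retained but flagged in the `oov_terms` attribute.
#'
#' @param tw_path path to the topic-word file.
#' @param td_path path to the document-topic file.
#' @param vocab optional `gsm_vocabulary` used to flag out-of-vocabulary
#'   terms.
#' @param n_docs optional expected number of documents; mismatch is an
#'   error.
#' @return list with `tw` (a `gsm_topics`, `oov_terms` attribute listing
#'   unknown terms) and `td` (numeric matrix, rows renormalized to sum 1).
#' @export
import_topic_artifacts <- function(tw_path, td_path, vocab = NULL,
                                   n_docs = NULL) {
  tw_lines <- readLines(tw_path)
  tw_lines <- tw_lines[nzchar(trimws(tw_lines))]
  if (length(tw_lines) == 0) stop("empty topic-word file", call. = FALSE)

  term_lists <- vector("list", length(tw_lines))
  phi_lists <- vector("list", length(tw_lines))
  any_phi <- FALSE
  for (i in seq_along(tw_lines)) {
    line <- sub("^[0-9]+[:\t ]+", "", tw_lines[i])
    toks <- strsplit(trimws(line), "[ \t]+")[[1]]
    has_phi <- grepl(":", toks, fixed = TRUE)
    terms <- sub(":.*$", "", toks)
    phi <- rep(NA_real_, length(toks))
    phi[has_phi] <- suppressWarnings(
      as.numeric(sub("^.*:", "", toks[has_phi])))
    term_lists[[i]] <- terms
    phi_lists[[i]] <- phi
    if (any(has_phi)) any_phi <- TRUE
  }
  tw <- topics_from_terms(term_lists, if (any_phi) phi_lists else NULL)

  td_raw <- utils::read.table(td_path, header = FALSE,
                              stringsAsFactors = FALSE)
  doc_ids <- NULL
  if (!is.numeric(td_raw[[1]])) {
    doc_ids <- as.character(td_raw[[1]])
    td_raw <- td_raw[, -1, drop = FALSE]
  }
  td <- as.matrix(td_raw)
  if (!is.numeric(td)) stop("document-topic file is not numeric", call. = FALSE)
  if (ncol(td) != tw$K) {
    stop("document-topic matrix has ", ncol(td), " columns but the ",
         "topic-word file defines ", tw$K, " topics", call. = FALSE)
  }
  if (!is.null(n_docs) && nrow(td) != n_docs) {
    stop("document-topic matrix has ", nrow(td), " rows; corpus has ",
         n_docs, " documents", call. = FALSE)
  }
  if (any(td < 0)) stop("negative document-topic entries", call. = FALSE)
  rs <- rowSums(td)
  if (any(abs(rs - 1) > 1e-3)) {
    bad <- which(abs(rs - 1) > 1e-3)
    stop("document-topic rows do not sum to 1 (first offender: row ",
         bad[1], ", sum ", format(rs[bad[1]]), ")", call. = FALSE)
  }
  td <- td / rs
  rownames(td) <- if (!is.null(doc_ids)) doc_ids else as.character(seq_len(nrow(td)))
  colnames(td) <- paste0("topic_", seq_len(ncol(td)))

  oov <- character(0)
  if (!is.null(vocab)) {
    all_terms <- unique(unlist(term_lists, use.names = FALSE))
    oov <- setdiff(all_terms, vocab$terms)
    if (length(oov) > 0) {
      warning(length(oov), " imported topic term(s) are not in the ",
              "vocabulary; they are retained but flagged")
    }
  }
  attr(tw, "oov_terms") <- oov
  list(tw = tw, td = td)
}
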