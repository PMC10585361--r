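#' Read a labeled short-text corpus from a delimited file
#'
#' Reads a delimited text file with one document per row and returns a corpus
#' data frame with columns `doc_id`, `text`, `label`. Labels are mapped to the
#' binary coding {0, 1}; non-numeric label sets require an explicit
#' `label_map` naming the positive and negative classes.
#'
#' @param path path to a delimited UTF-8 text file with a header row.
#' @param sep field separator (default tab).
#' @param col_id,col_text,col_label column names holding the document
#'   identifier, the text and the class label.
#' @param label_map optional named vector mapping raw label values to 0/1,
#'   e.g. `c("non-DILI" = 0, "DILI" = 1)`. Not needed when labels are already
#'   0/1.
#' @return a data frame of class `gsm_corpus` with columns
#'   `doc_id` (character), `text` (character), `label` (integer 0/1),
#'   one row per document, in file order.
#' @export
read_corpus <- function(path, sep = "\t", col_id = "id", col_text = "text",
                        col_label = "label", label_map = NULL) {
  if (!file.exists(path)) {
    stop("corpus file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           fileEncoding = "UTF-8", check.names = FALSE)
  for (col in c(col_id, col_text, col_label)) {
    if (!col %in% names(raw)) {
      stop("corpus file lacks required column '", col, "'", call. = FALSE)
    }
  }
  if (nrow(raw) == 0) {
    warning("corpus file has a header but no documents: ", path)
    return(as_corpus(data.frame(doc_id = character(0), text = character(0),
                                label = integer(0))))
  }
  ids <- as.character(raw[[col_id]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate document ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  labels <- map_labels(raw[[col_label]], label_map)
  as_corpus(data.frame(doc_id = ids, text = as.character(raw[[col_text]]),
                       label = labels, stringsAsFactors = FALSE))
}

#' @keywords internal
map_labels <- function(values, label_map = NULL) {
  vals <- as.character(values)
  if (!is.null(label_map)) {
    unknown <- setdiff(unique(vals), names(label_map))
    if (length(unknown) > 0) {
      stop("labels not covered by label_map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out <- as.integer(label_map[vals])
  } else {
    u <- unique(vals)
    if (!all(u %in% c("0", "1"))) {
      stop("label set {", paste(sort(u), collapse = ", "),
           "} is not binary 0/1; supply a label_map", call. = FALSE)
    }
    out <- as.integer(vals)
  }
  if (!all(out %in% c(0L, 1L))) {
    stop("label_map must map onto {0, 1}; got values ",
         paste(sort(unique(out)), collapse = ", "), call. = FALSE)
  }
  out
}

as_corpus <- function(df) {
  class(df) <- c("gsm_corpus", "data.frame")
  df
}

#' Default English stopword list
#'
#' Returns the standard English stopword list shipped with the package. A
#' custom list can be supplied to [preprocess_document()] instead.
#'
#' @return character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_english.txt", package = "gsmtopics")
  readLines(path, encoding = "UTF-8")
}

#' Normalize and tokenize one text
#'
#' Applies, in order: case folding; replacement of every non-alphabetic
#' character (punctuation, digits, symbols) by a space; whitespace
#' tokenization; removal of tokens shorter than 3 characters; stopword
#' removal; Snowball (Porter2) stemming. The length filter applies before
#' stemming, so stems that come out shorter than 3 characters are retained.
#'
#' @param text a character scalar (free text).
#' @param stopwords character vector of stopwords to drop (matched after
#'   case folding, before stemming).
#' @param stem logical; apply Snowball stemming (default TRUE).
#' @return character vector of normalized tokens (possibly empty).
#' @examples
#' preprocess_document("Drug-Induced Liver Injury: 2 Case Reports")
#' @export
preprocess_document <- function(text, stopwords = default_stopwords(),
                                stem = TRUE) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("[^a-z]+", " ", x)
  toks <- strsplit(trimws(x), "[ ]+")[[1]]
  toks <- toks[nchar(toks) >= 3L]
  toks <- toks[!toks %in% stopwords]
  if (length(toks) == 0) return(character(0))
  if (stem) toks <- snowball_stem(toks)
  toks
}

#' Tokenize a whole corpus
#'
#' Applies [preprocess_document()] to every document, or plain whitespace
#' splitting when `preprocess = FALSE` (for inputs that are already
#' normalized, such as synthetic corpora with machine-generated terms).
#'
#' @param corpus a corpus data frame from [read_corpus()] (columns `doc_id`,
#'   `text`, `label`).
#' @param preprocess logical; apply the full normalization pipeline.
#' @param stopwords,stem passed to [preprocess_document()].
#' @return a list with `doc_id`, `tokens` (list of character vectors) and
#'   `label`, of class `gsm_tokens`.
#' @export
tokenize_corpus <- function(corpus, preprocess = TRUE,
                            stopwords = default_stopwords(), stem = TRUE) {
  tokens <- if (preprocess) {
    lapply(corpus$text, preprocess_document, stopwords = stopwords, stem = stem)
  } else {
    lapply(strsplit(corpus$text, "[ \t]+"), function(t) t[nzchar(t)])
  }
  structure(list(doc_id = corpus$doc_id, tokens = tokens,
                 label = corpus$label),
            class = "gsm_tokens")
}

#' Build a vocabulary with a minimum-frequency cutoff
#'
#' Collects the terms of a tokenized corpus whose frequency reaches
#' `min_corpus_frequency`, in first-occurrence order. Frequency is counted
#' either as total corpus term frequency (default) or as document frequency.
#' A threshold of 1 disables the filter.
#'
#' @param tokens a `gsm_tokens` object from [tokenize_corpus()], or a plain
#'   list of character vectors.
#' @param min_corpus_frequency integer >= 1; terms below this frequency are
#'   dropped.
#' @param count one of `"term"` (total occurrences) or `"document"`
#'   (number of documents containing the term).
#' @return an object of class `gsm_vocabulary`: a list with `terms`
#'   (character, first-occurrence order) and `index` (named integer,
#'   term -> 1-based position).
#' @export
build_vocabulary <- function(tokens, min_corpus_frequency = 1L,
                             count = c("term", "document")) {
  count <- match.arg(count)
  if (min_corpus_frequency < 1) {
    stop("min_corpus_frequency must be >= 1", call. = FALSE)
  }
  tok_list <- if (inherits(tokens, "gsm_tokens")) tokens$tokens else tokens
  if (length(tok_list) == 0) {
    warning("empty document list; returning empty vocabulary")
    return(new_vocabulary(character(0)))
  }
  flat <- unlist(lapply(tok_list, if (count == "document") unique else identity),
                 use.names = FALSE)
  if (length(flat) == 0) {
    warning("no tokens in corpus; returning empty vocabulary")
    return(new_vocabulary(character(0)))
  }
  first_seen <- unique(unlist(tok_list, use.names = FALSE))
  freq <- table(factor(flat, levels = first_seen))
  keep <- first_seen[as.vector(freq) >= min_corpus_frequency]
  new_vocabulary(keep)
}

new_vocabulary <- function(terms) {
  idx <- seq_along(terms)
  names(idx) <- terms
  structure(list(terms = terms, index = idx), class = "gsm_vocabulary")
}

#' @exportS3Method base::print
print.gsm_vocabulary <- function(x, ...) {
  cat("<gsm_vocabulary> ", length(x$terms), " terms\n", sep = "")
  if (length(x$terms) > 0) {
    cat("  ", paste(utils::head(x$terms, 8), collapse = " "),
        if (length(x$terms) > 8) " ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Build a bag-of-words matrix
#'
#' Projects tokenized documents onto a vocabulary, producing a sparse
#' document-by-term matrix either of raw counts or of relative term
#' frequencies. In relative mode each count is divided by the document's
#' in-vocabulary token total by default, so every row with at least one
#' in-vocabulary token sums to 1; `denominator = "raw"` divides by the full
#' token count instead.
#'
#' @param tokens a `gsm_tokens` object or list of character vectors.
#' @param vocab a `gsm_vocabulary`.
#' @param weighting `"count"` or `"relative_tf"`.
#' @param denominator for `relative_tf`: `"in_vocab"` (default) or `"raw"`.
#' @return an object of class `gsm_bow`: list with `values` (a
#'   `Matrix::dgCMatrix`, documents x terms), `doc_ids`, `vocab`,
#'   `weighting`, `labels` (or NULL).
#' @export
build_bow <- function(tokens, vocab, weighting = c("count", "relative_tf"),
                      denominator = c("in_vocab", "raw")) {
  weighting <- match.arg(weighting)
  denominator <- match.arg(denominator)
  if (length(vocab$terms) == 0) stop("vocabulary is empty", call. = FALSE)
  tok_list <- if (inherits(tokens, "gsm_tokens")) tokens$tokens else tokens
  doc_ids <- if (inherits(tokens, "gsm_tokens")) tokens$doc_id else
    as.character(seq_along(tok_list))
  labels <- if (inherits(tokens, "gsm_tokens")) tokens$label else NULL

  D <- length(tok_list)
  V <- length(vocab$terms)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  raw_len <- vapply(tok_list, length, integer(1))
  for (d in seq_len(D)) {
    id <- vocab$index[tok_list[[d]]]
    id <- id[!is.na(id)]
    if (length(id) == 0) next
    tab <- table(id)
    j <- as.integer(names(tab))
    v <- as.numeric(tab)
    if (weighting == "relative_tf") {
      den <- if (denominator == "in_vocab") sum(v) else raw_len[d]
      v <- v / den
    }
    ii <- c(ii, rep.int(d, length(j)))
    jj <- c(jj, j)
    xx <- c(xx, v)
  }
  values <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(D, V),
                                 dimnames = list(doc_ids, vocab$terms))
  structure(list(values = values, doc_ids = doc_ids, vocab = vocab,
                 weighting = weighting, labels = labels),
            class = "gsm_bow")
}

#' @exportS3Method base::print
print.gsm_bow <- function(x, ...) {
  cat("<gsm_bow> ", nrow(x$values), " docs x ", ncol(x$values), " terms (",
      x$weighting, ")\n", sep = "")
  invisible(x)
}

#' Write a vocabulary to a text file (one term per line)
#' @param vocab a `gsm_vocabulary`.
#' @param path output file path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$terms, path)
  invisible(path)
}

#' Write a bag-of-words matrix as TSV
#'
#' Sparse format is a triplet table `doc_id, term, value`; dense format is a
#' full document-by-term table with a `doc_id` first column.
#'
#' @param bow a `gsm_bow`.
#' @param path output file path.
#' @param format `"sparse"` or `"dense"`.
#' @export
write_bow <- function(bow, path, format = c("sparse", "dense")) {
  format <- match.arg(format)
  if (format == "sparse") {
    tr <- Matrix::summary(bow$values)
    df <- data.frame(doc_id = bow$doc_ids[tr$i],
                     term = bow$vocab$terms[tr$j],
                     value = tr$x)
    df <- df[order(match(df$doc_id, bow$doc_ids), df$term), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- as.data.frame(as.matrix(bow$values))
    df <- cbind(doc_id = bow$doc_ids, df)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
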