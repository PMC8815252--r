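#' @noRd
make_ngrams <- function(tokens, n_range = 1:3) {
  if (length(tokens) == 0) return(character())
  out <- lapply(n_range, function(n) {
    if (length(tokens) < n) return(character())
    idx <- seq_len(length(tokens) - n + 1)
    vapply(idx, function(i) paste(tokens[i:(i + n - 1)], collapse = " "),
           character(1))
  })
  unlist(out)
}

#' Fit a TF-IDF model on a guideline corpus
#'
#' Builds an n-gram vocabulary (unigrams, bigrams and trigrams by default)
#' over the raw document bodies — cleaned of stop words and punctuation but
#' not lemmatized — and computes smoothed inverse-document-frequency
#' weights:
#'
#' \deqn{idf(t) = \ln\frac{1 + N}{1 + df_t} + 1}
#'
#' where \eqn{N} is the number of documents and \eqn{df_t} the number of
#' documents containing n-gram \eqn{t}.  Per-document weights are raw term
#' counts times idf, length-normalized to unit Euclidean norm.
#'
#' @param corpus A `guideline_corpus` with at least 2 documents.
#' @param ngram Integer vector of n-gram orders, default `1:3`.
#' @param stopwords Stop words removed before n-gram extraction.
#' @return A `tfidf_model`: list with `vocabulary` (n-gram -> column index),
#'   `idf`, `n_documents`, `doc_ids`, `ngram`, and the per-document token
#'   lists needed to recompute document weight vectors.
#' @export
fit_tfidf <- function(corpus, ngram = 1:3, stopwords = default_stopwords()) {
  if (nrow(corpus) < 2) {
    abort("TF-IDF fitting needs a corpus of at least 2 documents")
  }
  doc_tokens <- lapply(corpus$body, tokenize_and_clean, stopwords = stopwords)
  empty <- vapply(doc_tokens, length, 0L) == 0
  if (all(empty)) {
    abort("every document body is empty after cleaning")
  }
  if (any(empty)) {
    warn(paste0(
      "document body empty after cleaning (zero feature vector): ",
      paste(corpus$doc_id[empty], collapse = ", ")
    ))
  }
  doc_ngrams <- lapply(doc_tokens, make_ngrams, n_range = ngram)
  vocab <- sort(unique(unlist(doc_ngrams)))
  df <- table(factor(
    unlist(lapply(doc_ngrams, unique)), levels = vocab
  ))
  n_docs <- nrow(corpus)
  idf <- log((1 + n_docs) / (1 + as.numeric(df))) + 1
  structure(
    list(
      vocabulary = setNames(seq_along(vocab), vocab),
      idf = setNames(idf, vocab),
      n_documents = n_docs,
      doc_ids = corpus$doc_id,
      ngram = as.integer(ngram),
      doc_ngrams = setNames(doc_ngrams, corpus$doc_id)
    ),
    class = "tfidf_model"
  )
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat("<tfidf_model> ", length(x$vocabulary), " n-grams (orders ",
      paste(x$ngram, collapse = ","), ") over ", x$n_documents,
      " documents\n", sep = "")
  invisible(x)
}

# unit-norm tf-idf weights for one fitted document, as a named vector over
# the document's own n-grams
doc_weights <- function(model, doc_id) {
  ngrams <- model$doc_ngrams[[doc_id]]
  if (is.null(ngrams)) {
    abort(paste0("document not in fitted corpus: ", doc_id))
  }
  tf <- table(ngrams)
  w <- as.numeric(tf) * model$idf[names(tf)]
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) w <- w / nrm
  setNames(as.numeric(w), names(tf))
}

#' Top-weighted TF-IDF features of one document
#'
#' The k highest-weight n-grams of a fitted document, in descending weight
#' order, ties broken lexicographically by n-gram so indexes are
#' reproducible.  If the document has fewer than `k` nonzero-weight n-grams,
#' all of them are returned.
#'
#' @param model A fitted [fit_tfidf()] model.
#' @param doc_id Identifier of a document the model was fitted on.
#' @param k Number of features requested (default 50).
#' @return Tibble with columns `doc_id`, `rank`, `ngram`, `weight`,
#'   weights descending.
#' @export
top_features <- function(model, doc_id, k = 50) {
  stopifnot(k >= 1)
  w <- doc_weights(model, doc_id)
  if (length(w) == 0) {
    return(tibble(doc_id = character(), rank = integer(),
                  ngram = character(), weight = numeric()))
  }
  ord <- order(-w, names(w))
  n_keep <- min(k, length(w))
  idx <- ord[seq_len(n_keep)]
  tibble(
    doc_id = doc_id,
    rank = seq_len(n_keep),
    ngram = names(w)[idx],
    weight = as.numeric(w[idx])
  )
}

#' Join a feature set into embedding-ready text
#'
#' The text handed to the embedding backend for the TF-IDF view of a
#' document: the n-grams joined by single spaces in rank order.  An empty
#' feature set yields `""`, which embeds to the zero vector.
#'
#' @param features Tibble from [top_features()].
#' @return A single string.
#' @export
feature_text <- function(features) {
  paste(features$ngram, collapse = " ")
}

#' Persist or restore a TF-IDF model as JSON
#'
#' Writes vocabulary, idf weights, document ids and per-document n-gram
#' lists so an index can be rebuilt identically.
#'
#' @param model A `tfidf_model`.
#' @param path JSON file path.
#' @return The model (invisibly for write; restored for read).
#' @export
write_tfidf <- function(model, path) {
  jsonlite::write_json(
    list(
      vocabulary = as.list(model$vocabulary),
      idf = as.list(model$idf),
      n_documents = model$n_documents,
      doc_ids = model$doc_ids,
      ngram = model$ngram,
      doc_ngrams = lapply(model$doc_ngrams, as.list)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(model)
}

#' @rdname write_tfidf
#' @export
read_tfidf <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(
    list(
      vocabulary = setNames(as.integer(unlist(x$vocabulary)),
                            names(x$vocabulary)),
      idf = setNames(as.numeric(unlist(x$idf)), names(x$idf)),
      n_documents = as.integer(x$n_documents),
      doc_ids = as.character(x$doc_ids),
      ngram = as.integer(x$ngram),
      doc_ngrams = lapply(x$doc_ngrams, as.character)
    ),
    class = "tfidf_model"
  )
}
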