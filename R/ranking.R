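#' Cosine similarity between two embedding vectors
#'
#' \eqn{u \cdot v / (\lVert u\rVert \lVert v\rVert)}; defined as 0 when
#' either vector is the zero vector, so documents (or queries) with an empty
#' view stay comparable instead of propagating NaN.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 1), c(1, 0))
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    abort(paste0("dimension mismatch: ", length(u), " vs ", length(v)))
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Ranker configuration
#'
#' @param beta Nonnegative weight of the TF-IDF view in the combined score
#'   `S = H + B + beta * T`.  Default 1: the three views contribute equally.
#'   Raising `beta` emphasizes exact n-gram matching over semantic
#'   similarity, useful when queries carry little distracting language.
#' @param top_k Number of results returned by [search_guidelines()]
#'   (default 10).
#' @param lemmatize_query Lemmatize query tokens (default `FALSE`; document
#'   bodies are lemmatized at indexing time regardless).
#' @param case_sensitive_abbrev Case-sensitive abbreviation matching
#'   (default `TRUE`).
#' @return A `ranker_config` list.
#' @export
ranker_config <- function(beta = 1, top_k = 10, lemmatize_query = FALSE,
                          case_sensitive_abbrev = TRUE) {
  stopifnot(beta >= 0, top_k >= 1)
  structure(
    list(
      beta = beta, top_k = as.integer(top_k),
      lemmatize_query = isTRUE(lemmatize_query),
      case_sensitive_abbrev = isTRUE(case_sensitive_abbrev)
    ),
    class = "ranker_config"
  )
}

#' Build the three-view document index
#'
#' Each corpus document is embedded into three vectors: its header (title
#' plus variants, embedded raw), its body (cleaned and lemmatized), and the
#' text of its top `k` TF-IDF n-gram features.  Deterministic given the
#' backend: rebuilding with the same corpus, backend and model yields a
#' bit-identical index.
#'
#' @param corpus A `guideline_corpus`.
#' @param backend An `embedding_backend`.
#' @param tfidf A [fit_tfidf()] model fitted on `corpus`; fitted here when
#'   `NULL`.
#' @param k Number of TF-IDF features per document (default 50).
#' @param stopwords Stop words used for body cleaning and TF-IDF fitting.
#' @return A `document_index`: doc metadata tibble plus three row-per-document
#'   embedding matrices `H`, `B`, `T`.
#' @export
build_index <- function(corpus, backend, tfidf = NULL, k = 50,
                        stopwords = default_stopwords()) {
  stopifnot(inherits(backend, "embedding_backend"))
  if (is.null(tfidf)) {
    tfidf <- fit_tfidf(corpus, stopwords = stopwords)
  }
  n <- nrow(corpus)
  d <- backend$dimension
  H <- matrix(0, n, d)
  B <- matrix(0, n, d)
  TT <- matrix(0, n, d)
  headers <- header_text(corpus)
  for (i in seq_len(n)) {
    H[i, ] <- embed_text(backend, headers[i])
    body_tokens <- lemmatize(
      tokenize_and_clean(corpus$body[i], stopwords = stopwords)
    )
    B[i, ] <- embed_tokens(backend, body_tokens)
    feats <- top_features(tfidf, corpus$doc_id[i], k = k)
    TT[i, ] <- embed_text(backend, feature_text(feats))
  }
  rownames(H) <- rownames(B) <- rownames(TT) <- corpus$doc_id
  structure(
    list(
      docs = tibble(
        doc_id = corpus$doc_id,
        tags = corpus$tags,
        category = corpus$category
      ),
      H = H, B = B, T = TT,
      backend = backend,
      tfidf = tfidf,
      k = as.integer(k),
      stopwords = stopwords,
      tag_vocabulary = tag_vocabulary(corpus)
    ),
    class = "document_index"
  )
}

#' @export
print.document_index <- function(x, ...) {
  cat("<document_index> ", nrow(x$docs), " documents, backend '",
      x$backend$name, "' (dimension ", x$backend$dimension, "), ",
      x$k, " TF-IDF features per document\n", sep = "")
  invisible(x)
}

#' Combined ranking score of one document
#'
#' The hybrid score of document *i* for query *q*:
#' \deqn{S_i = H_{q,i} + B_{q,i} + \beta\, T_{q,i}}
#' the cosine similarities of one shared query embedding against the
#' document's header, body and TF-IDF feature vectors, with the TF-IDF term
#' weighted by `beta`.
#'
#' @param query_vec Query embedding vector.
#' @param entry List with `header_vec`, `body_vec`, `tfidf_vec` (equal
#'   dimension).
#' @param beta Nonnegative TF-IDF weight.
#' @return The score `S` (a single number).
#' @export
score_document <- function(query_vec, entry, beta = 1) {
  h <- cosine_similarity(query_vec, entry$header_vec)
  b <- cosine_similarity(query_vec, entry$body_vec)
  t_ <- cosine_similarity(query_vec, entry$tfidf_vec)
  h + b + beta * t_
}

# vectorized cosine of one query vector against a row-per-doc matrix
cosine_rows <- function(M, q) {
  qn <- sqrt(sum(q^2))
  if (qn == 0) return(numeric(nrow(M)))
  rn <- sqrt(rowSums(M^2))
  num <- as.numeric(M %*% q)
  out <- numeric(nrow(M))
  ok <- rn > 0
  out[ok] <- num[ok] / (rn[ok] * qn)
  out
}

#' Rank guideline documents for a free-text indication
#'
#' Preprocesses the query (abbreviation expansion, tokenization, stop-word
#' removal, optional lemmatization), embeds it once, scores every indexed
#' document with `S = H + B + beta * T`, and returns the `top_k` results in
#' descending score order.  Ties are broken by `doc_id` ascending so ranking
#' is deterministic.  Query-side work is a single pass over the query tokens,
#' then one pass over documents.
#'
#' A query that reduces to zero embeddable tokens (empty, or all stop words)
#' raises an `guidematch_unsearchable_query` error rather than silently
#' returning nothing — an unsearchable indication is a failure mode worth
#' surfacing to the caller.
#'
#' @param query A single free-text indication.
#' @param index A [build_index()] document index.
#' @param config A [ranker_config()].
#' @param abbrev Optional abbreviation table.
#' @param stopwords Stop words for query cleaning; defaults to the list the
#'   index was built with.
#' @return Tibble with columns `rank`, `doc_id`, `score`, `header_sim`,
#'   `body_sim`, `tfidf_sim`, one row per returned result.
#' @export
search_guidelines <- function(query, index, config = ranker_config(),
                              abbrev = NULL, stopwords = NULL) {
  stopifnot(inherits(index, "document_index"), length(query) == 1)
  if (is.null(stopwords)) stopwords <- index$stopwords
  tokens <- preprocess_query(
    query, table = abbrev, stopwords = stopwords,
    lemmatize_tokens = config$lemmatize_query,
    case_sensitive = config$case_sensitive_abbrev
  )
  q <- embed_tokens(index$backend, tokens)
  if (is_zero_vector(q)) {
    abort(
      paste0("unsearchable query: no embeddable tokens in ", encodeString(query, quote = '"')),
      class = "guidematch_unsearchable_query"
    )
  }
  h <- cosine_rows(index$H, q)
  b <- cosine_rows(index$B, q)
  t_ <- cosine_rows(index$T, q)
  s <- h + b + config$beta * t_
  ord <- order(-s, index$docs$doc_id)
  keep <- head(ord, config$top_k)
  tibble(
    rank = seq_along(keep),
    doc_id = index$docs$doc_id[keep],
    score = s[keep],
    header_sim = h[keep],
    body_sim = b[keep],
    tfidf_sim = t_[keep]
  )
}
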