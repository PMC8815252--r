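#' Sentence-embedding backends
#'
#' A backend is a deterministic map from free text to a fixed-dimension real
#' vector.  Sentence embedding is bag-of-tokens averaging: each token is
#' mapped to a token vector and the sentence vector is the arithmetic mean.
#' Text with no embeddable tokens (empty, or reduced to nothing upstream)
#' embeds to the zero vector — a defined outcome that scoring treats as
#' cosine 0, not an error.
#'
#' `toy_backend()` is a self-contained deterministic backend for testing and
#' benchmarking: each token is first canonicalized through an optional
#' synonym table (so declared synonyms embed identically), then hashed with a
#' stable 32-bit hash, and the hash seeds a pseudorandom unit vector.
#' Unrelated tokens are therefore nearly orthogonal at moderate dimension,
#' while synonyms coincide exactly.
#'
#' `pretrained_backend()` adapts a word-vector model in the word2vec/sent2vec
#' text format: a header line `<n_tokens> <dimension>` followed by one line
#' per token (`token v1 v2 ...`).  Out-of-vocabulary tokens are skipped;
#' biomedical sentence-vector models of this family typically use dimension
#' 700.
#'
#' @param dimension Vector dimension (>= 8 for the toy backend, so random
#'   token vectors are close to orthogonal).
#' @param seed Integer seed; different seeds give unrelated token vectors.
#' @param synonyms Named character vector mapping token -> canonical token.
#' @return An `embedding_backend` object.
#' @export
#' @examples
#' be <- toy_backend(dimension = 32, seed = 1,
#'                   synonyms = c(stone = "calculus"))
#' identical(embed_text(be, "stone"), embed_text(be, "calculus"))
toy_backend <- function(dimension = 64, seed = 0, synonyms = NULL) {
  stopifnot(dimension >= 8)
  if (!is.null(synonyms)) {
    stopifnot(!is.null(names(synonyms)))
    synonyms <- setNames(as.character(synonyms), names(synonyms))
  }
  cache <- new.env(parent = emptyenv())
  token_vector <- function(token) {
    canonical <- token
    if (!is.null(synonyms)) {
      m <- match(token, names(synonyms))
      if (!is.na(m)) canonical <- unname(synonyms[[m]])
    }
    hit <- get0(canonical, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    h <- strtoi(substr(
      digest::digest(canonical, algo = "xxhash32", serialize = FALSE), 1, 7
    ), 16L)
    local_seed <- as.integer((as.numeric(h) + as.numeric(seed) * 97) %% 2147483647)
    v <- withr::with_seed(local_seed, rnorm(dimension))
    v <- v / sqrt(sum(v^2))
    assign(canonical, v, envir = cache)
    v
  }
  structure(
    list(
      name = "toy",
      dimension = as.integer(dimension),
      deterministic = TRUE,
      token_vector = token_vector
    ),
    class = "embedding_backend"
  )
}

#' @rdname toy_backend
#' @param path Word-vector model file (text format described above).
#' @export
pretrained_backend <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("embedding model file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) abort(paste0("embedding model file is empty: ", path))
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || any(is.na(hdr)) || hdr[2] < 1) {
    abort(paste0("malformed embedding model header in ", path))
  }
  dimension <- hdr[2]
  vectors <- new.env(parent = emptyenv())
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(parts[-1]))
    if (length(v) != dimension || any(is.na(v))) {
      abort(paste0("malformed embedding row for token '", parts[1],
                   "' in ", path))
    }
    assign(parts[1], v, envir = vectors)
  }
  token_vector <- function(token) {
    get0(token, envir = vectors, inherits = FALSE)
  }
  structure(
    list(
      name = "pretrained",
      dimension = dimension,
      deterministic = TRUE,
      token_vector = token_vector
    ),
    class = "embedding_backend"
  )
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat("<embedding_backend> ", x$name, ", dimension ", x$dimension, "\n",
      sep = "")
  invisible(x)
}

#' Embed text into a sentence vector
#'
#' Tokenizes the text (lowercase word tokens; stop-word handling is the
#' caller's concern) and averages the backend's token vectors.  Tokens the
#' backend cannot embed are skipped; if nothing remains the zero vector is
#' returned.
#'
#' @param backend An `embedding_backend`.
#' @param text A single string (possibly empty).
#' @return Numeric vector of length `backend$dimension`.
#' @export
embed_text <- function(backend, text) {
  stopifnot(inherits(backend, "embedding_backend"), length(text) == 1)
  tokens <- tokenize_and_clean(text, stopwords = character())
  embed_tokens(backend, tokens)
}

#' @rdname embed_text
#' @param tokens Character vector of already-clean tokens.
#' @export
embed_tokens <- function(backend, tokens) {
  zero <- numeric(backend$dimension)
  if (length(tokens) == 0) return(zero)
  vecs <- lapply(tokens, backend$token_vector)
  vecs <- vecs[!vapply(vecs, is.null, logical(1))]
  if (length(vecs) == 0) return(zero)
  Reduce(`+`, vecs) / length(vecs)
}

#' Is a vector the zero embedding?
#' @param v Numeric vector.
#' @return `TRUE` when all entries are zero.
#' @export
is_zero_vector <- function(v) {
  all(v == 0)
}
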