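# Small fixtures and independent oracles used across the suite.

# two-document toy corpus with hand-checkable tf-idf weights
toy_corpus_2 <- function() {
  as_corpus(data.frame(
    doc_id = c("d1", "d2"),
    title = c("Kidney", "Chest"),
    body = c("kidney stone pain", "chest pain")
  ))
}

# a small corpus with disjoint per-document vocabularies; each title word
# appears only in its own document
tiny_disjoint_corpus <- function(n = 3) {
  vocab <- list(
    c("flank", "renal", "calculus", "hematuria"),
    c("dyspnea", "embolism", "hypoxia", "tachycardia"),
    c("headache", "aura", "photophobia", "nausea"),
    c("fracture", "fall", "swelling", "deformity"),
    c("jaundice", "pruritus", "bilirubin", "fatigue")
  )
  stopifnot(n <= length(vocab))
  tags <- default_tag_vocabulary()
  as_corpus(tibble::tibble(
    doc_id = sprintf("doc%02d", seq_len(n)),
    title = vapply(vocab[seq_len(n)],
                   function(w) paste(w[1:2], collapse = " "), ""),
    variants = lapply(seq_len(n), function(i) character()),
    body = vapply(vocab[seq_len(n)],
                  function(w) paste(rep(w, 4), collapse = " "), ""),
    tags = lapply(seq_len(n), function(i) tags[(i %% 3) + 1]),
    category = rep(c("CatA", "CatB"), length.out = n)
  ))
}

# all permutations of a vector (n <= 7)
all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

# NDCG by brute force: DCG of the given order divided by the maximum DCG
# over every permutation of the corpus relevances
brute_force_ndcg <- function(result_rel, all_rel = result_rel) {
  dcg <- function(rel) sum(rel / log2(seq_along(rel) + 1))
  best <- max(vapply(all_permutations(all_rel), dcg, numeric(1)))
  if (best == 0) return(0)
  dcg(result_rel) / best
}

# search oracle: score every document one at a time with score_document and
# sort, independent of the vectorized path in search_guidelines
brute_force_search <- function(query, index, beta = 1,
                               stopwords = default_stopwords()) {
  tokens <- preprocess_query(query, stopwords = stopwords)
  q <- embed_tokens(index$backend, tokens)
  scores <- vapply(seq_len(nrow(index$docs)), function(i) {
    entry <- list(
      header_vec = index$H[i, ],
      body_vec = index$B[i, ],
      tfidf_vec = index$T[i, ]
    )
    score_document(q, entry, beta = beta)
  }, numeric(1))
  ord <- order(-scores, index$docs$doc_id)
  tibble::tibble(
    rank = seq_along(ord),
    doc_id = index$docs$doc_id[ord],
    score = scores[ord]
  )
}

# brute-force per-document tf-idf weight table (unnormalized), built from
# first principles: raw n-gram counts times ln((1+N)/(1+df)) + 1
brute_force_weights <- function(corpus, doc_row, stopwords = character()) {
  toks <- lapply(corpus$body, tokenize_and_clean, stopwords = stopwords)
  ngrams_of <- function(tokens) {
    unlist(lapply(1:3, function(n) {
      if (length(tokens) < n) return(character())
      vapply(seq_len(length(tokens) - n + 1),
             function(i) paste(tokens[i:(i + n - 1)], collapse = " "), "")
    }))
  }
  grams <- lapply(toks, ngrams_of)
  mine <- grams[[doc_row]]
  tf <- table(mine)
  df <- vapply(names(tf), function(g) {
    sum(vapply(grams, function(gg) g %in% gg, logical(1)))
  }, numeric(1))
  idf <- log((1 + nrow(corpus)) / (1 + df)) + 1
  w <- as.numeric(tf) * idf
  stats::setNames(w / sqrt(sum(w^2)), names(tf))
}
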