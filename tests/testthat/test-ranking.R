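test_that("cosine similarity matches closed forms and conventions", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(cosine_similarity(c(0, 0), c(1, 2)), 0)
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "dimension mismatch")
})

test_that("the combined score is H + B + beta * T", {
  entry <- list(header_vec = c(1, 0, 0), body_vec = c(0, 1, 0),
                tfidf_vec = c(0, 0, 1))
  q <- c(1, 1, 1)
  h <- b <- t_ <- 1 / sqrt(3)
  expect_equal(score_document(q, entry, beta = 0.5),
               h + b + 0.5 * t_, tolerance = 1e-12)
  expect_equal(score_document(q, entry, beta = 0),
               h + b, tolerance = 1e-15)
  # query identical to all three views: cosines all 1 -> 2 + beta
  same <- list(header_vec = q, body_vec = q, tfidf_vec = q)
  expect_equal(score_document(q, same, beta = 0.7), 2.7, tolerance = 1e-12)
})

test_that("score is strictly monotone in each component for beta > 0", {
  q <- c(1, 0, 0)
  near <- c(1, 0.2, 0)   # higher cosine with q
  far <- c(1, 1, 0)      # lower cosine with q
  base <- list(header_vec = far, body_vec = far, tfidf_vec = far)
  s0 <- score_document(q, base, beta = 0.8)
  for (view in c("header_vec", "body_vec", "tfidf_vec")) {
    improved <- base
    improved[[view]] <- near
    expect_gt(score_document(q, improved, beta = 0.8), s0)
  }
  # with beta = 0 the tfidf view cannot move the score
  improved_t <- base
  improved_t$tfidf_vec <- near
  expect_equal(score_document(q, improved_t, beta = 0),
               score_document(q, base, beta = 0), tolerance = 1e-15)
})

test_that("index construction is structural, deterministic and zero-safe", {
  corpus <- tiny_disjoint_corpus(3)
  be <- toy_backend(dimension = 32, seed = 2)
  idx <- build_index(corpus, be, k = 10)
  expect_equal(nrow(idx$docs), 3)
  expect_equal(dim(idx$H), c(3, 32))
  expect_equal(dim(idx$B), c(3, 32))
  expect_equal(dim(idx$T), c(3, 32))
  idx2 <- build_index(corpus, toy_backend(dimension = 32, seed = 2), k = 10)
  expect_identical(idx$H, idx2$H)
  expect_identical(idx$B, idx2$B)
  expect_identical(idx$T, idx2$T)
})

test_that("a document whose body is all stop words still indexes", {
  corpus <- as_corpus(data.frame(
    doc_id = c("a", "b"),
    title = c("Alpha Topic", "Beta Topic"),
    body = c("unique wording here", "filler body")
  ))
  be <- toy_backend(dimension = 16, seed = 1)
  # body reduced to nothing -> zero body vector, but the index builds
  expect_warning(
    idx <- build_index(corpus, be, k = 5, stopwords = c("filler", "body")),
    "empty after cleaning"
  )
  expect_true(is_zero_vector(idx$B["b", ]))
  res <- search_guidelines("beta topic", idx,
                           config = ranker_config(top_k = 2),
                           stopwords = character())
  expect_equal(res$body_sim[res$doc_id == "b"], 0)
})

test_that("search equals brute-force score-and-sort on small corpora", {
  for (trial_seed in c(1, 2, 3)) {
    spec <- fixture_spec(n_docs = 8, seed = trial_seed,
                         body_length = c(30, 60))
    bundle <- generate_corpus(spec)
    be <- toy_backend(dimension = 32, seed = trial_seed,
                      synonyms = bundle$synonyms)
    idx <- build_index(bundle$corpus, be, k = 20)
    queries <- generate_query_set(bundle, spec, "simple")$query_text[1:4]
    for (q in queries) {
      got <- search_guidelines(q, idx, config = ranker_config(top_k = 8))
      oracle <- brute_force_search(q, idx, beta = 1)
      expect_equal(got$doc_id, oracle$doc_id)
      expect_equal(got$score, oracle$score, tolerance = 1e-12)
    }
  }
})

test_that("identical documents tie and are returned in doc_id order", {
  corpus <- as_corpus(data.frame(
    doc_id = c("bbb", "aaa"),
    title = c("Flank Pain", "Flank Pain"),
    body = c("flank pain colic", "flank pain colic")
  ))
  be <- toy_backend(dimension = 16, seed = 4)
  idx <- build_index(corpus, be, k = 5, stopwords = character())
  res <- search_guidelines("flank pain", idx,
                           config = ranker_config(top_k = 5),
                           stopwords = character())
  expect_equal(res$score[1], res$score[2], tolerance = 1e-12)
  expect_equal(res$doc_id, c("aaa", "bbb"))
  expect_equal(res$rank, 1:2)  # top_k beyond corpus: all docs, ranked
})

test_that("corpus order does not change scores or tie-broken ranks", {
  corpus <- tiny_disjoint_corpus(5)
  be <- toy_backend(dimension = 32, seed = 6)
  shuffled <- as_corpus(corpus[c(3, 1, 5, 2, 4), ])
  idx1 <- build_index(corpus, be, k = 10)
  idx2 <- build_index(shuffled, be, k = 10)
  res1 <- search_guidelines("flank renal colic", idx1,
                            config = ranker_config(top_k = 5))
  res2 <- search_guidelines("flank renal colic", idx2,
                            config = ranker_config(top_k = 5))
  expect_equal(res1$doc_id, res2$doc_id)
  expect_equal(res1$score, res2$score, tolerance = 1e-12)
})

test_that("a query matching one document's header ranks it first", {
  corpus <- tiny_disjoint_corpus(5)
  be <- toy_backend(dimension = 32, seed = 8)
  idx <- build_index(corpus, be, k = 10)
  for (i in seq_len(nrow(corpus))) {
    res <- search_guidelines(corpus$title[i], idx,
                             config = ranker_config(top_k = 1))
    expect_equal(res$doc_id, corpus$doc_id[i])
  }
})

test_that("unsearchable queries raise the typed error, not empty results", {
  idx <- build_index(tiny_disjoint_corpus(2),
                     toy_backend(dimension = 16, seed = 1), k = 5)
  expect_error(
    search_guidelines("the of and", idx),
    class = "guidematch_unsearchable_query"
  )
  expect_error(
    search_guidelines("...", idx),
    class = "guidematch_unsearchable_query"
  )
})

test_that("ranker config rejects invalid hyperparameters", {
  expect_error(ranker_config(beta = -0.1))
  expect_error(ranker_config(top_k = 0))
  cfg <- ranker_config(beta = 0)
  expect_equal(cfg$beta, 0)
})
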