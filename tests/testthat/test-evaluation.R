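test_that("tag relevance counts matching tags and rejects unknown ones", {
  expect_equal(tag_relevance(c("trauma", "vascular disease"), "trauma"), 1)
  expect_equal(tag_relevance("neoplasm", "congenital"), 0)
  three <- c("trauma", "surgical", "neoplasm")
  expect_equal(tag_relevance(three, three), 3)
  expect_error(tag_relevance("oncology", "trauma"), "oncology")
})

test_that("NDCG matches hand-evaluated values", {
  expect_equal(ndcg(c(3, 2, 1, 0, 0)), 1)
  # (0/log2(2) + 1/log2(3)) / (1/log2(2)) = 0.63093
  expect_equal(ndcg(c(0, 1), all_relevances = c(1, 0)),
               1 / log2(3), tolerance = 1e-9)
  expect_equal(round(ndcg(c(0, 1), all_relevances = c(1, 0)), 5), 0.63093)
  expect_warning(z <- ndcg(c(0, 0, 0)), class = "guidematch_zero_relevance")
  expect_equal(z, 0)
})

test_that("NDCG validates its inputs", {
  expect_error(ndcg(c(-1, 2)), "nonnegative")
  expect_error(ndcg(c(1, 2, 3), all_relevances = c(1, 2)), "longer")
  expect_error(ndcg(c(5, 0), all_relevances = c(1, 0)), "not drawn")
})

test_that("NDCG equals brute-force max-over-permutations on short lists", {
  set.seed(101)
  for (n in 2:6) {
    for (rep in 1:5) {
      all_rel <- sample(0:3, n, replace = TRUE)
      if (all(all_rel == 0)) all_rel[1] <- 1
      observed <- sample(all_rel)
      expect_equal(ndcg(observed, all_relevances = all_rel),
                   brute_force_ndcg(observed, all_rel), tolerance = 1e-12)
    }
  }
})

test_that("NDCG stays in [0, 1] over random permutations", {
  set.seed(77)
  for (rep in 1:50) {
    all_rel <- sample(0:4, sample(3:40, 1), replace = TRUE)
    if (all(all_rel == 0)) all_rel[1] <- 1
    v <- ndcg(sample(all_rel), all_relevances = all_rel)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  # ideal order is always exactly 1
  for (rep in 1:10) {
    all_rel <- sample(0:4, 12, replace = TRUE)
    if (all(all_rel == 0)) all_rel[1] <- 1
    expect_equal(ndcg(sort(all_rel, decreasing = TRUE),
                      all_relevances = all_rel), 1, tolerance = 1e-12)
  }
})

test_that("top-k accuracy follows its definition in both modes", {
  results <- list(c("a", "b", "c", "d", "e"), c("b", "c", "d", "e", "a"))
  gt <- list("a", "a")  # ranks 1 and 5
  expect_equal(top_k_accuracy(results, gt, k = 3, mode = "any")$accuracy, 0.5)
  # {a, b} at ranks 2 and 4 with k = 5 counts as a hit in mode all
  res2 <- list(c("x", "a", "y", "b", "z"))
  expect_equal(top_k_accuracy(res2, list(c("a", "b")), k = 5,
                              mode = "all")$accuracy, 1)
  expect_equal(top_k_accuracy(res2, list(c("a", "b")), k = 3,
                              mode = "all")$accuracy, 0)
  # k at corpus size: every query with nonempty ground truth is a hit
  expect_equal(top_k_accuracy(results, gt, k = 5, mode = "any")$accuracy, 1)
  # empty ground truth excluded from the denominator, counted separately
  out <- top_k_accuracy(c(results, res2),
                        list("a", "a", character()), k = 3)
  expect_equal(out$n_evaluated, 2)
  expect_equal(out$n_no_ground_truth, 1)
  expect_equal(out$accuracy, 0.5)
})

test_that("top-k accuracy is non-decreasing in k", {
  set.seed(5)
  docs <- sprintf("d%02d", 1:15)
  results <- lapply(1:12, function(i) sample(docs))
  gt <- lapply(1:12, function(i) sample(docs, sample(1:3, 1)))
  for (mode in c("any", "all")) {
    acc <- top_k_accuracy(results, gt, k = 1:15, mode = mode)$accuracy
    expect_true(all(diff(acc) >= 0))
    expect_equal(acc[15], 1)
  }
})

test_that("rank statistics aggregate best ground-truth ranks", {
  results <- list(c("a", "b"), c("c", "a"), c("b", "a", "c"))
  gt <- list("a", c("a", "c"), "b")
  # best ranks: 1, 1, 1? no: query2 best of {a->2, c->1} = 1; query3 b->1
  out <- rank_statistics(results, gt)
  expect_equal(out$mean_rank, 1)
  out2 <- rank_statistics(list(c("x", "a"), c("a", "x"), c("x", "y", "a")),
                          list("a", "a", "a"))
  expect_equal(out2$mean_rank, mean(c(2, 1, 3)))
  expect_equal(out2$sd_rank, sd(c(2, 1, 3)))
  # single query
  single <- rank_statistics(list(c(letters[1:7])), list("g"))
  expect_equal(single$mean_rank, 7)
  expect_equal(single$sd_rank, 0)
  # ground truth absent from the ranked list: flagged and excluded
  miss <- rank_statistics(list(c("a", "b"), c("a", "b")), list("z", "a"))
  expect_equal(miss$n_missing, 1)
  expect_equal(miss$mean_rank, 1)
})

test_that("query sets round-trip through JSON", {
  queries <- tibble::tibble(
    query_text = c("flank pain", "no match at all"),
    ground_truth_ids = list("doc01", character()),
    query_tags = list(c("trauma", "surgical"), character()),
    complexity = c("simple", "clinical")
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_query_set(queries, path)
  back <- read_query_set(path)
  expect_equal(back$query_text, queries$query_text)
  expect_equal(back$ground_truth_ids, queries$ground_truth_ids)
  expect_equal(back$query_tags, queries$query_tags)
  expect_equal(back$complexity, queries$complexity)
})

test_that("evaluate matches a hand-computed report on a small suite", {
  corpus <- tiny_disjoint_corpus(4)
  be <- toy_backend(dimension = 32, seed = 12)
  idx <- build_index(corpus, be, k = 10)
  queries <- tibble::tibble(
    query_text = c(corpus$title[1], corpus$title[2],
                   corpus$title[3], "the of and"),
    ground_truth_ids = list("doc01", "doc02", "doc03", "doc04"),
    query_tags = corpus$tags[c(1, 2, 3, 4)],
    complexity = c("simple", "simple", "complex", "complex")
  )
  ev <- evaluate_queries(queries, idx, k = c(1, 3))
  per <- tidy(ev)
  # the all-stop-word query is recorded as an error, not fatal
  expect_equal(ev$n_errors, 1)
  expect_match(per$error[4], "unsearchable")
  # hand oracle: per-query NDCG recomputed from the brute-force ranking
  for (i in 1:3) {
    oracle_rank <- brute_force_search(queries$query_text[i], idx)$doc_id
    rel <- vapply(oracle_rank, function(id) {
      tag_relevance(queries$query_tags[[i]],
                    corpus$tags[[match(id, corpus$doc_id)]])
    }, numeric(1))
    expect_equal(per$ndcg[i], brute_force_ndcg(unname(rel)),
                 tolerance = 1e-12)
    expect_equal(per$best_rank[i],
                 match(queries$ground_truth_ids[[i]], oracle_rank))
  }
  # self-retrieval on disjoint vocabularies: all searched queries rank
  # their ground truth first
  expect_equal(per$best_rank[1:3], c(1, 1, 1))
  expect_equal(ev$top_k$accuracy[ev$top_k$k == 1 & ev$top_k$mode == "any"], 1)
  g <- glance(ev)
  expect_equal(g$n_queries, 4)
  expect_equal(g$mean_rank, 1)
})

test_that("evaluation is invariant to query order", {
  corpus <- tiny_disjoint_corpus(4)
  be <- toy_backend(dimension = 32, seed = 13)
  idx <- build_index(corpus, be, k = 10)
  queries <- tibble::tibble(
    query_text = corpus$title,
    ground_truth_ids = as.list(corpus$doc_id),
    query_tags = corpus$tags,
    complexity = "simple"
  )
  ev1 <- evaluate_queries(queries, idx)
  ev2 <- evaluate_queries(queries[c(3, 1, 4, 2), ], idx)
  expect_equal(sort(tidy(ev1)$ndcg), sort(tidy(ev2)$ndcg))
  expect_equal(glance(ev1)$mean_ndcg, glance(ev2)$mean_ndcg)
  expect_equal(ev1$top_k$accuracy, ev2$top_k$accuracy)
})

test_that("evaluate rejects ground truths missing from the index", {
  idx <- build_index(tiny_disjoint_corpus(2),
                     toy_backend(dimension = 16, seed = 1), k = 5)
  queries <- tibble::tibble(
    query_text = "flank", ground_truth_ids = list("ghost"),
    query_tags = list("trauma"), complexity = "simple"
  )
  expect_error(evaluate_queries(queries, idx), "ghost")
})

test_that("plot methods return ggplot objects", {
  corpus <- tiny_disjoint_corpus(4)
  idx <- build_index(corpus, toy_backend(dimension = 16, seed = 3), k = 5)
  queries <- tibble::tibble(
    query_text = corpus$title,
    ground_truth_ids = as.list(corpus$doc_id),
    query_tags = corpus$tags,
    complexity = rep(c("simple", "complex"), 2)
  )
  ev <- evaluate_queries(queries, idx)
  expect_s3_class(autoplot(ev), "ggplot")
  res <- search_guidelines(corpus$title[1], idx)
  expect_s3_class(plot_search_scores(res), "ggplot")
})
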