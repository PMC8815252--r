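#' Graded relevance from category tags
#'
#' The relevance of a document to a query is the number of tags they share:
#' a result sharing all of the query's etiology tags is maximally relevant,
#' one sharing none is irrelevant.  Both tag sets must come from the same
#' vocabulary.
#'
#' @param query_tags,doc_tags Character vectors of tags.
#' @param vocabulary Allowed tags; [default_tag_vocabulary()] by default.
#' @return Nonnegative integer count of matching tags.
#' @export
#' @examples
#' tag_relevance(c("trauma", "vascular disease"), "trauma")
tag_relevance <- function(query_tags, doc_tags,
                          vocabulary = default_tag_vocabulary()) {
  bad <- setdiff(c(query_tags, doc_tags), vocabulary)
  if (length(bad) > 0) {
    abort(paste0("unknown tag(s): ", paste(bad, collapse = ", ")))
  }
  length(intersect(query_tags, doc_tags))
}

#' Normalized discounted cumulative gain
#'
#' Ranking quality of one result list under graded relevance:
#' \deqn{NDCG = \frac{\sum_{i=1}^{n} rel_i / \log_2(i+1)}
#'                   {\sum_{i=1}^{n} REL_i / \log_2(i+1)}}
#' where \eqn{rel_i} is the relevance of the result at rank \eqn{i} and the
#' denominator is the ideal DCG: the same relevances sorted in descending
#' order over all \eqn{n} corpus documents.  1 indicates a perfect ranking.
#' When every relevance is zero the ideal DCG is zero; the convention here is
#' NDCG = 0, with a warning.
#'
#' @param result_relevances Integer relevances in ranked order (a prefix of,
#'   or the full, corpus ranking).
#' @param all_relevances Relevances of every corpus document (any order);
#'   defaults to `result_relevances` when the result list covers the corpus.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' ndcg(c(3, 2, 1, 0, 0))             # ideal order -> 1
#' ndcg(c(0, 1), all_relevances = c(1, 0))
ndcg <- function(result_relevances, all_relevances = result_relevances) {
  result_relevances <- as.numeric(result_relevances)
  all_relevances <- as.numeric(all_relevances)
  if (any(result_relevances < 0) || any(all_relevances < 0)) {
    abort("relevances must be nonnegative")
  }
  if (length(result_relevances) > length(all_relevances)) {
    abort("result list longer than the corpus relevance list")
  }
  res_counts <- table(result_relevances)
  all_counts <- table(all_relevances)
  extra <- setdiff(names(res_counts), names(all_counts))
  if (length(extra) > 0 ||
      any(res_counts > all_counts[names(res_counts)])) {
    abort("result relevances are not drawn from the corpus relevances")
  }
  discount <- function(rel) {
    if (length(rel) == 0) return(0)
    sum(rel / log2(seq_along(rel) + 1))
  }
  idcg <- discount(sort(all_relevances, decreasing = TRUE))
  if (idcg == 0) {
    warn("all relevances are zero; NDCG undefined, returning 0",
         class = "guidematch_zero_relevance")
    return(0)
  }
  discount(result_relevances) / idcg
}

#' Top-k retrieval accuracy over a query set
#'
#' The fraction of queries whose ground-truth document(s) appear within the
#' first `k` ranked results.  Mode `"any"`: at least one ground-truth id in
#' the top k.  Mode `"all"`: every ground-truth id in the top k.  Queries
#' with no ground truth are excluded from the denominator and counted
#' separately.
#'
#' @param results List of ranked doc-id character vectors, one per query.
#' @param ground_truth List of ground-truth doc-id vectors, one per query
#'   (possibly empty).
#' @param k Integer cutoff(s); one output row per value.
#' @param mode `"any"` or `"all"`.
#' @return Tibble with columns `k`, `mode`, `accuracy`, `n_evaluated`,
#'   `n_no_ground_truth`.
#' @export
top_k_accuracy <- function(results, ground_truth, k = 3,
                           mode = c("any", "all")) {
  mode <- match.arg(mode)
  stopifnot(length(results) == length(ground_truth), all(k >= 1))
  has_gt <- vapply(ground_truth, length, 0L) > 0
  purrr::map_dfr(k, function(kk) {
    hit <- vapply(which(has_gt), function(i) {
      topk <- head(results[[i]], kk)
      inside <- ground_truth[[i]] %in% topk
      if (mode == "any") any(inside) else all(inside)
    }, logical(1))
    tibble(
      k = as.integer(kk), mode = mode,
      accuracy = if (length(hit)) mean(hit) else NA_real_,
      n_evaluated = sum(has_gt),
      n_no_ground_truth = sum(!has_gt)
    )
  })
}

#' Ground-truth rank statistics over a query set
#'
#' Per query, the rank of the best-ranked ground-truth document; aggregated
#' as mean and standard deviation.  Queries whose ground truth is absent
#' from the ranked list are flagged, excluded from the aggregate, and
#' counted.
#'
#' @inheritParams top_k_accuracy
#' @return Tibble with columns `mean_rank`, `sd_rank`, `n`, `n_missing`.
#' @export
rank_statistics <- function(results, ground_truth) {
  stopifnot(length(results) == length(ground_truth))
  best <- vapply(seq_along(results), function(i) {
    pos <- match(ground_truth[[i]], results[[i]])
    pos <- pos[!is.na(pos)]
    if (length(pos) == 0) NA_real_ else min(pos)
  }, numeric(1))
  has_gt <- vapply(ground_truth, length, 0L) > 0
  best[!has_gt] <- NA_real_
  ok <- !is.na(best)
  tibble(
    mean_rank = if (any(ok)) mean(best[ok]) else NA_real_,
    sd_rank = if (sum(ok) > 1) sd(best[ok]) else if (any(ok)) 0 else NA_real_,
    n = sum(ok),
    n_missing = sum(has_gt & !ok)
  )
}

#' Annotated query sets on disk
#'
#' A query set is a tibble with columns `query_text`, `ground_truth_ids`
#' (list of doc ids, possibly empty = no matching document), `query_tags`
#' (list of tags) and `complexity` (`"simple"`, `"complex"` or
#' `"clinical"`).  On disk it is a JSON array of objects with those keys.
#'
#' @param path JSON file path.
#' @return A tibble (for read); the input, invisibly (for write).
#' @export
read_query_set <- function(path) {
  if (!file.exists(path)) abort(paste0("query set file not found: ", path))
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                          simplifyVector = TRUE)
  out <- as_tibble(x)
  out$ground_truth_ids <- lapply(out$ground_truth_ids, function(g) {
    g <- as.character(unlist(g))
    g[nzchar(g)]
  })
  out$query_tags <- lapply(out$query_tags, function(g) {
    g <- as.character(unlist(g))
    g[nzchar(g)]
  })
  out
}

#' @rdname read_query_set
#' @param queries Query-set tibble.
#' @export
write_query_set <- function(queries, path) {
  out <- lapply(seq_len(nrow(queries)), function(i) {
    list(
      query_text = queries$query_text[i],
      ground_truth_ids = as.list(queries$ground_truth_ids[[i]]),
      query_tags = as.list(queries$query_tags[[i]]),
      complexity = queries$complexity[i]
    )
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(queries)
}

#' Evaluate retrieval quality over an annotated query set
#'
#' Runs [search_guidelines()] for every query against the full corpus (the
#' displayed top-k is a prefix of the full ranking; NDCG is computed over
#' all indexed documents), grades every document by matching-tag relevance,
#' and aggregates NDCG, top-k accuracy and ground-truth rank statistics —
#' overall, by query complexity, and by the ground-truth document's
#' category.  Per-query search errors (unsearchable queries) are recorded,
#' not fatal.
#'
#' @param queries Query-set tibble, see [read_query_set()].
#' @param index A [build_index()] document index.
#' @param config A [ranker_config()]; its `top_k` is ignored here (the full
#'   ranking is always scored).
#' @param abbrev Optional abbreviation table applied to queries.
#' @param k Integer cutoffs for top-k accuracy (default `c(3, 5, 10)`).
#' @return A `guideline_eval` object; see [tidy.guideline_eval()] and
#'   [glance.guideline_eval()].
#' @export
evaluate_queries <- function(queries, index, config = ranker_config(),
                             abbrev = NULL, k = c(3, 5, 10)) {
  n_docs <- nrow(index$docs)
  vocab <- index$tag_vocabulary
  full_config <- ranker_config(
    beta = config$beta, top_k = n_docs,
    lemmatize_query = config$lemmatize_query,
    case_sensitive_abbrev = config$case_sensitive_abbrev
  )
  unknown_gt <- setdiff(unique(unlist(queries$ground_truth_ids)),
                        index$docs$doc_id)
  if (length(unknown_gt) > 0) {
    abort(paste0("ground-truth id(s) not in index: ",
                 paste(unknown_gt, collapse = ", ")))
  }
  rows <- purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    gt <- queries$ground_truth_ids[[i]]
    qtags <- queries$query_tags[[i]]
    res <- tryCatch(
      search_guidelines(queries$query_text[i], index, config = full_config,
                        abbrev = abbrev),
      guidematch_unsearchable_query = function(e) e
    )
    category <- if (length(gt) > 0) {
      index$docs$category[match(gt[1], index$docs$doc_id)]
    } else {
      NA_character_
    }
    if (inherits(res, "error")) {
      return(tibble(
        query_id = i, complexity = queries$complexity[i],
        category = category, n_ground_truth = length(gt),
        best_rank = NA_real_, worst_rank = NA_real_, ndcg = NA_real_,
        ranking = list(character()), error = conditionMessage(res)
      ))
    }
    rel_by_doc <- vapply(
      index$docs$tags[match(res$doc_id, index$docs$doc_id)],
      function(dt) tag_relevance(qtags, dt, vocabulary = vocab),
      numeric(1)
    )
    q_ndcg <- withCallingHandlers(
      ndcg(rel_by_doc, all_relevances = rel_by_doc),
      guidematch_zero_relevance = function(w) invokeRestart("muffleWarning")
    )
    pos <- match(gt, res$doc_id)
    pos <- pos[!is.na(pos)]
    tibble(
      query_id = i, complexity = queries$complexity[i],
      category = category, n_ground_truth = length(gt),
      best_rank = if (length(pos)) min(pos) else NA_real_,
      worst_rank = if (length(pos)) max(pos) else NA_real_,
      ndcg = q_ndcg,
      ranking = list(res$doc_id),
      error = NA_character_
    )
  })
  searched <- is.na(rows$error)
  results_list <- rows$ranking[searched]
  gt_list <- queries$ground_truth_ids[searched]
  topk <- dplyr::bind_rows(
    top_k_accuracy(results_list, gt_list, k = k, mode = "any"),
    top_k_accuracy(results_list, gt_list, k = k, mode = "all")
  )
  rankstats <- rank_statistics(results_list, gt_list)
  by_complexity <- rows |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$complexity) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ndcg = mean(.data$ndcg, na.rm = TRUE),
      sd_ndcg = sd(.data$ndcg, na.rm = TRUE),
      mean_rank = mean(.data$best_rank, na.rm = TRUE),
      top_3 = mean(.data$best_rank <= 3, na.rm = TRUE),
      .groups = "drop"
    )
  by_category <- rows |>
    dplyr::filter(is.na(.data$error), !is.na(.data$category)) |>
    dplyr::group_by(.data$category, .data$complexity) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ndcg = mean(.data$ndcg, na.rm = TRUE),
      sd_ndcg = sd(.data$ndcg, na.rm = TRUE),
      .groups = "drop"
    )
  structure(
    list(
      per_query = dplyr::select(rows, -"ranking"),
      top_k = topk,
      rank_stats = rankstats,
      by_complexity = by_complexity,
      by_category = by_category,
      n_queries = nrow(queries),
      n_no_match = sum(vapply(queries$ground_truth_ids, length, 0L) == 0),
      n_errors = sum(!searched),
      beta = config$beta
    ),
    class = "guideline_eval"
  )
}

#' @export
print.guideline_eval <- function(x, ...) {
  cat("<guideline_eval> ", x$n_queries, " queries (",
      x$n_no_match, " without ground truth, ", x$n_errors,
      " unsearchable)\n", sep = "")
  cat("mean NDCG: ", round(mean(x$per_query$ndcg, na.rm = TRUE), 3),
      "; mean ground-truth rank: ", round(x$rank_stats$mean_rank, 2),
      "\n", sep = "")
  print(x$top_k)
  invisible(x)
}

#' Tidy per-query evaluation results
#'
#' @param x A `guideline_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per query: `query_id`, `complexity`,
#'   `category`, `n_ground_truth`, `best_rank`, `worst_rank`, `ndcg`,
#'   `error`.
#' @method tidy guideline_eval
#' @export
tidy.guideline_eval <- function(x, ...) {
  x$per_query
}

#' One-row evaluation summary
#'
#' @param x A `guideline_eval` object.
#' @param ... Unused.
#' @return One-row tibble: query counts, mean/sd NDCG, top-3 accuracy
#'   (mode any), mean and sd of ground-truth rank.
#' @method glance guideline_eval
#' @export
glance.guideline_eval <- function(x, ...) {
  top3 <- x$top_k$accuracy[x$top_k$k == min(x$top_k$k) &
                             x$top_k$mode == "any"]
  tibble(
    n_queries = x$n_queries,
    n_no_match = x$n_no_match,
    n_errors = x$n_errors,
    mean_ndcg = mean(x$per_query$ndcg, na.rm = TRUE),
    sd_ndcg = sd(x$per_query$ndcg, na.rm = TRUE),
    top_k_accuracy = if (length(top3)) top3[1] else NA_real_,
    mean_rank = x$rank_stats$mean_rank,
    sd_rank = x$rank_stats$sd_rank
  )
}

#' Plot NDCG by category and query complexity
#'
#' Bar chart of mean NDCG per ground-truth document category, split by query
#' complexity, with one-standard-deviation error bars.
#'
#' @param object A `guideline_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot guideline_eval
#' @export
autoplot.guideline_eval <- function(object, ...) {
  dat <- object$by_category
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$category, y = .data$mean_ndcg,
                 fill = .data$complexity)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean_ndcg - .data$sd_ndcg),
                   ymax = pmin(1, .data$mean_ndcg + .data$sd_ndcg)),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "mean NDCG", fill = "query type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the ranked-score profile of one search
#'
#' Dot-and-segment plot of the combined score and its three components for
#' a single result tibble from [search_guidelines()].
#'
#' @param results Result tibble from [search_guidelines()].
#' @return A ggplot object.
#' @export
plot_search_scores <- function(results) {
  long <- tidyr::pivot_longer(
    results,
    cols = c("score", "header_sim", "body_sim", "tfidf_sim"),
    names_to = "component", values_to = "value"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$rank, y = .data$value, colour = .data$component)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rank", y = "cosine / combined score") +
    ggplot2::theme_minimal()
}
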