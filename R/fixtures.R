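#' Specification for synthetic benchmark generation
#'
#' Controls the seeded generator that emulates a guideline-retrieval test
#' collection: a corpus of topic documents with largely disjoint core
#' vocabularies, plus one "simple" and one "complex" indication per
#' document.  Complex indications carry clinical distractors — an age phrase
#' in text form, less-relevant medical history, less-relevant social
#' history, and synonymous rewording of title keywords — and a much lower
#' title-keyword overlap than simple indications (defaults 32% vs 9% of
#' query words being title keywords).
#'
#' @param n_docs Number of documents (default 50).
#' @param vocabulary_size Distinct pseudo-words available for core document
#'   vocabularies and synonyms (default 1200).
#' @param tags_per_doc Length-2 integer range of tags per document.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param distractor_rates Named probabilities for the four distractor
#'   types: `age`, `history`, `social`, `synonym`.
#' @param target_keyword_overlap Named fractions (`simple`, `complex`): the
#'   target share of query words that are title keywords.
#' @param body_length Length-2 integer range of body tokens per document.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_docs = 50,
                         vocabulary_size = 1200,
                         tags_per_doc = c(1, 3),
                         seed = 42,
                         distractor_rates = c(age = 0.8, history = 0.6,
                                              social = 0.4, synonym = 0.9),
                         target_keyword_overlap = c(simple = 0.32,
                                                    complex = 0.09),
                         body_length = c(50, 200)) {
  stopifnot(
    n_docs >= 2,
    all(distractor_rates >= 0 & distractor_rates <= 1),
    all(c("age", "history", "social", "synonym") %in%
          names(distractor_rates)),
    all(c("simple", "complex") %in% names(target_keyword_overlap)),
    all(target_keyword_overlap > 0 & target_keyword_overlap < 1),
    length(tags_per_doc) == 2, length(body_length) == 2
  )
  structure(
    list(
      n_docs = as.integer(n_docs),
      vocabulary_size = as.integer(vocabulary_size),
      tags_per_doc = as.integer(tags_per_doc),
      seed = as.integer(seed),
      distractor_rates = distractor_rates,
      target_keyword_overlap = target_keyword_overlap,
      body_length = as.integer(body_length)
    ),
    class = "fixture_spec"
  )
}

# shared non-stop-word clinical filler; appears in every document's body and
# in queries, so it carries no document-discriminating signal
filler_pool <- c(
  "patient", "presents", "presenting", "evaluation", "evaluate",
  "assessment", "concern", "suspected", "acute", "chronic", "progressive",
  "persistent", "worsening", "onset", "bilateral", "followup", "status",
  "post", "weeks", "days", "months", "severe", "mild", "moderate",
  "recurrent", "unexplained", "found", "noted", "reports", "denies",
  "symptoms", "exam", "workup", "please", "study", "imaging", "ordered",
  "rule", "clinical", "known"
)

history_pool <- c(
  "hypertension", "diabetes mellitus", "hyperlipidemia", "asthma",
  "copd", "depression", "obesity", "gerd", "hypothyroidism"
)

social_pool <- c(
  "pack year smoker", "former smoker", "alcohol use disorder",
  "lives alone", "retired teacher"
)

category_pool <- c(
  "Breast", "Cardiac", "Gastrointestinal", "Gyn and Obstetrics",
  "Major Trauma", "Musculoskeletal", "Neurologic", "Pediatric",
  "Polytrauma", "Thoracic", "Urologic", "Vascular"
)

# pronounceable unique pseudo-words; never end in "s" so document-side
# lemmatization cannot split query/body token identity
make_words <- function(n) {
  onset <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v",
             "z", "ch", "st", "tr", "pl", "br", "cl", "dr")
  vowel <- c("a", "e", "i", "o", "u", "ai", "ea", "io", "ou")
  coda <- c("", "l", "n", "r", "x", "th", "m")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    batch <- vapply(seq_len(need * 2), function(i) {
      k <- sample(2:3, 1)
      paste0(
        paste0(sample(onset, k, replace = TRUE),
               sample(vowel, k, replace = TRUE), collapse = ""),
        sample(coda, 1)
      )
    }, character(1))
    out <- unique(c(out, batch))
  }
  out[seq_len(n)]
}

#' Generate a synthetic guideline corpus
#'
#' Builds `n_docs` topic documents with disjoint core vocabularies
#' (pseudo-words), titles of 2–3 core keywords, 0–3 title variants worded
#' with synonyms, bodies of 50–200 tokens mixing core words with shared
#' clinical filler, and 1–3 tags from the seven-tag default vocabulary.
#' The returned synonym table maps variant wording back to core wording so
#' the deterministic toy backend embeds synonyms identically — the
#' stand-in for semantic similarity in a pretrained model.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `corpus` (a `guideline_corpus`) and `synonyms` (named
#'   character vector, synonym -> core word).
#' @export
generate_corpus <- function(spec = fixture_spec()) {
  n_core <- 12
  n_syn_max <- 3
  need <- spec$n_docs * (n_core + n_syn_max)
  if (spec$vocabulary_size < need) {
    abort(paste0(
      "vocabulary too small for disjoint document vocabularies: need ",
      need, ", have ", spec$vocabulary_size
    ))
  }
  withr::with_seed(spec$seed, {
    words <- make_words(spec$vocabulary_size)
    core_words <- words[seq_len(spec$n_docs * n_core)]
    syn_words <- words[spec$n_docs * n_core + seq_len(spec$n_docs * n_syn_max)]
    synonyms <- character(0)
    docs <- purrr::map_dfr(seq_len(spec$n_docs), function(i) {
      core <- core_words[(i - 1) * n_core + seq_len(n_core)]
      n_kw <- sample(2:3, 1)
      title_kw <- core[seq_len(n_kw)]
      syns <- syn_words[(i - 1) * n_syn_max + seq_len(n_kw)]
      synonyms[syns] <<- title_kw
      n_var <- sample(0:3, 1)
      variants <- character(0)
      if (n_var >= 1) variants <- c(variants, paste(syns, collapse = " "))
      if (n_var >= 2) {
        variants <- c(variants,
                      paste(c(syns[1], title_kw[-1]), collapse = " "))
      }
      if (n_var >= 3) {
        variants <- c(variants, paste(rev(title_kw), collapse = " "))
      }
      len <- sample(spec$body_length[1]:spec$body_length[2], 1)
      n_core_tok <- round(0.6 * len)
      body_tokens <- c(
        sample(core, n_core_tok, replace = TRUE),
        sample(filler_pool, len - n_core_tok, replace = TRUE)
      )
      body_tokens <- sample(body_tokens)
      n_tags <- sample(spec$tags_per_doc[1]:spec$tags_per_doc[2], 1)
      tibble(
        doc_id = sprintf("doc-%03d", i),
        title = stringr::str_to_title(paste(title_kw, collapse = " ")),
        variants = list(variants),
        body = paste(body_tokens, collapse = " "),
        tags = list(sample(default_tag_vocabulary(), n_tags)),
        category = sample(category_pool, 1)
      )
    })
    list(corpus = as_corpus(docs), synonyms = synonyms)
  })
}

#' Title-keyword overlap of a query
#'
#' The fraction of a query's word tokens that are keywords of the given
#' document title — the statistic that separates simple from complex
#' indications (about a third of words versus under a tenth).
#'
#' @param query_text Query string.
#' @param title Document title string.
#' @return Fraction in \[0, 1\].
#' @export
keyword_overlap <- function(query_text, title) {
  q <- tokenize_and_clean(query_text, stopwords = character())
  if (length(q) == 0) return(0)
  t_ <- tokenize_and_clean(title, stopwords = character())
  mean(q %in% t_)
}

# one rejection-sampled query for one document; returns text + distractor count
compose_query <- function(title_kw, core_extra, synonyms_for_kw, mode, spec) {
  target <- spec$target_keyword_overlap[[mode]]
  rates <- spec$distractor_rates
  best <- NULL
  best_gap <- Inf
  for (attempt in seq_len(200)) {
    n_distractors <- 0L
    if (mode == "simple") {
      kw <- title_kw
      extras <- c(
        sample(core_extra, sample(1:2, 1)),
        sample(filler_pool, max(0, round(length(kw) / target) -
                                   length(kw) - 2) + sample(0:2, 1),
               replace = FALSE)
      )
      tokens <- c(sample(filler_pool, 1), extras[1], kw, extras[-1])
    } else {
      substitute <- stats::runif(length(title_kw)) < rates[["synonym"]]
      if (any(substitute)) n_distractors <- n_distractors + 1L
      kw <- ifelse(substitute, synonyms_for_kw, title_kw)
      lead <- character(0)
      if (stats::runif(1) < rates[["age"]]) {
        lead <- c(lead, paste(sample(18:95, 1), "year old"))
        n_distractors <- n_distractors + 1L
      }
      if (stats::runif(1) < rates[["history"]]) {
        lead <- c(lead, paste("history of",
                              paste(sample(history_pool, sample(1:2, 1)),
                                    collapse = " ")))
        n_distractors <- n_distractors + 1L
      }
      if (stats::runif(1) < rates[["social"]]) {
        lead <- c(lead, if (stats::runif(1) < 0.5) {
          paste(sample(10:60, 1), sample(social_pool, 1))
        } else {
          sample(social_pool, 1)
        })
        n_distractors <- n_distractors + 1L
      }
      if (n_distractors == 0L) {
        lead <- c(lead, paste(sample(18:95, 1), "year old"))
        n_distractors <- 1L
      }
      tokens <- c(
        lead, sample(filler_pool, sample(2:4, 1)),
        sample(core_extra, 1), kw
      )
    }
    text <- paste(unlist(tokens), collapse = " ")
    gap <- abs(keyword_overlap(text, paste(title_kw, collapse = " ")) - target)
    if (gap < best_gap) {
      best <- list(text = text, n_distractors = n_distractors)
      best_gap <- gap
    }
    if (gap <= 0.06) break
  }
  best
}

#' Generate an annotated benchmark query set
#'
#' One query per corpus document.  Simple queries are built mostly from the
#' document's title keywords plus shared clinical filler; complex queries
#' reword keywords with synonyms and inject distractors (age phrase,
#' less-relevant medical history, less-relevant social history) at the
#' spec's rates — every complex query carries at least one distractor, no
#' simple query carries any.  Query wording is rejection-sampled until the
#' title-keyword overlap sits near the spec's target for the mode.  The
#' ground truth of each query is its source document; query tags are copied
#' from it.
#'
#' @param corpus_bundle The list returned by [generate_corpus()] (`corpus` +
#'   `synonyms`).
#' @param spec The [fixture_spec()] used for generation.
#' @param mode `"simple"` or `"complex"`.
#' @return Query-set tibble with columns `query_text`, `ground_truth_ids`,
#'   `query_tags`, `complexity`, `n_distractors`.
#' @export
generate_query_set <- function(corpus_bundle, spec = fixture_spec(),
                               mode = c("simple", "complex")) {
  mode <- match.arg(mode)
  corpus <- corpus_bundle$corpus
  synonyms <- corpus_bundle$synonyms
  core_to_syn <- setNames(names(synonyms), synonyms)
  mode_seed <- spec$seed + if (mode == "simple") 1L else 2L
  withr::with_seed(mode_seed, {
    purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
      title_kw <- tokenize_and_clean(corpus$title[i], stopwords = character())
      body_tokens <- unique(
        tokenize_and_clean(corpus$body[i], stopwords = character())
      )
      core_extra <- setdiff(body_tokens, c(title_kw, filler_pool))
      syns <- core_to_syn[title_kw]
      syns[is.na(syns)] <- title_kw[is.na(syns)]
      q <- compose_query(title_kw, core_extra, unname(syns), mode, spec)
      tibble(
        query_text = q$text,
        ground_truth_ids = list(corpus$doc_id[i]),
        query_tags = corpus$tags[i],
        complexity = mode,
        n_distractors = if (mode == "simple") 0L else q$n_distractors
      )
    })
  })
}

#' Generate a synthetic abbreviation table for a corpus
#'
#' Samples distinct corpus terms and invents a short uppercase abbreviation
#' for each, so queries can be written in abbreviated form and expanded by
#' the preprocessing pipeline back to wording the corpus contains.
#'
#' @param corpus_bundle The list returned by [generate_corpus()].
#' @param n_entries Number of abbreviations (default 20).
#' @param seed Integer seed.
#' @return An abbreviation-table tibble (see [abbreviation_table()]).
#' @export
generate_abbreviation_table <- function(corpus_bundle, n_entries = 20,
                                        seed = 1) {
  stopifnot(n_entries >= 1)
  corpus <- corpus_bundle$corpus
  withr::with_seed(seed, {
    terms <- unique(unlist(lapply(
      corpus$body, tokenize_and_clean, stopwords = character()
    )))
    terms <- setdiff(terms, filler_pool)
    terms <- terms[nchar(terms) >= 4]
    terms <- sample(terms, min(n_entries, length(terms)))
    abbr <- toupper(substr(terms, 1, 3))
    dup <- duplicated(abbr)
    abbr[dup] <- paste0(abbr[dup], seq_len(sum(dup)))
    abbreviation_table(abbr, terms)
  })
}
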