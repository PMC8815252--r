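Package: guidematch
Title: Hybrid Semantic and TF-IDF Retrieval of Imaging Guideline Documents
    from Free-Text Clinical Indications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matches free-text clinical indications, as written in imaging
    orders, to guideline topic documents (such as imaging appropriateness
    criteria) with a hybrid ranking score: cosine similarity between a
    sentence embedding of the query and three embedded views of each document
    (its header of title plus variants, its full body, and its top TF-IDF
    n-gram features), combined as S = H + B + beta * T.  Includes the query
    preprocessing pipeline (abbreviation expansion, tokenization, stop-word
    removal, lemmatization, indication-section extraction), a deterministic
    toy embedding backend and an adapter for pretrained word-vector models,
    graded-relevance NDCG and top-k evaluation over annotated query sets, and
    a seeded generator of synthetic corpora and simple/complex benchmark
    queries with clinical distractors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
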