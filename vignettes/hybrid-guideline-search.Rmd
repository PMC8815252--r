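---
title: "Hybrid semantic + TF-IDF retrieval of guideline documents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid semantic + TF-IDF retrieval of guideline documents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(guidematch)
library(dplyr)
```

## The problem

Clinicians ordering imaging studies write a short free-text *clinical
indication* ("64yo M with flank pain, r/o stone").  Evidence-based imaging
guidelines — topic documents, each covering one clinical scenario and
carrying category tags — are underused largely because looking the right
document up takes time.  guidematch ranks guideline documents directly from
such free text, so a recommendation can be surfaced inside the ordering
workflow.

Clinical indications defeat ordinary keyword search: they are telegraphic,
abbreviation-heavy, and full of *distractors* — an age phrase, less-relevant
medical or social history, and synonymous wording that shares no tokens with
the document title ("kidney stones" for a document titled "Urolithiasis").

## The ranking model

Each document $i$ is represented by three embedded views:

* **Header** — title plus alternate titles, embedded raw;
* **Body** — the full text, cleaned (stop words, punctuation) and
  lemmatized;
* **TF-IDF features** — the document's top $k$ (default 50) n-grams by
  TF-IDF weight, joined into one text and embedded.

One shared embedding $q$ of the preprocessed query is compared against all
three views by cosine similarity, and the document score is

$$S_i = H_{q,i} + B_{q,i} + \beta\, T_{q,i},$$

where $H$, $B$, $T$ are the three cosines and $\beta \ge 0$ weights the
TF-IDF view.  The semantic views catch synonymous wording; the TF-IDF view
anchors ranking to each document's most characteristic phrases.  The default
is $\beta = 1$ (all views equal).  When queries carry little distracting
language, raising $\beta$ emphasizes exact phrase matching over semantic
similarity; with noisy EHR-style queries, lower $\beta$ lets the semantic
views dominate.  Documents are sorted by $S_i$ descending, ties broken by
document id so rankings are reproducible.  A view that embeds to the zero
vector (for example a body that is all stop words) contributes cosine 0
rather than being skipped, keeping scores comparable across documents.

Query preprocessing expands abbreviations by *appending* each matched
expansion once (the original text is always preserved as a prefix — an
expansion can only add signal, never destroy it), then tokenizes,
lowercases, and removes stop words and punctuation.  A query with no
embeddable tokens left raises a typed error (`guidematch_unsearchable_query`)
rather than returning an empty list: silently returning nothing is itself a
retrieval failure mode and the caller should see it.

### TF-IDF variant, pinned

Standard vectorizers differ in smoothing and normalization, so the exact
variant is fixed here for bit-reproducibility: vocabulary over uni-, bi-
and trigrams of the cleaned (not lemmatized) body text; smoothed
$\mathrm{idf}(t) = \ln\frac{1+N}{1+df_t} + 1$; per-document weights are raw
term counts times idf, normalized to unit Euclidean norm.  This is the
common default of the scikit-learn vectorizer family, and the test suite
pins it with hand-evaluated values (for a two-document corpus,
$\mathrm{idf} = \ln(3/3)+1 = 1$ for a shared term and $\ln(3/2)+1 \approx
1.4055$ for a unique one).  Top-feature selection sorts by weight
descending with lexicographic tie-breaks; selection order is invariant to
the positive rescaling, so normalized and unnormalized weights select the
same features.

### Lemmatization

Document bodies are lemmatized at indexing time; queries are not, by
default (`lemmatize_query` in `ranker_config()` flips this).  Rationale:
document text is curated prose where plural/singular variation is common,
while query tokens are often abbreviations or already-terse noun phrases,
and an over-eager lemmatizer can corrupt them.  The built-in lemmatizer is
rule-based (irregular-plural table plus plural-suffix rules); it
deliberately favors predictability over linguistic coverage, and any
length-preserving function can be plugged in via the `lemmatizer` argument
for users with a richer morphological backend.

## Embedding backends

The embedding contract is small: a deterministic map from text to a
fixed-dimension vector, with the zero vector reserved for unembeddable
text.  Sentence embedding is bag-of-tokens averaging, matching the
continuous-bag-of-words character of the sentence-embedding models this
engine targets (those models typically use dimension 700; the adapter takes
whatever the model file declares).

`pretrained_backend()` reads the word2vec/sent2vec text format.  No model
is bundled — training or downloading one is outside this package's scope.

`toy_backend()` exists so that everything above it is testable without a
model file: each token is canonicalized through a synonym table, hashed
(stable 32-bit hash), and the hash seeds a pseudorandom unit vector.
Consequences worth knowing:

* declared synonyms embed *identically* — an idealization of semantic
  similarity (a real model yields high, not perfect, cosine);
* unrelated tokens are nearly orthogonal (mean $|\cos| \approx 0.1$ at
  dimension 64), an idealization of semantic unrelatedness;
* there is no graded similarity between related-but-not-synonymous terms,
  and no bigram-level composition.

Benchmark results with the toy backend therefore validate the *machinery* —
preprocessing, scoring, ranking, evaluation — and the *direction* of
effects (distractors hurt; synonyms are recovered), not absolute retrieval
numbers on real clinical text.

## Evaluation

Relevance of document $i$ to a query is graded as the number of shared
category tags (the default vocabulary is seven etiology tags: vascular
disease, infection/inflammation, neoplasm, congenital, trauma, surgical,
many etiologies/topics).  Ranking quality is

$$NDCG = \frac{\sum_{i=1}^{n} rel_i/\log_2(i+1)}
             {\sum_{i=1}^{n} REL_i/\log_2(i+1)},$$

summed over **all** $n$ corpus documents (the displayed top-$k$ is a prefix
of the full ranking), with the denominator the ideal ordering.  NDCG of 1
is a perfect ranking.  When every document has zero relevance to a query
the measure is undefined; the convention here is 0 with a warning, so
degenerate annotations are visible rather than silently optimal.  The suite
cross-checks the implementation against a brute-force
maximum-over-permutations normalization on short lists.

`evaluate_queries()` also reports top-$k$ accuracy (mode *any*: at least
one ground-truth document in the top $k$; mode *all*: every one) and the
mean and standard deviation of the best ground-truth rank, overall and
broken down by query complexity and by document category.  Queries with no
matching document are excluded from accuracy denominators and counted
separately; unsearchable queries are recorded per query, not fatal.

## The synthetic benchmark

`generate_corpus()` and `generate_query_set()` build a test collection with
the statistical structure that makes clinical retrieval hard, at desk
scale, fully seeded:

* documents with largely disjoint core vocabularies (pseudo-words), titles
  of 2–3 keywords, 0–3 synonym-worded title variants, bodies of 50–200
  tokens mixing core words with shared clinical filler, 1–3 tags;
* one **simple** query per document: mostly title keywords plus filler;
* one **complex** query per document: title keywords rewritten as synonyms,
  plus distractors — an age phrase in text form ("72 year old"),
  less-relevant medical history ("history of hypertension diabetes
  mellitus"), less-relevant social history ("40 pack year smoker").  Every
  complex query carries at least one distractor; no simple query carries
  any.  Distractor phrase pools are short template lists in code.

Query wording is rejection-sampled (up to 200 draws, keeping the best) so
that the share of query words that are title keywords lands near 32% for
simple and 9% for complex queries — the calibration that separates clean
search-box queries from EHR-style indications.  The generator's synonym
table doubles as the toy backend's synonym table, so "semantic" recovery of
reworded keywords is exercised end to end.

Defaults: 50 documents, seed 42, distractor rates (age 0.8, history 0.6,
social 0.4, synonym 0.9).  Corpus pseudo-words never end in "s", so
document-side lemmatization cannot break the identity between query and
body tokens.  What this benchmark does *not* emulate: real clinical prose
style, graded semantic proximity, vocabulary shared across topics beyond
the filler pool, and multi-document ground truths.

```{r benchmark}
spec <- fixture_spec()            # 50 documents, seed 42
bundle <- generate_corpus(spec)
backend <- toy_backend(dimension = 64, seed = 0,
                       synonyms = bundle$synonyms)
index <- build_index(bundle$corpus, backend)

simple <- generate_query_set(bundle, spec, "simple")
complex <- generate_query_set(bundle, spec, "complex")
ev_simple <- evaluate_queries(simple, index, k = 3)
ev_complex <- evaluate_queries(complex, index, k = 3)

bind_rows(simple = glance(ev_simple), complex = glance(ev_complex),
          .id = "queries") |>
  select(queries, mean_ndcg, top_k_accuracy, mean_rank)
```

Simple queries are retrieved nearly perfectly; complex queries rank lower
on every metric — the qualitative ordering expected when distractors and
synonym rewording degrade keyword overlap.

```{r plot, fig.width = 7, fig.height = 4}
ev_both <- evaluate_queries(bind_rows(simple, complex), index, k = 3)
autoplot(ev_both)
```

## Numerical and design choices

* **Ties**: by document id in search, lexicographic by n-gram in feature
  selection — determinism everywhere the underlying math is indifferent.
* **Zero vectors**: cosine with a zero vector is defined as 0 (not NaN, not
  an error) so a missing view degrades gracefully.
* **Header join**: title and variants joined by single spaces, title first;
  variants are not weighted differently from the title.
* **Abbreviation matching**: whole-token and case-sensitive by default
  ("PE" the embolism vs "pe" in prose); a case-insensitive switch exists.
  Ambiguous abbreviations are a curation problem upstream of this engine.
* **TF-IDF on unlemmatized text**: the feature view indexes the documents'
  raw phrasing; lemmatized body text already covers normalized matching.
* **Benchmark sizes**: tests run the full benchmark at 50 documents and
  oracle comparisons on corpora of 3–20 documents with a 16–64-dimension
  toy backend — sizes at which exhaustive oracles (permutation NDCG,
  score-every-document search) are exact and fast.

## Limitations

* Retrieval quality on real corpora depends on the pretrained embedding
  model; nothing here trains one, and the toy backend's idealizations mean
  synthetic benchmark numbers are not forecasts of clinical performance.
* The toy backend averages unigram vectors only; models that also embed
  bigrams may rank multi-word idioms differently.
* The engine does no query refinement beyond abbreviation expansion, no
  approximate-nearest-neighbor indexing (corpora of a few hundred documents
  are scored exhaustively), and no learning-to-rank.
* Statistical comparison between engines or categories is out of scope;
  `tidy()` emits per-query values for any downstream stats package.
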