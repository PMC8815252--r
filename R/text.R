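#' Default English stop-word list
#'
#' The snowball English stop-word list (public domain), used when cleaning
#' document bodies and queries.  Any character vector can be substituted.
#'
#' @return Character vector of lowercase stop words.
#' @export
default_stopwords <- function() {
  c(
    "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "yourself", "yourselves", "he", "him", "his",
    "himself", "she", "her", "hers", "herself", "it", "its", "itself",
    "they", "them", "their", "theirs", "themselves", "what", "which",
    "who", "whom", "this", "that", "these", "those", "am", "is", "are",
    "was", "were", "be", "been", "being", "have", "has", "had", "having",
    "do", "does", "did", "doing", "would", "should", "could", "ought",
    "a", "an", "the", "and", "but", "if", "or", "because", "as", "until",
    "while", "of", "at", "by", "for", "with", "about", "against",
    "between", "into", "through", "during", "before", "after", "above",
    "below", "to", "from", "up", "down", "in", "out", "on", "off", "over",
    "under", "again", "further", "then", "once", "here", "there", "when",
    "where", "why", "how", "all", "any", "both", "each", "few", "more",
    "most", "other", "some", "such", "no", "nor", "not", "only", "own",
    "same", "so", "than", "too", "very", "s", "t", "can", "will", "just",
    "don", "now"
  )
}

#' Build or read an abbreviation table
#'
#' An abbreviation table maps single-token abbreviations to one or more
#' expansion texts.  The file format is a two-column UTF-8 CSV
#' (`abbreviation,expansion`); repeated abbreviation rows accumulate multiple
#' expansions.
#'
#' @param abbreviation,expansion Parallel character vectors.
#' @return A tibble with columns `abbreviation` and `expansion`.
#' @export
#' @examples
#' abbreviation_table(c("PE", "CHF"),
#'                    c("pulmonary embolism", "congestive heart failure"))
abbreviation_table <- function(abbreviation, expansion) {
  tbl <- tibble(
    abbreviation = as.character(abbreviation),
    expansion = as.character(expansion)
  )
  validate_abbreviation_table(tbl)
  tbl
}

validate_abbreviation_table <- function(tbl) {
  if (!all(c("abbreviation", "expansion") %in% names(tbl))) {
    abort("abbreviation table needs columns 'abbreviation' and 'expansion'")
  }
  if (any(grepl("\\s", tbl$abbreviation))) {
    abort("abbreviations must be single tokens (no whitespace)")
  }
  self <- tbl$abbreviation == tbl$expansion
  if (any(self)) {
    abort(paste0(
      "abbreviation maps to itself: ",
      paste(unique(tbl$abbreviation[self]), collapse = ", ")
    ))
  }
  invisible(tbl)
}

#' @rdname abbreviation_table
#' @param path CSV file to read or write.
#' @export
read_abbreviations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("abbreviation file not found: ", path))
  }
  tbl <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  names(tbl)[1:2] <- c("abbreviation", "expansion")
  validate_abbreviation_table(tbl)
  tbl
}

#' @rdname abbreviation_table
#' @param table Abbreviation table tibble.
#' @export
write_abbreviations <- function(table, path) {
  validate_abbreviation_table(table)
  readr::write_csv(table[, c("abbreviation", "expansion")], path,
                   progress = FALSE)
  invisible(table)
}

#' Expand clinical abbreviations in free text
#'
#' Every table entry whose abbreviation occurs as a whole token in the input
#' has its expansion appended to the text, exactly once per entry, in
#' first-occurrence order.  The original text is never altered: expansion
#' always returns the input as a prefix, so no information is lost if an
#' apparent abbreviation was nothing of the kind.
#'
#' Matching is whole-token and case-sensitive by default — clinical
#' abbreviations such as "PE" are case-meaningful.  Leading and trailing
#' punctuation on a token is ignored for matching, so "PE." still matches
#' "PE".
#'
#' @param text Character vector of free text (vectorized).
#' @param table Abbreviation table, see [abbreviation_table()].
#' @param case_sensitive Match abbreviation case exactly (default `TRUE`).
#' @return Character vector: each input followed by its matched expansions.
#' @export
#' @examples
#' tbl <- abbreviation_table("PE", "pulmonary embolism")
#' expand_abbreviations("r/o PE", tbl)
expand_abbreviations <- function(text, table, case_sensitive = TRUE) {
  if (is.null(table) || nrow(table) == 0) return(text)
  validate_abbreviation_table(table)
  vapply(text, function(one) {
    raw_tokens <- strsplit(one, "\\s+")[[1]]
    raw_tokens <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", raw_tokens)
    raw_tokens <- raw_tokens[nzchar(raw_tokens)]
    if (length(raw_tokens) == 0) return(one)
    abbr <- table$abbreviation
    tok <- raw_tokens
    if (!case_sensitive) {
      abbr <- tolower(abbr)
      tok <- tolower(tok)
    }
    # first-occurrence order of matched abbreviations in the text
    pos <- match(abbr, tok)
    hit <- which(!is.na(pos))
    if (length(hit) == 0) return(one)
    hit <- hit[order(pos[hit], hit)]
    expansions <- unique(table$expansion[hit])
    paste(c(one, expansions), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Tokenize text and drop stop words and punctuation
#'
#' Lowercases, extracts word tokens (runs of letters and digits), and removes
#' stop words.  Order is preserved and the operation is deterministic and
#' idempotent on its own (re-joined) output.
#'
#' @param text A single string.
#' @param stopwords Character vector of stop words to drop;
#'   [default_stopwords()] by default.
#' @return Character vector of clean lowercase tokens (possibly empty).
#' @export
#' @examples
#' tokenize_and_clean("Chest pain, with fever.", stopwords = "with")
tokenize_and_clean <- function(text, stopwords = default_stopwords()) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(character())
  tokens <- stringr::str_extract_all(
    stringr::str_to_lower(text), "[\\p{L}\\p{N}]+"
  )[[1]]
  tokens[!tokens %in% stopwords]
}

# irregular plurals the suffix rules would get wrong
irregular_lemmas <- c(
  men = "man", women = "woman", children = "child", teeth = "tooth",
  feet = "foot", criteria = "criterion", data = "datum",
  diagnoses = "diagnosis", stenoses = "stenosis", metastases = "metastasis",
  prostheses = "prosthesis", emboli = "embolus", calculi = "calculus",
  nuclei = "nucleus", fungi = "fungus", bacteria = "bacterium",
  vertebrae = "vertebra", sequelae = "sequela", mice = "mouse"
)

#' Lemmatize a token sequence
#'
#' Maps each token to its lemma with a rule-based English noun lemmatizer:
#' an irregular-plural table plus standard plural-suffix rules
#' (`*ies -> *y`, `*sses -> *ss`, `*xes`/`*ches`/`*shes`/`*zes` strip `es`,
#' other final `s` stripped).  Length-preserving and deterministic; the
#' backend is pluggable via `lemmatizer`.
#'
#' @param tokens Character vector of clean lowercase tokens.
#' @param lemmatizer Optional function `character -> character`
#'   (length-preserving) replacing the built-in rules.
#' @return Character vector of lemmas, same length as `tokens`.
#' @export
#' @examples
#' lemmatize(c("kidney", "stones"))
lemmatize <- function(tokens, lemmatizer = NULL) {
  if (length(tokens) == 0) return(character())
  if (!is.null(lemmatizer)) {
    out <- lemmatizer(tokens)
    if (length(out) != length(tokens)) {
      abort("custom lemmatizer must preserve length")
    }
    return(out)
  }
  out <- tokens
  irr <- match(out, names(irregular_lemmas))
  out[!is.na(irr)] <- irregular_lemmas[irr[!is.na(irr)]]
  todo <- is.na(irr)
  lemma_one <- function(w) {
    n <- nchar(w)
    if (n <= 3 || !grepl("s$", w)) return(w)
    if (grepl("(ss|us|is)$", w)) return(w)
    if (grepl("ies$", w) && n > 4) return(sub("ies$", "y", w))
    if (grepl("sses$", w)) return(sub("es$", "", w))
    if (grepl("(xes|ches|shes|zes)$", w)) return(sub("es$", "", w))
    sub("s$", "", w)
  }
  out[todo] <- vapply(out[todo], lemma_one, character(1), USE.NAMES = FALSE)
  out
}

#' Default section-header patterns for indication extraction
#' @return Character vector of header patterns, tried in order.
#' @export
default_section_patterns <- function() {
  c("INDICATION:", "CLINICAL INDICATION:", "HISTORY:")
}

#' Extract the clinical-indication section from report text
#'
#' Radiology reports carry the ordering clinician's free-text indication
#' under a section header.  The first pattern that matches marks the start of
#' the section; the span runs to the next section header (an uppercase word
#' run ending in ":") or the end of the text, and is trimmed.  Reports with
#' no matching header or a blank section yield `NA_character_` — such reports
#' are excluded from evaluation rather than searched with empty text.
#'
#' @param report_text Character vector of full report texts (vectorized).
#' @param patterns Ordered character vector of literal section-header
#'   patterns; [default_section_patterns()] by default.
#' @return Character vector: the indication text, or `NA_character_` when
#'   not found or blank.
#' @export
#' @examples
#' extract_indication("INDICATION: flank pain\nTECHNIQUE: CT")
extract_indication <- function(report_text,
                               patterns = default_section_patterns()) {
  if (length(patterns) == 0) abort("at least one section pattern required")
  vapply(report_text, function(one) {
    if (is.na(one)) return(NA_character_)
    start <- NA_integer_
    header_len <- 0L
    for (p in patterns) {
      loc <- regexpr(p, one, fixed = TRUE)
      if (loc > 0) {
        start <- as.integer(loc)
        header_len <- nchar(p)
        break
      }
    }
    if (is.na(start)) return(NA_character_)
    rest <- substring(one, start + header_len)
    nxt <- regexpr("[A-Z][A-Z /-]+:", rest)
    if (nxt > 0) rest <- substring(rest, 1, nxt - 1)
    rest <- trimws(rest)
    if (!nzchar(rest)) NA_character_ else rest
  }, character(1), USE.NAMES = FALSE)
}

#' Preprocess a query indication into clean tokens
#'
#' The full query pipeline: abbreviation expansion (expansions appended, the
#' original text kept), tokenization with stop-word and punctuation removal,
#' and optional lemmatization.
#'
#' @param text A single query string.
#' @param table Optional abbreviation table.
#' @param stopwords Stop words to drop.
#' @param lemmatize_tokens Lemmatize the cleaned tokens (default `FALSE` for
#'   queries; document bodies are lemmatized at indexing time).
#' @param case_sensitive Abbreviation matching case sensitivity.
#' @return Character vector of clean tokens (possibly empty).
#' @export
#' @examples
#' preprocess_query("r/o PE", abbreviation_table("PE", "pulmonary embolism"),
#'                  stopwords = character())
preprocess_query <- function(text, table = NULL,
                             stopwords = default_stopwords(),
                             lemmatize_tokens = FALSE,
                             case_sensitive = TRUE) {
  stopifnot(length(text) == 1)
  if (!is.null(table)) {
    text <- expand_abbreviations(text, table, case_sensitive = case_sensitive)
  }
  tokens <- tokenize_and_clean(text, stopwords = stopwords)
  if (lemmatize_tokens) tokens <- lemmatize(tokens)
  tokens
}
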