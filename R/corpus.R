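#' Default tag vocabulary for graded relevance
#'
#' The seven broad clinical-etiology tags used to grade how relevant a
#' guideline document is to a query: each document and each annotated query
#' carries one or more of these labels, and relevance is the number of labels
#' they share.
#'
#' @return Character vector of seven tag labels.
#' @export
#' @examples
#' default_tag_vocabulary()
default_tag_vocabulary <- function() {
  c(
    "vascular disease", "infection/inflammation", "neoplasm",
    "congenital", "trauma", "surgical", "many etiologies/topics"
  )
}

#' Construct a validated guideline corpus
#'
#' A corpus is a tibble with one row per guideline topic document and columns
#' `doc_id`, `title`, `variants` (list of character), `body`, `tags`
#' (list of character) and `category`.  `as_corpus()` normalizes and
#' validates a data frame into this shape.
#'
#' @param x Data frame with at least `doc_id`, `title`, `body`.  `variants`
#'   and `tags` may be list columns or semicolon-joined strings; missing
#'   `variants`/`tags`/`category` columns are filled with empties.
#' @param tag_vocabulary Allowed tag labels; defaults to
#'   [default_tag_vocabulary()].
#' @return A `guideline_corpus` tibble with a `tag_vocabulary` attribute.
#' @export
#' @examples
#' as_corpus(data.frame(
#'   doc_id = "urolithiasis", title = "Urolithiasis",
#'   body = "flank pain hematuria renal calculus"
#' ))
as_corpus <- function(x, tag_vocabulary = default_tag_vocabulary()) {
  x <- as_tibble(x)
  required <- c("doc_id", "title", "body")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "corpus is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"variants" %in% names(x)) x$variants <- vector("list", nrow(x))
  if (!"tags" %in% names(x)) x$tags <- vector("list", nrow(x))
  if (!"category" %in% names(x)) x$category <- NA_character_
  x$variants <- lapply(x$variants, split_listish)
  x$tags <- lapply(x$tags, split_listish)
  x <- x[, c("doc_id", "title", "variants", "body", "tags", "category")]
  x$doc_id <- as.character(x$doc_id)
  x$title <- as.character(x$title)
  x$body <- as.character(x$body)
  x$category <- as.character(x$category)
  validate_corpus(x, tag_vocabulary)
  structure(x,
    tag_vocabulary = tag_vocabulary,
    class = c("guideline_corpus", class(x))
  )
}

# accept list cells, plain vectors, or "a; b"-joined strings
split_listish <- function(cell) {
  if (is.null(cell) || length(cell) == 0) return(character())
  cell <- as.character(unlist(cell))
  cell <- cell[!is.na(cell)]
  cell <- unlist(strsplit(cell, ";", fixed = TRUE))
  cell <- trimws(cell)
  cell[nzchar(cell)]
}

validate_corpus <- function(x, tag_vocabulary) {
  if (any(!nzchar(x$doc_id) | is.na(x$doc_id))) {
    abort("every document needs a nonempty doc_id")
  }
  dup <- unique(x$doc_id[duplicated(x$doc_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate document id: ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(trimws(x$title)) | is.na(x$title))) {
    abort("every document needs a nonempty title")
  }
  if (any(!nzchar(trimws(x$body)) | is.na(x$body))) {
    abort("every document needs a nonempty body")
  }
  bad <- setdiff(unique(unlist(x$tags)), tag_vocabulary)
  if (length(bad) > 0) {
    abort(paste0(
      "tag(s) not in vocabulary: ", paste(bad, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Tag vocabulary attached to a corpus
#' @param corpus A `guideline_corpus`.
#' @return Character vector of allowed tags.
#' @export
tag_vocabulary <- function(corpus) {
  attr(corpus, "tag_vocabulary") %||% default_tag_vocabulary()
}

#' Read a guideline corpus from disk
#'
#' Two plain-text formats are supported.  `"json"` (canonical): a JSON array
#' of objects with keys `doc_id`, `title`, `variants`, `body`, `tags`,
#' `category`.  `"csv"`: UTF-8 comma-separated with one row per document and
#' `variants`/`tags` as semicolon-joined lists.
#'
#' Unknown tags are an error, never silently dropped.
#'
#' @param path File to read.
#' @param format `"json"` or `"csv"`.
#' @inheritParams as_corpus
#' @return A `guideline_corpus` tibble.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, format = c("json", "csv"),
                        tag_vocabulary = default_tag_vocabulary()) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("corpus file not found: ", path))
  }
  x <- switch(format,
    json = as_tibble(jsonlite::fromJSON(path, simplifyDataFrame = TRUE)),
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  )
  as_corpus(x, tag_vocabulary = tag_vocabulary)
}

#' Write a guideline corpus to disk
#'
#' `read_corpus()` after `write_corpus()` reproduces the corpus
#' field-for-field in either format.
#'
#' @param corpus A `guideline_corpus`.
#' @inheritParams read_corpus
#' @return `corpus`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    out <- lapply(seq_len(nrow(corpus)), function(i) {
      list(
        doc_id = corpus$doc_id[i],
        title = corpus$title[i],
        variants = as.list(corpus$variants[[i]]),
        body = corpus$body[i],
        tags = as.list(corpus$tags[[i]]),
        category = corpus$category[i]
      )
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
  } else {
    flat <- tibble(
      doc_id = corpus$doc_id,
      title = corpus$title,
      variants = vapply(corpus$variants, paste, "", collapse = ";"),
      body = corpus$body,
      tags = vapply(corpus$tags, paste, "", collapse = ";"),
      category = corpus$category
    )
    readr::write_csv(flat, path, progress = FALSE)
  }
  if (!file.exists(path)) abort(paste0("could not write corpus to ", path))
  invisible(corpus)
}

#' Document header text: title plus variants
#'
#' The header view of a document is its title followed by all alternate
#' titles, joined by single spaces, title first and variant order preserved.
#' This is the text embedded into the header vector of the index.
#'
#' @param x A `guideline_corpus` (or any data frame with `title` and
#'   `variants` columns), or a single title string.
#' @param variants Character vector of alternate titles when `x` is a title
#'   string.
#' @return Character vector of header texts, one per document.
#' @export
#' @examples
#' header_text("Urolithiasis", c("kidney stones"))
header_text <- function(x, variants = character()) {
  if (is.character(x)) {
    return(paste(c(x, variants), collapse = " "))
  }
  vapply(
    seq_len(nrow(x)),
    function(i) paste(c(x$title[i], x$variants[[i]]), collapse = " "),
    character(1)
  )
}

#' @export
print.guideline_corpus <- function(x, ...) {
  cat("<guideline_corpus> ", nrow(x), " documents, ",
      length(tag_vocabulary(x)), " tags in vocabulary\n", sep = "")
  NextMethod()
}
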