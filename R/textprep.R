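#' Stopword sets
#'
#' The default stopword list ships with the package: a standard English list
#' extended with forum pleasantries ("thanks", "xx", "hugs", ...) that carry
#' no clinical meaning. Files hold one word per line; `#` starts a comment.
#'
#' @param path Path to a stopword file; `NULL` loads the shipped default.
#' @return Character vector of lowercase stopwords (class `stopword_set`).
#' @export
read_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "ontomine")
  }
  if (!file.exists(path)) stop("no such stopword file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  words <- tolower(trimws(lines))
  words <- unique(words[nzchar(words)])
  structure(words, class = "stopword_set")
}

#' Tokenize raw text
#'
#' Lowercases and splits on any character outside `[a-z0-9]`, so hyphenated
#' terms split into their parts and punctuation never sticks to tokens.
#' Numerals are kept: clinical grading terms ("grade 1") are meaningful.
#'
#' @param text Character scalar (may be empty).
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(character())
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Preprocess post text into a cleaned token stream
#'
#' The normalization the mining stage assumes: lowercase, tokenize on
#' non-alphanumeric boundaries, drop stopwords, then Porter-stem every
#' remaining token (so "pained", "painful" and "pains" all become "pain").
#' A total function: empty or all-stopword text yields an empty stream.
#'
#' @param text Raw post text (character scalar).
#' @param stopwords A [read_stopwords()] set (default: the shipped list).
#' @return Character vector of lowercase stems.
#' @examples
#' preprocess("The pains were painful, thanks xx")
#' @export
preprocess <- function(text, stopwords = read_stopwords()) {
  toks <- tokenize(text)
  toks <- toks[!(toks %in% stopwords)]
  porter_stem(toks)
}
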