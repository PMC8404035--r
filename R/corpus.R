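#' Forum corpus objects
#'
#' A `forum_corpus` is a tibble of posts — one row per post with columns
#' `post_id`, `thread_id`, `forum_id`, `position` and `text` — carrying the
#' class `forum_corpus`. Threads are implicit: all posts sharing a
#' `thread_id`, ordered by `position`, with `position == 0` marking the
#' thread-opening post. This flat shape mirrors the serialized formats
#' (JSON Lines or CSV, one record per post) and keeps every dplyr verb
#' available for downstream grouping.
#'
#' @param posts A data frame with columns `post_id`, `thread_id`, `forum_id`,
#'   `position` (non-negative integer; 0 = first post of its thread) and
#'   `text` (character, may be empty but not `NA`).
#' @return A `forum_corpus` tibble.
#' @examples
#' corpus <- forum_corpus(tibble::tibble(
#'   post_id = c("p1", "p2", "p3"),
#'   thread_id = c("t1", "t1", "t2"),
#'   forum_id = "OV",
#'   position = c(0L, 1L, 0L),
#'   text = c("my eye hurts", "mine too", "blurry vision again")
#' ))
#' summarize_corpus(corpus)
#' @export
forum_corpus <- function(posts) {
  posts <- tibble::as_tibble(posts)
  required <- c("post_id", "thread_id", "forum_id", "position", "text")
  missing <- setdiff(required, names(posts))
  if (length(missing) > 0) {
    stop("corpus is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  posts$post_id <- as.character(posts$post_id)
  posts$thread_id <- as.character(posts$thread_id)
  posts$forum_id <- as.character(posts$forum_id)
  posts$position <- as.integer(posts$position)
  posts$text <- as.character(posts$text)
  validate_corpus(posts)
  posts <- posts[order(posts$forum_id, posts$thread_id, posts$position), required]
  structure(posts, class = c("forum_corpus", class(tibble::tibble())))
}

validate_corpus <- function(posts) {
  if (anyNA(posts$post_id) || anyNA(posts$thread_id) || anyNA(posts$forum_id)) {
    stop("post_id, thread_id and forum_id must not be missing", call. = FALSE)
  }
  if (anyNA(posts$text)) stop("post text may be empty but not absent", call. = FALSE)
  if (anyNA(posts$position) || any(posts$position < 0)) {
    stop("position must be a non-negative integer", call. = FALSE)
  }
  if (anyDuplicated(posts$post_id)) {
    dup <- posts$post_id[duplicated(posts$post_id)][1]
    stop("duplicate post_id: ", dup, call. = FALSE)
  }
  firsts <- posts[posts$position == 0L, ]
  if (anyDuplicated(firsts$thread_id)) {
    dup <- firsts$thread_id[duplicated(firsts$thread_id)][1]
    stop("thread ", dup, " has more than one post at position 0", call. = FALSE)
  }
  # a thread lives in exactly one forum
  tf <- unique(posts[, c("thread_id", "forum_id")])
  if (anyDuplicated(tf$thread_id)) {
    dup <- tf$thread_id[duplicated(tf$thread_id)][1]
    stop("thread ", dup, " spans more than one forum_id", call. = FALSE)
  }
  invisible(posts)
}

#' @export
print.forum_corpus <- function(x, ...) {
  cat(sprintf("<forum_corpus> %d posts, %d threads, %d forum(s)\n",
              nrow(x), length(unique(x$thread_id)),
              length(unique(x$forum_id))))
  NextMethod()
}

#' Read a forum corpus from JSON Lines or CSV
#'
#' JSON Lines is the canonical format: one post object per line with keys
#' `post_id`, `thread_id`, `forum_id`, `position`, `text`. CSV is a
#' convenience dialect with the same columns, UTF-8, quoted text.
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` or `"csv"`. Defaults from the file extension.
#' @return A [forum_corpus()].
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- resolve_format(path, format)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(empty_corpus())
    records <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) {
                        stop("malformed JSONL record at line ", i, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
      need <- c("post_id", "thread_id", "forum_id", "position", "text")
      absent <- setdiff(need, names(rec))
      if (length(absent) > 0) {
        stop("record at line ", i, " missing field(s): ",
             paste(absent, collapse = ", "), call. = FALSE)
      }
      records[[i]] <- tibble::tibble(
        post_id = as.character(rec$post_id),
        thread_id = as.character(rec$thread_id),
        forum_id = as.character(rec$forum_id),
        position = as.integer(rec$position),
        text = as.character(rec$text)
      )
    }
    posts <- dplyr::bind_rows(records)
  } else {
    posts <- readr::read_csv(path, col_types = readr::cols(
      post_id = readr::col_character(),
      thread_id = readr::col_character(),
      forum_id = readr::col_character(),
      position = readr::col_integer(),
      text = readr::col_character()
    ), locale = readr::locale(encoding = "UTF-8"), progress = FALSE)
    if (nrow(posts) == 0) return(empty_corpus())
    posts$text[is.na(posts$text)] <- ""
  }
  forum_corpus(posts)
}

empty_corpus <- function() {
  forum_corpus(tibble::tibble(post_id = character(), thread_id = character(),
                              forum_id = character(), position = integer(),
                              text = character()))
}

resolve_format <- function(path, format) {
  if (length(format) == 1) return(match.arg(format, c("jsonl", "csv")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl"
  else if (ext == "csv") "csv"
  else "jsonl"
}

#' Write a forum corpus
#'
#' Round-trips with [read_corpus()] field-for-field, including unicode text.
#'
#' @param corpus A [forum_corpus()].
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  stopifnot(inherits(corpus, "forum_corpus"))
  format <- resolve_format(path, format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(list(post_id = corpus$post_id[i],
                            thread_id = corpus$thread_id[i],
                            forum_id = corpus$forum_id[i],
                            position = corpus$position[i],
                            text = corpus$text[i]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    readr::write_csv(tibble::as_tibble(corpus), path, progress = FALSE)
  }
  invisible(path)
}

#' Thread-level view of a corpus
#'
#' @param corpus A [forum_corpus()].
#' @return A tibble with one row per thread: `thread_id`, `forum_id`, `size`.
#' @export
corpus_threads <- function(corpus) {
  stopifnot(inherits(corpus, "forum_corpus"))
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(corpus),
                                   .data$thread_id, .data$forum_id),
                   size = dplyr::n(), .groups = "drop")
}

#' Per-forum descriptive summary
#'
#' Posts-per-thread mean and standard deviation per forum; the sd uses the
#' sample (n - 1) denominator. Forums with a single thread report sd 0.
#'
#' @param corpus A [forum_corpus()].
#' @return A tibble with columns `forum_id`, `n_posts`, `n_threads`,
#'   `mean_posts_per_thread`, `sd_posts_per_thread`, `min_thread_size`,
#'   `max_thread_size`.
#' @export
summarize_corpus <- function(corpus) {
  th <- corpus_threads(corpus)
  if (nrow(th) == 0) {
    warning("corpus has no threads; empty summary", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(th, .data$forum_id),
    n_posts = sum(.data$size),
    n_threads = dplyr::n(),
    mean_posts_per_thread = mean(.data$size),
    sd_posts_per_thread = if (dplyr::n() > 1) stats::sd(.data$size) else 0,
    min_thread_size = min(.data$size),
    max_thread_size = max(.data$size),
    .groups = "drop"
  )
  out
}
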