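#' Tag a post against the term index
#'
#' Dictionary named-entity tagging on the raw (not stemmed) text:
#' case-insensitive, word-boundary-anchored matching — a boundary is a
#' transition to a non-alphanumeric character or a string end, so "mtx,"
#' matches "mtx". Candidate terms are tried longest-first and matches are
#' taken greedily left to right without overlap, so "anterior uveitis" beats
#' "uveitis" on the same span. Offsets are 0-based, half-open, in characters.
#'
#' @param text Raw post text (character scalar).
#' @param index A [build_term_index()] term index.
#' @return Tibble `class_id`, `start`, `end`, `surface`, ordered by `start`.
#' @export
tag_post <- function(text, index) {
  empty <- tibble::tibble(class_id = character(), start = integer(),
                          end = integer(), surface = character())
  if (is.na(text) || !nzchar(text) || nrow(index) == 0) return(empty)
  lower <- tolower(text)
  n <- nchar(lower)
  is_word <- function(pos) {
    pos >= 1 && pos <= n && grepl("[a-z0-9]", substr(lower, pos, pos))
  }
  cand <- list()
  for (i in seq_len(nrow(index))) {
    term <- index$term[i]
    starts <- gregexpr(term, lower, fixed = TRUE)[[1]]
    if (starts[1] == -1) next
    len <- nchar(term)
    for (s in starts) {
      if (is_word(s - 1) || is_word(s + len)) next  # not boundary-anchored
      cand[[length(cand) + 1]] <- c(start = s, len = len, idx = i)
    }
  }
  if (length(cand) == 0) return(empty)
  cm <- do.call(rbind, cand)
  # greedy left-to-right, longest-first at each start (index is sorted
  # longest-first, so lower idx = longer-or-equal term)
  cm <- cm[order(cm[, "start"], -cm[, "len"], cm[, "idx"]), , drop = FALSE]
  taken_until <- 0
  keep <- logical(nrow(cm))
  for (r in seq_len(nrow(cm))) {
    if (cm[r, "start"] > taken_until) {
      keep[r] <- TRUE
      taken_until <- cm[r, "start"] + cm[r, "len"] - 1
    }
  }
  cm <- cm[keep, , drop = FALSE]
  tibble::tibble(
    class_id = index$class_id[cm[, "idx"]],
    start = as.integer(cm[, "start"] - 1L),
    end = as.integer(cm[, "start"] - 1L + cm[, "len"]),
    surface = substr(rep(text, nrow(cm)), cm[, "start"],
                     cm[, "start"] + cm[, "len"] - 1)
  )
}

#' Tag every post of a corpus
#'
#' @param corpus A [forum_corpus()].
#' @param index A [build_term_index()] term index.
#' @return Tibble `post_id`, `forum_id`, `class_id`, `start`, `end`,
#'   `surface` — one row per match, in corpus order; posts without matches
#'   contribute no rows.
#' @export
tag_corpus <- function(corpus, index) {
  posts <- tibble::as_tibble(corpus)
  res <- lapply(seq_len(nrow(posts)), function(i) {
    m <- tag_post(posts$text[i], index)
    if (nrow(m) == 0) return(NULL)
    tibble::tibble(post_id = posts$post_id[i], forum_id = posts$forum_id[i], m)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(post_id = character(), forum_id = character(),
                          class_id = character(), start = integer(),
                          end = integer(), surface = character())
  }
  out
}

#' Per-forum class frequency table
#'
#' Counts posts containing at least one mention of each class — presence-
#' based, so repeat mentions within a post count once — with the percentage
#' of each forum's posts.
#'
#' @param tags Tag table from [tag_corpus()].
#' @param corpus The tagged [forum_corpus()] (supplies per-forum totals).
#' @return Tibble `class_id`, `forum_id`, `n_posts_mentioning`, `percent`,
#'   `forum_total`.
#' @export
frequency_table <- function(tags, corpus) {
  posts <- tibble::as_tibble(corpus)
  totals <- dplyr::count(posts, .data$forum_id, name = "forum_total")
  if (any(totals$forum_total == 0)) {
    warning("forum with zero posts omitted", call. = FALSE)
    totals <- totals[totals$forum_total > 0, ]
  }
  hits <- dplyr::distinct(tags, .data$forum_id, .data$class_id, .data$post_id)
  counts <- dplyr::count(hits, .data$class_id, .data$forum_id,
                         name = "n_posts_mentioning")
  # every class x forum combination, zero-filled
  grid <- expand.grid(class_id = unique(tags$class_id),
                      forum_id = totals$forum_id,
                      stringsAsFactors = FALSE)
  out <- dplyr::left_join(tibble::as_tibble(grid), counts,
                          by = c("class_id", "forum_id"))
  out$n_posts_mentioning[is.na(out$n_posts_mentioning)] <- 0L
  out <- dplyr::inner_join(out, totals, by = "forum_id")
  out$percent <- 100 * out$n_posts_mentioning / out$forum_total
  out[order(out$class_id, out$forum_id), ]
}

#' Post-count gain from adding synonyms
#'
#' The percentage increase in posts identified when synonyms are included in
#' the index relative to labels alone: `100 * (with - without) / without`,
#' rounded to the nearest integer percent. The with-synonyms count can never
#' be below the labels-only count (index enlargement is monotone); a
#' labels-only count of zero makes the increase undefined (`Inf` — the class
#' was only ever reached through its synonyms).
#'
#' @param count_labels_only Posts mentioning the class via labels alone.
#' @param count_with_synonyms Posts mentioning it with synonyms included.
#' @return Percent increase, rounded to the nearest integer (or `Inf`).
#' @examples
#' synonym_impact(185, 333) # 80
#' synonym_impact(7, 218)   # 3014
#' @export
synonym_impact <- function(count_labels_only, count_with_synonyms) {
  stopifnot(count_labels_only >= 0, count_with_synonyms >= 0)
  if (count_with_synonyms < count_labels_only) {
    stop("with-synonyms count below labels-only count: ",
         "the synonym index must be a superset", call. = FALSE)
  }
  if (count_labels_only == 0) {
    if (count_with_synonyms == 0) return(0)
    return(Inf)
  }
  round(100 * (count_with_synonyms - count_labels_only) / count_labels_only)
}
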