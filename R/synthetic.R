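# Seeded synthetic-forum generator. Emulates the statistical structure the
# pipeline assumes: a zero-truncated negative-binomial thread-size
# distribution, clinical terms and lay synonyms planted at per-forum
# per-post mention rates (optionally misspelled by single-character edits),
# and a sentiment effect in which first posts draw from a negative word
# pool with a configurable odds ratio relative to replies.

default_filler_vocabulary <- function() {
  c("appointment", "clinic", "doctor", "consultant", "week", "month", "year",
    "today", "yesterday", "morning", "evening", "letter", "phone", "call",
    "question", "answer", "update", "news", "result", "test", "check",
    "routine", "visit", "waiting", "list", "referral", "review", "note",
    "advice", "experience", "story", "post", "thread", "reply", "forum",
    "group", "family", "school", "work", "holiday", "travel", "home",
    "daughter", "son", "child", "husband", "wife", "friend", "people",
    "everyone", "anyone", "someone", "thing", "things", "time", "times",
    "day", "days", "bit", "lot", "little", "another", "different", "new",
    "old", "long", "short", "first", "last", "next", "area", "local",
    "hospital", "nurse", "team", "department", "unit", "read", "reading",
    "wondering", "thinking", "hoping", "asking", "looking", "trying",
    "started", "starting", "stopped", "continue", "change", "changed",
    "dose", "level", "number", "record", "chart", "plan", "option")
}

default_planted_terms <- function() {
  tibble::tibble(
    class_id = c("OCIMIDO:00213", "OCIMIDO:00301", "OCIMIDO:00302",
                 "OCIMIDO:00141", "OCIMIDO:00303"),
    label = c("uveitis", "methotrexate", "adalimumab", "blurred vision",
              "prednisolone"),
    synonyms = list("iritis", "mtx", "humira", "blurry", "pred")
  )
}

#' Configuration for the synthetic forum generator
#'
#' Defaults reproduce the conditions the pipeline targets: thread sizes from
#' a zero-truncated negative binomial whose truncated mean/sd are 5.2/3.9
#' posts per thread, planted clinical terms mentioned in 5% of posts, and
#' first posts 3.3 times more likely (on the odds scale) than replies to
#' draw their emotional words from the negative pool of the shipped
#' sentiment lexicon.
#'
#' @param n_threads Named integer vector: threads per forum,
#'   e.g. `c(OV = 416)`.
#' @param seed Integer seed (mandatory; generation is fully deterministic).
#' @param thread_size_mean,thread_size_sd Target mean and sd of posts per
#'   thread after zero-truncation.
#' @param planted_terms Tibble with columns `class_id`, `label` and a list
#'   column `synonyms`; planted mention surfaces are drawn uniformly from
#'   the synonyms (or the label when a term has none).
#' @param mention_rate Per-post probability that each planted term is
#'   mentioned; a scalar, or a named vector by forum.
#' @param misspelling_rate Probability that a planted mention is corrupted
#'   by a single-character substitution after the first character.
#' @param first_post_negativity_or Odds ratio for a first post drawing from
#'   the negative word pool, relative to replies.
#' @param reply_negative_rate Probability a reply draws from the negative
#'   pool (the baseline the odds ratio acts on).
#' @param vocabulary Background filler word list (disjoint from the
#'   sentiment lexicon by default so pools stay identifiable).
#' @param filler_words Range (length 2) of filler words per post.
#' @param sentiment_words Range (length 2) of pool words per post (minimum
#'   1, so every post carries a sentiment signal).
#' @param lexicon Sentiment lexicon used for the word pools
#'   (default: the shipped one, see [read_sentiment_lexicon()]).
#' @return A `forum_sim_config` list.
#' @export
forum_sim_config <- function(n_threads = c(OV = 416),
                             seed,
                             thread_size_mean = 5.2,
                             thread_size_sd = 3.9,
                             planted_terms = default_planted_terms(),
                             mention_rate = 0.05,
                             misspelling_rate = 0,
                             first_post_negativity_or = 3.3,
                             reply_negative_rate = 0.35,
                             vocabulary = default_filler_vocabulary(),
                             filler_words = c(6L, 12L),
                             sentiment_words = c(1L, 3L),
                             lexicon = read_sentiment_lexicon()) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(names(n_threads)) || any(!nzchar(names(n_threads)))) {
    stop("n_threads must be a named vector (names are forum ids)", call. = FALSE)
  }
  if (any(n_threads < 1)) stop("n_threads must be >= 1 per forum", call. = FALSE)
  stopifnot(misspelling_rate >= 0, misspelling_rate <= 1,
            first_post_negativity_or > 0,
            reply_negative_rate > 0, reply_negative_rate < 1,
            sentiment_words[1] >= 1)
  if (any(mention_rate < 0) || any(mention_rate > 1)) {
    stop("mention_rate must be in [0, 1]", call. = FALSE)
  }
  planted_terms <- tibble::as_tibble(planted_terms)
  if (nrow(planted_terms) > 0) {
    if (any(!valid_curie(planted_terms$class_id))) {
      stop("planted term class ids must be valid CURIEs", call. = FALSE)
    }
    if (anyDuplicated(planted_terms$class_id)) {
      stop("duplicate planted class id", call. = FALSE)
    }
  }
  structure(list(
    n_threads = n_threads, seed = as.integer(seed),
    thread_size_mean = thread_size_mean, thread_size_sd = thread_size_sd,
    planted_terms = planted_terms, mention_rate = mention_rate,
    misspelling_rate = misspelling_rate,
    first_post_negativity_or = first_post_negativity_or,
    reply_negative_rate = reply_negative_rate,
    vocabulary = vocabulary, filler_words = filler_words,
    sentiment_words = sentiment_words, lexicon = lexicon
  ), class = "forum_sim_config")
}

# Solve untruncated NB (mu, size) so the zero-truncated distribution has the
# target mean and sd. Moments of the truncation: with p0 = P(X = 0),
# E[X | X>0] = mu / (1 - p0) and E[X^2 | X>0] = (mu + mu^2(1 + 1/size)) / (1 - p0).
ztnb_solve <- function(target_mean, target_sd) {
  if (target_mean <= 1 || target_sd <= 0) {
    stop("impossible thread-size distribution parameters", call. = FALSE)
  }
  obj <- function(par) {
    mu <- exp(par[1]); size <- exp(par[2])
    p0 <- (size / (size + mu))^size
    m <- mu / (1 - p0)
    e2 <- (mu + mu^2 * (1 + 1 / size)) / (1 - p0)
    v <- e2 - m^2
    if (!is.finite(v) || v <= 0) return(1e6)
    (m - target_mean)^2 + (sqrt(v) - target_sd)^2
  }
  fit <- stats::optim(c(log(target_mean), log(2)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$value > 1e-6) {
    stop("impossible thread-size distribution parameters (mean ",
         target_mean, ", sd ", target_sd, ")", call. = FALSE)
  }
  list(mu = exp(fit$par[1]), size = exp(fit$par[2]))
}

rztnb <- function(n, mu, size) {
  x <- stats::rnbinom(n, mu = mu, size = size)
  while (any(x == 0)) {
    idx <- which(x == 0)
    x[idx] <- stats::rnbinom(length(idx), mu = mu, size = size)
  }
  x
}

misspell_once <- function(word) {
  n <- nchar(word)
  if (n < 2) return(word)
  pos <- sample(2:n, 1)
  old <- substr(word, pos, pos)
  repl <- sample(setdiff(letters, old), 1)
  paste0(substr(word, 1, pos - 1), repl,
         if (pos < n) substr(word, pos + 1, n) else "")
}

#' Generate a synthetic forum corpus with ground truth
#'
#' Deterministic for a fixed seed. Post text is assembled as a shuffled bag
#' of phrases: neutral filler words, one or more words from the sentiment
#' pool assigned to the post, and any planted term mentions — so every
#' planted mention string appears verbatim in the text and is recorded in
#' the ground truth.
#'
#' @param config A [forum_sim_config()].
#' @return A list with elements `corpus` (a [forum_corpus()]) and `truth`:
#'   `mentions` (post_id, forum_id, class_id, surface, misspelled),
#'   `sentiment` (post_id, forum_id, first_post, negative_pool), and
#'   `mention_counts` (forum_id, class_id, n_posts — distinct posts with a
#'   planted mention).
#' @export
generate_forum <- function(config) {
  stopifnot(inherits(config, "forum_sim_config"))
  set.seed(config$seed)
  nb <- ztnb_solve(config$thread_size_mean, config$thread_size_sd)

  lex <- config$lexicon
  neg_pool <- lex$token[lex$polarity < 0]
  pos_pool <- lex$token[lex$polarity > 0]
  if (length(neg_pool) == 0 || length(pos_pool) == 0) {
    stop("lexicon must contain both negative and positive words", call. = FALSE)
  }

  odds_reply <- config$reply_negative_rate / (1 - config$reply_negative_rate)
  odds_first <- odds_reply * config$first_post_negativity_or
  p_first <- odds_first / (1 + odds_first)

  posts_all <- list(); mentions_all <- list()
  for (forum in names(config$n_threads)) {
    n_th <- config$n_threads[[forum]]
    sizes <- rztnb(n_th, nb$mu, nb$size)
    thread_id <- sprintf("%s-t%05d", forum, seq_len(n_th))
    posts <- tibble::tibble(
      thread_id = rep(thread_id, sizes),
      forum_id = forum,
      position = unlist(lapply(sizes, function(s) seq_len(s) - 1L),
                        use.names = FALSE)
    )
    posts$post_id <- sprintf("%s-p%06d", forum, seq_len(nrow(posts)))
    first <- posts$position == 0L
    negative <- stats::runif(nrow(posts)) <
      ifelse(first, p_first, config$reply_negative_rate)

    rate <- if (length(config$mention_rate) > 1) {
      if (!forum %in% names(config$mention_rate)) {
        stop("mention_rate has no entry for forum ", forum, call. = FALSE)
      }
      config$mention_rate[[forum]]
    } else {
      config$mention_rate
    }
    n_terms <- nrow(config$planted_terms)
    mention <- if (n_terms > 0) {
      matrix(stats::runif(nrow(posts) * n_terms) < rate, ncol = n_terms)
    } else {
      matrix(FALSE, nrow(posts), 0)
    }

    text <- character(nrow(posts))
    ment_rows <- list()
    for (i in seq_len(nrow(posts))) {
      n_fill <- sample(config$filler_words[1]:config$filler_words[2], 1)
      tokens <- sample(config$vocabulary, n_fill, replace = TRUE)
      n_sent <- sample(config$sentiment_words[1]:config$sentiment_words[2], 1)
      pool <- if (negative[i]) neg_pool else pos_pool
      tokens <- c(tokens, sample(pool, n_sent, replace = TRUE))
      for (j in which(mention[i, ])) {
        syns <- config$planted_terms$synonyms[[j]]
        surface <- if (length(syns) > 0) {
          if (length(syns) == 1) syns else sample(syns, 1)
        } else {
          config$planted_terms$label[j]
        }
        misspelled <- stats::runif(1) < config$misspelling_rate
        if (misspelled) surface <- misspell_once(surface)
        tokens <- c(tokens, surface)
        ment_rows[[length(ment_rows) + 1]] <- tibble::tibble(
          post_id = posts$post_id[i], forum_id = forum,
          class_id = config$planted_terms$class_id[j],
          surface = surface, misspelled = misspelled)
      }
      text[i] <- paste(sample(tokens), collapse = " ")
    }
    posts$text <- text
    posts$first_post <- first
    posts$negative_pool <- negative
    posts_all[[forum]] <- posts
    mentions_all[[forum]] <- dplyr::bind_rows(ment_rows)
  }
  posts <- dplyr::bind_rows(posts_all)
  mentions <- dplyr::bind_rows(mentions_all)
  if (nrow(mentions) == 0) {
    mentions <- tibble::tibble(post_id = character(), forum_id = character(),
                               class_id = character(), surface = character(),
                               misspelled = logical())
  }
  counts <- if (nrow(mentions) > 0) {
    dplyr::summarise(
      dplyr::group_by(dplyr::distinct(mentions, .data$forum_id,
                                      .data$class_id, .data$post_id),
                      .data$forum_id, .data$class_id),
      n_posts = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble(forum_id = character(), class_id = character(),
                   n_posts = integer())
  }
  list(
    corpus = forum_corpus(posts[, c("post_id", "thread_id", "forum_id",
                                    "position", "text")]),
    truth = list(
      mentions = mentions,
      sentiment = posts[, c("post_id", "forum_id", "first_post",
                            "negative_pool")],
      mention_counts = counts
    )
  )
}

#' Build a toy ontology from planted terms
#'
#' One class per planted term, labels set, no synonyms: the synonyms are
#' what the mining loop must recover.
#'
#' @param planted_terms Tibble with `class_id`, `label` (a
#'   [forum_sim_config()]'s `planted_terms` works directly).
#' @return An [ontology()].
#' @export
generate_toy_ontology <- function(planted_terms) {
  planted_terms <- tibble::as_tibble(planted_terms)
  if (nrow(planted_terms) == 0) return(ontology())
  ontology(classes = tibble::tibble(id = planted_terms$class_id,
                                    label = planted_terms$label))
}
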