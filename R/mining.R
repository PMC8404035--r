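#' Mining configuration
#'
#' Parameters of the iterative tf-idf synonym-mining procedure. Defaults:
#' threads are stratified into 3 equal-frequency size bins, a random 20%
#' of threads form the test set, terms scoring above 1.0 are reviewed, the
#' loop runs at most 10 rounds, and each thread (its posts concatenated in
#' position order) is one document.
#'
#' @param n_bins Number of equal-frequency thread-size bins (>= 1).
#' @param test_fraction Fraction of threads per bin drawn into the test set.
#' @param score_threshold Review threshold tau: terms scoring above it go to
#'   the curator.
#' @param max_rounds Maximum curate-remove-rerank rounds.
#' @param document_unit `"thread"` (default) or `"post"`.
#' @param aggregate Corpus-level tf-idf aggregation across documents:
#'   `"max"` (default; preserves the "score above 1" review semantics) or
#'   `"sum"`.
#' @param seed Integer seed for the split.
#' @return A `mining_config` list.
#' @export
mining_config <- function(n_bins = 3L, test_fraction = 0.2,
                          score_threshold = 1.0, max_rounds = 10L,
                          document_unit = c("thread", "post"),
                          aggregate = c("max", "sum"), seed = 1L) {
  stopifnot(n_bins >= 1, test_fraction > 0, test_fraction < 1,
            score_threshold >= 0, max_rounds >= 1)
  structure(list(n_bins = as.integer(n_bins), test_fraction = test_fraction,
                 score_threshold = score_threshold,
                 max_rounds = as.integer(max_rounds),
                 document_unit = match.arg(document_unit),
                 aggregate = match.arg(aggregate),
                 seed = as.integer(seed)),
            class = "mining_config")
}

#' Stratified train/test split by thread size
#'
#' Threads sorted by size are cut into `n_bins` contiguous equal-frequency
#' groups (remainder threads go to the smallest-size bins). Each bin
#' contributes at least `floor(test_fraction * bin size)` threads, drawn
#' without replacement; the shortfall against the overall target
#' `floor(test_fraction * n)` is topped up one thread per bin by largest
#' fractional remainder, so every bin's test share stays within one thread
#' of its floor. When even the overall target is zero the split falls back
#' to one test thread per bin with a warning. Train and test partition the
#' input; the draw is deterministic under the config seed.
#'
#' @param corpus A [forum_corpus()].
#' @param config A [mining_config()].
#' @return List with `train` and `test`, both [forum_corpus()] objects.
#' @export
stratified_split <- function(corpus, config = mining_config()) {
  th <- corpus_threads(corpus)
  n <- nrow(th)
  if (n < config$n_bins) {
    stop("fewer threads (", n, ") than bins (", config$n_bins, ")",
         call. = FALSE)
  }
  th <- th[order(th$size, th$thread_id), , drop = FALSE]
  base <- n %/% config$n_bins
  rem <- n %% config$n_bins
  # remainder spread to the smallest-size bins (the first ones after sorting)
  bin_sizes <- rep(base, config$n_bins) + c(rep(1L, rem),
                                            rep(0L, config$n_bins - rem))
  th$bin <- rep(seq_len(config$n_bins), times = bin_sizes)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  targets <- config$test_fraction * bin_sizes
  k_bin <- floor(targets)
  total_target <- floor(config$test_fraction * n)
  if (total_target == 0) {
    warning("test_fraction too small for ", n,
            " threads; taking 1 test thread per bin", call. = FALSE)
    k_bin <- rep(1L, config$n_bins)
  } else {
    shortfall <- total_target - sum(k_bin)
    if (shortfall > 0) {
      topup <- order(targets - k_bin, decreasing = TRUE)[seq_len(shortfall)]
      k_bin[topup] <- k_bin[topup] + 1L
    }
  }
  test_ids <- character()
  for (b in seq_len(config$n_bins)) {
    ids <- th$thread_id[th$bin == b]
    test_ids <- c(test_ids, sample(ids, min(k_bin[b], length(ids))))
  }
  posts <- tibble::as_tibble(corpus)
  list(train = forum_corpus(posts[!(posts$thread_id %in% test_ids), ]),
       test = forum_corpus(posts[posts$thread_id %in% test_ids, ]))
}

#' Assemble preprocessed documents from a corpus
#'
#' With `document_unit = "thread"` each thread is one document: its posts
#' concatenated in position order, then [preprocess()]ed. With `"post"`,
#' one document per post.
#'
#' @param corpus A [forum_corpus()].
#' @param config A [mining_config()].
#' @param stopwords Stopword set passed to [preprocess()].
#' @return Named list of character vectors of stems (names are thread or
#'   post ids).
#' @export
build_documents <- function(corpus, config = mining_config(),
                            stopwords = read_stopwords()) {
  posts <- tibble::as_tibble(corpus)
  if (nrow(posts) == 0) return(list())
  if (config$document_unit == "thread") {
    posts <- posts[order(posts$thread_id, posts$position), ]
    texts <- tapply(posts$text, posts$thread_id,
                    function(x) paste(x, collapse = " "))
    docs <- lapply(as.character(texts), preprocess, stopwords = stopwords)
    names(docs) <- names(texts)
  } else {
    docs <- lapply(posts$text, preprocess, stopwords = stopwords)
    names(docs) <- posts$post_id
  }
  docs
}

#' tf-idf term ranking
#'
#' For term *t* with raw count tf(t,d) in document *d*, df(t) documents
#' containing *t* and *N* documents, the smoothed idf is
#' `ln((1 + N) / (1 + df)) + 1`, the per-document weight is `tf * idf`, and
#' the corpus score is the maximum (or, by config, sum) of the weights over
#' documents. No vector normalization is applied — scores must be able to
#' exceed the 1.0 review threshold, so normalization stays off by design.
#' A term occurring once in every document scores exactly 1.0.
#'
#' @param documents List of stem vectors, as from [build_documents()].
#' @param aggregate `"max"` (default) or `"sum"`.
#' @return A tibble `term`, `score`, sorted score-descending with
#'   alphabetical tie-break.
#' @export
tfidf_rank <- function(documents, aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  documents <- documents[lengths(documents) > 0]
  n_docs <- length(documents)
  if (n_docs == 0) {
    warning("all documents empty; empty ranking", call. = FALSE)
    return(tibble::tibble(term = character(), score = numeric()))
  }
  counts <- lapply(documents, function(d) table(d))
  term <- unlist(lapply(counts, names), use.names = FALSE)
  tf <- unlist(lapply(counts, as.integer), use.names = FALSE)
  df <- table(term)  # each term appears once per containing document
  idf <- log((1 + n_docs) / (1 + as.numeric(df[term]))) + 1
  w <- tf * idf
  score <- if (aggregate == "max") {
    tapply(w, term, max)
  } else {
    tapply(w, term, sum)
  }
  out <- tibble::tibble(term = names(score), score = as.numeric(score))
  out[order(-out$score, out$term), ]
}

#' Curation decisions
#'
#' A decision table has one row per reviewed stemmed term with columns
#' `term`, `action` (`"synonym_of"`, `"new_class"` or `"reject"`), `target`
#' (class CURIE for `synonym_of`; label for `new_class`), `surface_forms`
#' (|-separated unstemmed variants, including corrected misspellings, stored
#' as the synonyms) and `scope`. [read_decisions()] and [write_decisions()]
#' exchange the table as TSV.
#'
#' @param term,action,target,surface_forms,scope Vectors of equal length
#'   (scalars recycle).
#' @return A `curation_decisions` tibble.
#' @export
curation_decisions <- function(term, action, target = NA_character_,
                               surface_forms = NA_character_,
                               scope = "unspecified") {
  ok <- action %in% c("synonym_of", "new_class", "reject")
  if (any(!ok)) stop("unknown action: ", action[!ok][1], call. = FALSE)
  out <- tibble::tibble(term = term, action = action, target = target,
                        surface_forms = surface_forms, scope = scope)
  structure(out, class = c("curation_decisions", class(out)))
}

#' @rdname curation_decisions
#' @param path TSV path.
#' @export
read_decisions <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = "",
                          fileEncoding = "UTF-8")
  if (!"scope" %in% names(df)) df$scope <- "unspecified"
  df$scope[is.na(df$scope)] <- "unspecified"
  curation_decisions(df$term, df$action, df$target, df$surface_forms, df$scope)
}

#' @rdname curation_decisions
#' @param decisions A `curation_decisions` tibble.
#' @export
write_decisions <- function(decisions, path) {
  utils::write.table(tibble::as_tibble(decisions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

decision_surfaces <- function(decisions, i) {
  sf <- decisions$surface_forms[i]
  if (is.na(sf) || !nzchar(sf)) decisions$term[i]
  else strsplit(sf, "|", fixed = TRUE)[[1]]
}

#' Apply curation decisions to the ontology and the training documents
#'
#' Accepted surface forms are stored as synonyms (via [add_synonym()]) on
#' the target class — created first for `new_class` decisions; every
#' occurrence of an accepted stemmed term is then removed from all
#' documents, so the next ranking round reweighs the remaining vocabulary.
#' Rejected terms are returned so callers can keep a persistent reject list
#' and never re-surface them.
#'
#' @param ontology An [ontology()].
#' @param documents List of stem vectors.
#' @param decisions A [curation_decisions()] table.
#' @param source Provenance tag recorded on added synonyms.
#' @return List `ontology`, `documents`, `accepted` (stems removed),
#'   `rejected` (stems to suppress).
#' @export
apply_decisions <- function(ontology, documents, decisions, source = "forum") {
  accepted <- character(); rejected <- character()
  for (i in seq_len(nrow(decisions))) {
    act <- decisions$action[i]
    if (act == "reject") {
      rejected <- c(rejected, decisions$term[i])
      next
    }
    if (act == "new_class") {
      label <- decisions$target[i]
      if (is.na(label) || !nzchar(label)) {
        stop("new_class decision for '", decisions$term[i],
             "' has no label", call. = FALSE)
      }
      ontology <- add_class(ontology, label)
      class_id <- attr(ontology, "new_id")
    } else {
      class_id <- decisions$target[i]
      if (is.na(class_id) || !class_id %in% ontology$classes$id) {
        stop("decision for '", decisions$term[i],
             "' targets unknown class: ", class_id, call. = FALSE)
      }
    }
    for (sf in decision_surfaces(decisions, i)) {
      lab <- ontology$classes$label[ontology$classes$id == class_id]
      if (tolower(sf) != tolower(lab)) {
        ontology <- add_synonym(ontology, class_id, sf, source = source,
                                scope = decisions$scope[i])
      }
    }
    accepted <- c(accepted, decisions$term[i])
  }
  if (length(accepted) > 0) {
    documents <- lapply(documents, function(d) d[!(d %in% accepted)])
  }
  list(ontology = ontology, documents = documents,
       accepted = accepted, rejected = rejected)
}

#' Replay curator
#'
#' Builds a curator function for [mine_synonyms()] from a fixed decision
#' table: terms present in the table get their recorded decision; any other
#' term surfacing above the threshold gets `default_action` (reject, by
#' default — mirroring an expert who dismisses uninformative words).
#'
#' @param decisions A [curation_decisions()] table.
#' @param default_action Action for terms not in the table.
#' @return A function `(terms, ranked) -> curation_decisions`.
#' @export
replay_curator <- function(decisions, default_action = "reject") {
  force(decisions); force(default_action)
  function(terms, ranked) {
    idx <- match(terms, decisions$term)
    out <- curation_decisions(
      term = terms,
      action = ifelse(is.na(idx), default_action, decisions$action[idx]),
      target = ifelse(is.na(idx), NA_character_, decisions$target[idx]),
      surface_forms = ifelse(is.na(idx), NA_character_,
                             decisions$surface_forms[idx]),
      scope = ifelse(is.na(idx), "unspecified", decisions$scope[idx])
    )
    out
  }
}

#' Iterative synonym mining
#'
#' The curate-remove-rerank loop: rank the training documents by tf-idf,
#' send every not-yet-decided term scoring above the threshold to the
#' curator, apply the decisions (synonyms into the ontology, accepted stems
#' removed from the documents, rejects onto a persistent suppress list), and
#' re-rank. Terminates when a round accepts no terms, when nothing is left
#' to review, or at `max_rounds`. If the curator fails mid-round the loop
#' aborts, the audit log up to the last completed round is flushed, and the
#' ontology state from that round is returned.
#'
#' @param corpus Training [forum_corpus()] (already split), or a list of
#'   documents from [build_documents()].
#' @param ontology An [ontology()].
#' @param curator Function `(terms, ranked) -> curation_decisions`, e.g.
#'   [replay_curator()].
#' @param config A [mining_config()].
#' @param stopwords Stopword set for preprocessing.
#' @param rejected Initial persistent reject list (stems never re-surfaced).
#' @param source Provenance tag for added synonyms.
#' @return List `ontology`, `audit` (tibble, one row per round: round,
#'   n_ranked, n_reviewed, n_accepted, n_rejected, vocabulary_size),
#'   `rejected` (the grown reject list), `termination` (reason).
#' @export
mine_synonyms <- function(corpus, ontology, curator,
                          config = mining_config(),
                          stopwords = read_stopwords(),
                          rejected = character(), source = "forum") {
  documents <- if (inherits(corpus, "forum_corpus")) {
    build_documents(corpus, config, stopwords)
  } else {
    corpus
  }
  audit <- list()
  termination <- "max-rounds"
  for (round in seq_len(config$max_rounds)) {
    ranked <- suppressWarnings(tfidf_rank(documents, config$aggregate))
    review <- ranked$term[ranked$score > config$score_threshold]
    review <- setdiff(review, rejected)
    if (length(review) == 0) {
      audit[[round]] <- tibble::tibble(
        round = round, n_ranked = nrow(ranked), n_reviewed = 0L,
        n_accepted = 0L, n_rejected = 0L,
        vocabulary_size = length(unique(unlist(documents))))
      termination <- "no-terms-to-review"
      break
    }
    decisions <- tryCatch(curator(review, ranked), error = function(e) e)
    if (inherits(decisions, "error")) {
      termination <- paste0("curator-error: ", conditionMessage(decisions))
      break
    }
    applied <- apply_decisions(ontology, documents, decisions, source = source)
    ontology <- applied$ontology
    documents <- applied$documents
    rejected <- union(rejected, applied$rejected)
    audit[[round]] <- tibble::tibble(
      round = round, n_ranked = nrow(ranked), n_reviewed = length(review),
      n_accepted = length(applied$accepted),
      n_rejected = length(applied$rejected),
      vocabulary_size = length(unique(unlist(documents))))
    if (length(applied$accepted) == 0) {
      termination <- "no-accepts"
      break
    }
  }
  list(ontology = ontology, audit = dplyr::bind_rows(audit),
       rejected = rejected, termination = termination)
}

#' Compare training and test rankings for missed terms
#'
#' Lists test-set terms above the threshold that were neither accepted nor
#' surfaced above the threshold in training — the candidate misses a manual
#' split-sample validation would flag.
#'
#' @param train_ranked,test_ranked Rankings from [tfidf_rank()] computed
#'   with the same config.
#' @param accepted Character vector of accepted stems.
#' @param score_threshold Review threshold.
#' @return List `candidate_misses` (character), `n_test_above`,
#'   `n_train_above`.
#' @export
validate_split <- function(train_ranked, test_ranked, accepted = character(),
                           score_threshold = 1.0) {
  test_above <- test_ranked$term[test_ranked$score > score_threshold]
  train_above <- train_ranked$term[train_ranked$score > score_threshold]
  misses <- setdiff(setdiff(test_above, accepted), train_above)
  list(candidate_misses = misses,
       n_test_above = length(test_above),
       n_train_above = length(train_above))
}
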