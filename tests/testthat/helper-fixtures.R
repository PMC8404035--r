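# Shared fixture builders and independent oracles. The oracles re-derive
# expected values by brute force and stay independent of the code paths
# they check.

# Deterministic corpus with the given thread sizes (one forum).
make_corpus <- function(sizes, forum = "OV", text = "an eye post") {
  n <- sum(sizes)
  tid <- rep(sprintf("%s-t%04d", forum, seq_along(sizes)), sizes)
  tibble::tibble(
    post_id = sprintf("%s-p%05d", forum, seq_len(n)),
    thread_id = tid,
    forum_id = forum,
    position = as.integer(unlist(lapply(sizes, function(s) seq_len(s) - 1L))),
    text = if (n == 0) character() else text
  ) |> forum_corpus()
}

# Thread sizes with an exact post total: base size for all, +1 for the first
# `total - base * n_threads` threads.
sizes_for_total <- function(n_threads, total) {
  base <- total %/% n_threads
  extra <- total - base * n_threads
  rep(base, n_threads) + c(rep(1L, extra), rep(0L, n_threads - extra))
}

# Brute-force tf-idf: plain loops over the formula, no shared code with
# tfidf_rank().
brute_tfidf <- function(documents, aggregate = "max") {
  documents <- documents[lengths(documents) > 0]
  n <- length(documents)
  vocab <- sort(unique(unlist(documents)))
  scores <- numeric(length(vocab))
  for (i in seq_along(vocab)) {
    t <- vocab[i]
    df <- sum(vapply(documents, function(d) t %in% d, logical(1)))
    idf <- log((1 + n) / (1 + df)) + 1
    w <- vapply(documents, function(d) sum(d == t) * idf, numeric(1))
    scores[i] <- if (aggregate == "max") max(w) else sum(w)
  }
  names(scores) <- vocab
  scores
}

# Brute-force maximal-munch tagger: scan positions left to right; at the
# first position where any boundary-anchored term matches, take the longest.
brute_tag <- function(text, terms, class_ids) {
  lower <- tolower(text)
  n <- nchar(lower)
  is_word <- function(p) p >= 1 && p <= n &&
    grepl("[a-z0-9]", substr(lower, p, p))
  ord <- order(-nchar(terms), terms)
  terms <- terms[ord]; class_ids <- class_ids[ord]
  out <- list()
  pos <- 1
  while (pos <= n) {
    hit <- FALSE
    for (j in seq_along(terms)) {
      len <- nchar(terms[j])
      if (pos + len - 1 > n) next
      if (substr(lower, pos, pos + len - 1) != terms[j]) next
      if (is_word(pos - 1) || is_word(pos + len)) next
      out[[length(out) + 1]] <- tibble::tibble(
        class_id = class_ids[j], start = pos - 1L,
        end = pos - 1L + len)
      pos <- pos + len
      hit <- TRUE
      break
    }
    if (!hit) pos <- pos + 1
  }
  dplyr::bind_rows(out)
}

# Pearson chi-square by the textbook formula (expected counts from margins).
pearson_chi2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  tot <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / tot
  stat <- sum((m - e)^2 / e)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# A small ontology used across tests.
toy_ontology <- function() {
  ontology(
    classes = tibble::tibble(
      id = c("OCIMIDO:00141", "OCIMIDO:00213", "OCIMIDO:00302"),
      label = c("blurred vision", "uveitis", "adalimumab")),
    synonyms = tibble::tibble(
      class_id = c("OCIMIDO:00141", "OCIMIDO:00302"),
      term = c("blurry", "humira"),
      source = c("OV", "OV"),
      scope = c("unspecified", "unspecified")),
    xrefs = tibble::tibble(class_id = "OCIMIDO:00213",
                           xref = "SNOMEDCT:128473001"),
    parents = tibble::tibble(class_id = c("OCIMIDO:00141", "OCIMIDO:00302"),
                             parent = c("OCIMIDO:00213", "OCIMIDO:00213")),
    relationships = tibble::tibble(class_id = "OCIMIDO:00302",
                                   relation = "treatment_of",
                                   target = "OCIMIDO:00213"),
    relation_types = tibble::tibble(id = "treatment_of", label = "treatment of")
  )
}

# Decision table that accepts exactly the planted synonyms of a generator
# config (first synonym of each planted term).
planted_decisions <- function(config) {
  surfaces <- vapply(config$planted_terms$synonyms, `[`, character(1), 1)
  curation_decisions(
    term = vapply(surfaces, function(s) preprocess(s)[1], character(1)),
    action = "synonym_of",
    target = config$planted_terms$class_id,
    surface_forms = surfaces
  )
}
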