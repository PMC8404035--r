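test_that("stratified split partitions threads with per-bin test floors", {
  corpus <- make_corpus(rep(3L, 100))
  cfg <- mining_config(seed = 7)
  sp <- stratified_split(corpus, cfg)
  expect_equal(nrow(corpus_threads(sp$test)), 20)
  expect_equal(nrow(corpus_threads(sp$train)), 80)
  # partition: union is the corpus, intersection empty
  expect_setequal(c(sp$train$post_id, sp$test$post_id), corpus$post_id)
  expect_length(intersect(sp$train$thread_id, sp$test$thread_id), 0)
  # determinism
  sp2 <- stratified_split(corpus, cfg)
  expect_identical(sort(sp$test$thread_id), sort(sp2$test$thread_id))
  # a different seed draws a different test set (almost surely)
  sp3 <- stratified_split(corpus, mining_config(seed = 8))
  expect_false(identical(sort(unique(sp$test$thread_id)),
                         sort(unique(sp3$test$thread_id))))
})

test_that("each bin's test share is within one thread of its floor", {
  set.seed(1)
  corpus <- make_corpus(sample(1:12, 61, replace = TRUE))
  cfg <- mining_config(n_bins = 3, test_fraction = 0.2, seed = 5)
  sp <- stratified_split(corpus, cfg)
  th <- corpus_threads(corpus)
  th <- th[order(th$size, th$thread_id), ]
  bins <- rep(1:3, times = c(21, 20, 20))  # remainder to smallest-size bin
  for (b in 1:3) {
    ids <- th$thread_id[bins == b]
    got <- sum(unique(sp$test$thread_id) %in% ids)
    expect_lte(abs(got - floor(0.2 * length(ids))), 1)
  }
  # and the overall test share hits the global floor
  expect_equal(nrow(corpus_threads(sp$test)), floor(0.2 * 61))
})

test_that("splits too small for the test fraction fall back with a warning", {
  # 10 threads of sizes 1..10: bins {4,3,3}, per-bin floors all zero, but
  # the global 20% target still yields 2 test threads by remainder top-up
  sp <- stratified_split(make_corpus(1:10), mining_config(seed = 2))
  expect_equal(nrow(corpus_threads(sp$test)), 2)
  # when even the global target is zero, fall back to one thread per bin
  expect_warning(
    sp <- stratified_split(make_corpus(rep(2L, 4)),
                           mining_config(test_fraction = 0.1, seed = 2)),
    "1 test thread per bin")
  expect_equal(nrow(corpus_threads(sp$test)), 3)
  expect_error(stratified_split(make_corpus(c(2L, 3L)), mining_config(seed = 1)),
               "fewer threads")
})

test_that("documents concatenate posts per thread before preprocessing", {
  corpus <- forum_corpus(tibble::tibble(
    post_id = c("p1", "p2"), thread_id = "t1", forum_id = "OV",
    position = c(0L, 1L), text = c("eye pain", "pains again")))
  docs <- build_documents(corpus)
  expect_length(docs, 1)
  # oracle: preprocess the two posts independently
  expected <- c(preprocess("eye pain"), preprocess("pains again"))
  expect_equal(sum(docs[[1]] == "pain"), 2)
  expect_equal(docs[[1]], expected)

  expect_equal(build_documents(make_corpus(integer())), list())
  per_post <- build_documents(make_corpus(5L),
                              mining_config(document_unit = "post"))
  expect_length(per_post, 5)
})

test_that("tf-idf follows the smoothed unnormalized formula", {
  # single document ["pain","pain"]: 2 * (ln(2/2) + 1) = 2.0
  r <- tfidf_rank(list(c("pain", "pain")))
  expect_equal(r$score[r$term == "pain"], 2.0)
  # a term once in every one of N documents scores exactly 1.0
  r <- tfidf_rank(list(c("uveitis", "a"), c("uveitis", "b"), c("uveitis", "c")))
  expect_equal(r$score[r$term == "uveitis"], 1.0)
  # equal scores are ordered alphabetically
  r <- tfidf_rank(list(c("zeta", "alpha")))
  expect_equal(r$term, c("alpha", "zeta"))
  expect_equal(r$score[1], r$score[2])
  expect_warning(r <- tfidf_rank(list(character(), character())), "empty")
  expect_equal(nrow(r), 0)
})

test_that("tf-idf agrees with brute-force evaluation on small corpora", {
  set.seed(42)
  vocab <- c("a", "b", "c", "d")
  for (case in 1:60) {
    n_docs <- sample(1:5, 1)
    docs <- lapply(seq_len(n_docs), function(i)
      sample(vocab, sample(1:10, 1), replace = TRUE))
    for (agg in c("max", "sum")) {
      got <- tfidf_rank(docs, agg)
      want <- brute_tfidf(docs, agg)
      expect_equal(stats::setNames(got$score, got$term),
                   want[order(-want, names(want))])
    }
  }
})

test_that("applying decisions updates the ontology and removes accepted stems", {
  onto <- toy_ontology()
  docs <- list(d1 = c("humira", "pain", "humira"), d2 = c("pain", "hospit"))
  dec <- curation_decisions(
    term = c("humira2", "hospit"),
    action = c("synonym_of", "reject"),
    target = c("OCIMIDO:00302", NA),
    surface_forms = c("humira2|humira-two", NA))
  out <- apply_decisions(onto, docs, dec, source = "OV")
  expect_true("humira2" %in% out$ontology$synonyms$term)
  expect_true("humira-two" %in% out$ontology$synonyms$term)
  expect_false("humira2" %in% unlist(out$documents))
  # rejected stems stay in the documents
  expect_true("hospit" %in% unlist(out$documents))
  expect_equal(out$rejected, "hospit")
  # unknown target class fails naming the decision
  bad <- curation_decisions("x", "synonym_of", "OCIMIDO:99999")
  expect_error(apply_decisions(onto, docs, bad), "x.*OCIMIDO:99999")
  # empty decision list is the identity
  out <- apply_decisions(onto, docs, curation_decisions(character(),
                                                        character()))
  expect_equal(out$documents, docs)
  expect_equal(ontology_stats(out$ontology), ontology_stats(onto))
})

test_that("decision tables round-trip through TSV", {
  dec <- curation_decisions(
    term = c("humira", "glaucoma2"),
    action = c("synonym_of", "new_class"),
    target = c("OCIMIDO:00302", "secondary glaucoma"),
    surface_forms = c("humira", NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_decisions(dec, path)
  back <- read_decisions(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(dec))
  expect_error(curation_decisions("x", "accept"), "unknown action")
})

test_that("the mining loop recovers planted synonyms and terminates", {
  cfg_gen <- forum_sim_config(n_threads = c(OV = 320), seed = 19,
                              misspelling_rate = 0)
  g <- generate_forum(cfg_gen)
  expect_gte(nrow(g$corpus), 1500)
  onto <- generate_toy_ontology(cfg_gen$planted_terms)
  dec <- planted_decisions(cfg_gen)
  res <- mine_synonyms(g$corpus, onto, replay_curator(dec),
                       mining_config(seed = 3))
  planted <- vapply(cfg_gen$planted_terms$synonyms, `[`, character(1), 1)
  expect_setequal(res$ontology$synonyms$term, planted)
  expect_lte(max(res$audit$round[res$audit$n_accepted > 0]), 3)
  expect_true(res$termination %in% c("no-accepts", "no-terms-to-review"))
  # accepted stems never resurface: their score is absent after removal
  expect_equal(sum(res$audit$n_accepted), length(planted))
})

test_that("a curator rejecting everything leaves the ontology unchanged", {
  g <- generate_forum(forum_sim_config(n_threads = c(OV = 30), seed = 5))
  onto <- generate_toy_ontology(ontomine:::default_planted_terms())
  res <- mine_synonyms(g$corpus, onto,
                       replay_curator(curation_decisions(character(),
                                                         character())),
                       mining_config(seed = 1))
  expect_equal(res$termination, "no-accepts")
  expect_equal(max(res$audit$round), 1)
  expect_equal(ontology_stats(res$ontology)$n_synonyms, 0L)
  # second round would have had nothing to review: rejects persist
  expect_gt(length(res$rejected), 0)
})

test_that("a threshold above the maximum score reviews nothing", {
  g <- generate_forum(forum_sim_config(n_threads = c(OV = 20), seed = 5))
  onto <- generate_toy_ontology(ontomine:::default_planted_terms())
  res <- mine_synonyms(g$corpus, onto,
                       replay_curator(curation_decisions(character(),
                                                         character())),
                       mining_config(score_threshold = 1e6, seed = 1))
  expect_equal(res$termination, "no-terms-to-review")
  expect_equal(res$audit$n_reviewed, 0L)
})

test_that("curator failure aborts with the last completed round's state", {
  g <- generate_forum(forum_sim_config(n_threads = c(OV = 30), seed = 6))
  onto <- generate_toy_ontology(ontomine:::default_planted_terms())
  boom <- function(terms, ranked) stop("curator unavailable")
  res <- mine_synonyms(g$corpus, onto, boom, mining_config(seed = 1))
  expect_match(res$termination, "curator-error")
  expect_equal(nrow(res$audit), 0)
  expect_equal(ontology_stats(res$ontology)$n_synonyms, 0L)
})

test_that("mining terminates within max_rounds for any curator", {
  g <- generate_forum(forum_sim_config(n_threads = c(OV = 40), seed = 9,
                                       mention_rate = 0.2))
  onto <- generate_toy_ontology(ontomine:::default_planted_terms())
  # pathological curator: accepts one arbitrary term per round
  greedy <- function(terms, ranked) {
    curation_decisions(terms,
                       action = c("synonym_of", rep("reject",
                                                    length(terms) - 1)),
                       target = c("OCIMIDO:00213", rep(NA, length(terms) - 1)))
  }
  res <- mine_synonyms(g$corpus, onto, greedy, mining_config(max_rounds = 4,
                                                             seed = 1))
  expect_lte(max(res$audit$round), 4)
})

test_that("split validation reports test-only candidate misses", {
  docs_train <- list(a = c("pain", "pain", "steroid", "steroid"))
  docs_test <- list(b = c("pain", "pain", "xibrom", "xibrom"))
  train_r <- tfidf_rank(docs_train)
  test_r <- tfidf_rank(docs_test)
  # identical corpora: no misses
  v <- validate_split(train_r, train_r, accepted = character())
  expect_length(v$candidate_misses, 0)
  # a novel planted term in test only is exactly what gets reported
  v <- validate_split(train_r, test_r, accepted = c("pain"))
  expect_equal(v$candidate_misses, "xibrom")
  # empty accepted set: every above-threshold test term is reported
  v <- validate_split(tfidf_rank(list(z = "zzz")), test_r)
  expect_setequal(v$candidate_misses, c("pain", "xibrom"))
})
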