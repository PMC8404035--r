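---
title: "Mining patient-preferred synonyms into a clinical ontology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining patient-preferred synonyms into a clinical ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients writing on online support forums use lay terms — "humira", "mtx",
"blurry" — where a clinical ontology knows "adalimumab", "methotrexate",
"blurred vision". Dictionary-based annotation of patient text against such
an ontology therefore misses a large share of mentions unless the ontology
also carries the patient-preferred surface forms as synonyms. `ontomine`
implements a curation-efficient way to find those synonyms in forum text,
attach them to ontology classes with provenance, and run the downstream
analyses the enriched ontology makes possible: per-forum class frequency
tables, chi-square comparisons of two forums, quantification of the
post-count gain attributable to synonyms, and logistic models of negative
sentiment.

```{r setup}
library(ontomine)
```

## The mining procedure

The unit of observation is the *thread* (an opening post and its replies).
The procedure:

1. **Stratified split.** Threads are sorted by size (posts per thread) and
   cut into `n_bins = 3` contiguous equal-frequency bins; each bin
   contributes its share of a random `test_fraction = 0.2` of threads to a
   held-out test set. Each bin contributes at least
   `floor(test_fraction * bin size)` threads; the shortfall against the
   global target `floor(test_fraction * n)` is topped up by largest
   fractional remainder, so every bin stays within one thread of its floor.
   Splits are deterministic under the config seed.
2. **Preprocessing.** Each training thread becomes one document: posts are
   concatenated in position order, lowercased, tokenized on any character
   outside `[a-z0-9]`, stopwords removed, and every remaining token reduced
   with the Porter stemming algorithm ("pained", "painful", "pains" all
   become "pain"). Numerals are kept — grading terms like "grade 1" are
   clinically meaningful.
3. **tf-idf ranking.** For term $t$ in document $d$, with $N$ documents and
   $\mathrm{df}(t)$ documents containing $t$:
   $$w(t,d) = \mathrm{tf}(t,d)\,\Big(\ln\frac{1+N}{1+\mathrm{df}(t)} + 1\Big),
     \qquad \mathrm{score}(t) = \max_d w(t,d).$$
   No vector normalization is applied. This matters: the review threshold is
   an *absolute* score of 1.0, and a length-normalized score could never
   exceed it. A term occurring once in every document scores exactly 1.0,
   which makes the threshold interpretable — reviewed terms are exactly
   those more informative than a uniformly distributed one.
4. **Curation.** Every term scoring above the threshold goes to a curator —
   interactively, or replayed from a decision file. A decision either
   attaches surface forms (including corrected misspellings) to an existing
   class as synonyms, creates a new class, or rejects the term.
5. **Remove and re-rank.** Accepted stems are removed from the documents and
   the ranking is recomputed, reweighing what remains; rejected stems go
   onto a persistent reject list and are never re-surfaced. The loop stops
   when a round accepts nothing, when nothing is left to review, or at
   `max_rounds`.

Worked example on a synthetic forum (Recovering planted synonyms):

```{r mining}
cfg <- forum_sim_config(n_threads = c(OV = 320), seed = 2024,
                        mention_rate = 0.05, misspelling_rate = 0)
gen <- generate_forum(cfg)
onto <- generate_toy_ontology(cfg$planted_terms)

surfaces <- vapply(cfg$planted_terms$synonyms, `[`, character(1), 1)
decisions <- curation_decisions(
  term = vapply(surfaces, function(s) preprocess(s)[1], character(1)),
  action = "synonym_of",
  target = cfg$planted_terms$class_id,
  surface_forms = surfaces)

res <- mine_synonyms(gen$corpus, onto, replay_curator(decisions),
                     mining_config(seed = 1))
res$audit
res$ontology$synonyms
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_bins` | 3 | equal-frequency thread-size strata for the split |
| `test_fraction` | 0.2 | held-out share of threads, drawn per bin |
| `score_threshold` | 1.0 | absolute tf-idf review threshold |
| `max_rounds` | 10 | hard cap on curate-remove-rerank rounds |
| `document_unit` | thread | `"post"` ranks per post instead |
| `aggregate` | max | corpus score across documents; `"sum"` available |
| `retain_fraction` | 0.25 | per-tail share kept in quartile retention |
| `screen_alpha` | 0.1 | univariable LRT screen for model candidates |
| `ci_level` | 0.95 | Wald CI level on odds ratios |

Three tf-idf choices are deliberately config-exposed because the procedure
is often described without fixing them: the document unit (thread vs post),
the cross-document aggregation (max vs sum), and normalization (fixed off,
as explained above). The defaults treat each thread as one document and use
the max, which preserves "scores above 1.0" as a meaningful review rule and
is robust to corpus size.

## Dictionary tagging

`tag_post()` matches raw lowercased text — not stemmed text, so character
offsets stay meaningful — against a term index built from labels and
synonyms. Matching is word-boundary-anchored (a boundary is a transition to
a non-alphanumeric or a string end, so "mtx," matches "mtx"), tried
longest-first, and taken greedily left to right without overlaps: "anterior
uveitis" tags the anterior-uveitis class, not "uveitis". A term claimed by
two classes is ambiguous and excluded from the index with a report. Each
class counts at most once per post, so frequency tables are presence-based.
No negation or temporality handling is attempted — "no prior methotrexate
use" counts as a methotrexate mention, a known limitation of
mention-counting analyses.

The value of enrichment is quantified by `synonym_impact()`: the integer
percent increase in posts reaching a class when synonyms enter the index.
Because a with-synonyms index is a superset of a labels-only index, the
count can only grow; a labels-only count of zero makes the increase
undefined and is reported as `Inf`.

## Sentiment model

`sentiment_score()` is a lexicon-mean scorer: tokens (no stemming, no
stopword removal) are matched against a polarity lexicon in $[-1, 1]$ and
the post score is the mean matched polarity, 0 when nothing matches.
External scorers can be substituted wherever a score column is consumed,
under the same range contract — lexicon scorers are known to disagree with
one another, which is why the scorer is an exchangeable input rather than a
fixed dependency.

Within each forum independently, the middle 50% of scores is discarded and
the most negative 25% (labelled 1) and most positive 25% (labelled 0) are
retained, with ties broken by a stable sort on post id. Candidate
covariates (class-mention indicators) are screened univariably at
`screen_alpha = 0.1` by likelihood-ratio test; the multivariable logistic
model is then reduced by stepwise backward elimination on AIC (BIC by
config), with both criteria recorded at every step. The first-post
indicator is a mandatory covariate, exempt from elimination. Fits use
`glm` (IRLS, tolerance 1e-8, max 100 iterations); a coefficient beyond
±15 is treated as separation and is an error rather than a number. The
model report carries odds ratios with Wald CIs, log-likelihood, AIC
($2k - 2\ell$), BIC ($k\ln n - 2\ell$), the LRT p-value against the
intercept-only model, and AUC as Mann–Whitney concordance.

```{r sentiment}
scores <- score_corpus(gen$corpus)
retained <- quartile_retain(scores)
fit <- fit_logistic(data.frame(first_post = as.integer(retained$first_post)),
                    retained$negative)
fit
```

## What the synthetic generator emulates — and what it does not

The generator exists so every stage is testable without access to any real
forum. It emulates, per forum:

- **Thread sizes** from a zero-truncated negative binomial whose
  *truncated* mean and sd hit the configured targets (defaults 5.2 and 3.9
  posts per thread, the scale of real support-forum threads); the
  untruncated parameters are solved numerically from the truncated moment
  equations, and unreachable targets (e.g. sub-Poisson dispersion) are a
  config error.
- **Planted clinical terms**: each post mentions each planted term with a
  per-forum probability (default 0.05); the mention surface is drawn from
  the term's lay synonyms and optionally corrupted by a single-character
  edit after the first character (the "mxt" for "mtx" pattern). Every
  planted mention is recorded in a ground-truth table.
- **A sentiment effect**: each post draws its emotional words from either a
  negative or a positive pool (disjoint halves of the shipped lexicon).
  Replies are negative with probability 0.35; first posts with the odds
  multiplied by `first_post_negativity_or` (default 3.3, a magnitude
  reported for real fora).

Post text is a shuffled bag of phrases — filler words, pool words, planted
mentions — because every consumer downstream is bag-of-words; word order,
grammar, spelling variation beyond the single-edit model, and user identity
across posts are *not* modelled. Passing tests therefore demonstrate that
the pipeline recovers structure it is pointed at, not that it handles the
full messiness of real forum language.

One property of the design is worth making explicit, because the
sentiment-recovery tests depend on it. With disjoint pools and every post
carrying at least one pool word, all negative-pool posts score below all
positive-pool posts, so the retained bottom quartile is a subset of the
negative-pool posts and the top quartile of the positive-pool posts. The
retained-set odds of a bottom-quartile label given first-post status are
then the planted odds times a factor (the ratio of pool retention rates)
that is *identical* for first posts and replies — so it cancels from the
odds ratio, and the fitted first-post OR consistently estimates the planted
one, provided each pool exceeds the 25% retention share overall (true for
any base rate between roughly 0.25 and 0.75, as with the defaults).

## Numerical and design choices

- **Chi-square without continuity correction.** Forum-comparison 2x2 tables
  use the plain Pearson statistic; with Yates' correction the smaller
  printed p-values of published forum comparisons cannot be reproduced
  (e.g. a table with an expected cell near 4.8 gives p = 0.046 only
  uncorrected). Empty margins are an error, not a 0/0.
- **Stemmer.** Porter (1980), implemented in the package; tokens containing
  non-letters are passed through unchanged. The stemmer is not a projection
  ("nurse" to "nurs" to "nur"); the test suite pins the known exceptions
  explicitly rather than asserting blanket idempotence.
- **Misspelling handling.** Consolidating misspellings onto the correct
  surface form is the curator's job (the `surface_forms` field of a
  decision); the engine performs no automatic spell-correction.
- **Tie-breaks.** Equal tf-idf scores order alphabetically; equal sentiment
  scores at a quartile boundary resolve by post id under a stable sort —
  retained counts are then reproducible even when many posts share a score.
- **Reject persistence.** Rejected stems are never re-surfaced across
  rounds (and can be carried across runs via the returned reject list), so
  the loop's review burden shrinks monotonically and termination within
  `max_rounds` is guaranteed.
- **Axioms without reasoning.** Equivalence/disjointness pairs are stored
  as annotations and checked structurally (no pair may be both); no
  description-logic reasoning is performed. Parent graphs are checked for
  cycles on every read and write; dangling targets are reported, not fatal.
- **Synonym scopes.** Synonyms default to scope `"unspecified"`
  (exact/narrow/broad/related are accepted and preserved); an unspecified
  scope is written to OBO without a scope keyword, which round-trips here
  but should be classified before export to strict OBO consumers.

## Problem sizes used by the test suite

The packaged checks run on synthetic fora of 300–420 threads (roughly
1,500–2,200 posts), which is the scale of a real single-forum corpus and
large enough that the recovery properties are stable: planted synonyms at a
5% mention rate clear the review threshold in the first round, and 50
seeded replicates of the sentiment model cover the planted odds ratio with
their 95% CIs at close to the nominal rate. The exhaustive cross-checks
(tf-idf against brute force, tagger against a maximal-munch oracle) run on
small corpora where enumeration is feasible.

## Known limitations

- Posts by the same user are not independent observations; neither the
  model nor the generator represents user identity.
- Post-level sentiment conflates multiple topics mentioned in one post.
- Dictionary tagging has no context disambiguation (negation, temporality,
  bearer).
- The shipped sentiment lexicon and stopword list are compact defaults
  meant to be replaced per deployment; both are plain-text files.
- Embedding-based synonym discovery is out of scope by design; the ranking
  is purely frequency-based.
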