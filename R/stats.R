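#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction), df = 1, upper-tail p —
#' the convention that reproduces published forum-comparison p-values from
#' printed counts. For a forum comparison, `a`/`b` are mention/non-mention
#' counts in one forum and `c`/`d` in the other.
#'
#' @param a,b,c,d Non-negative integer cells.
#' @return List `statistic`, `p`, `df` (= 1), `expected` (2x2 matrix).
#' @examples
#' chi2_2x2(333, 2176 - 333, 937, 6855 - 937) # p ~= 0.056
#' @export
chi2_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (sum(m) == 0) stop("table total must be positive", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square undefined: empty row or column margin", call. = FALSE)
  }
  ht <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value, df = 1L,
       expected = ht$expected)
}

#' Sentiment lexicons and scoring
#'
#' A sentiment lexicon maps lowercase tokens to polarities in `[-1, 1]`
#' (TSV: `token<TAB>polarity`); the package ships a compact general-purpose
#' default. [sentiment_score()] is the built-in lexicon-mean scorer: text is
#' tokenized as in [tokenize()] (no stemming, no stopword removal) and the
#' score is the arithmetic mean of the polarities of matched tokens — 0 when
#' nothing matches. External scorers can be swapped in anywhere a score
#' column is consumed, provided they honour the same `[-1, 1]` range.
#'
#' @param path Lexicon TSV path; `NULL` loads the shipped default.
#' @return `read_sentiment_lexicon`: tibble `token`, `polarity`.
#' @export
read_sentiment_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sentiment_lexicon.tsv",
                        package = "ontomine")
  }
  lex <- utils::read.delim(path, colClasses = c("character", "numeric"),
                           fileEncoding = "UTF-8")
  names(lex) <- c("token", "polarity")
  if (any(lex$polarity < -1 | lex$polarity > 1)) {
    stop("lexicon polarities must lie in [-1, 1]", call. = FALSE)
  }
  lex$token <- tolower(lex$token)
  tibble::as_tibble(lex)
}

#' @rdname read_sentiment_lexicon
#' @param text Raw post text (character scalar).
#' @param lexicon Lexicon tibble.
#' @return `sentiment_score`: list `score` (in `[-1, 1]`), `n_matched`.
#' @export
sentiment_score <- function(text, lexicon = read_sentiment_lexicon()) {
  toks <- tokenize(text)
  pol <- lexicon$polarity[match(toks, lexicon$token)]
  pol <- pol[!is.na(pol)]
  if (length(pol) == 0) return(list(score = 0, n_matched = 0L))
  list(score = mean(pol), n_matched = length(pol))
}

#' Score every post of a corpus
#'
#' @param corpus A [forum_corpus()].
#' @param lexicon Lexicon tibble.
#' @return Tibble `post_id`, `forum_id`, `first_post`, `score`, `n_matched`.
#' @export
score_corpus <- function(corpus, lexicon = read_sentiment_lexicon()) {
  posts <- tibble::as_tibble(corpus)
  res <- lapply(posts$text, sentiment_score, lexicon = lexicon)
  tibble::tibble(
    post_id = posts$post_id,
    forum_id = posts$forum_id,
    first_post = posts$position == 0L,
    score = vapply(res, `[[`, numeric(1), "score"),
    n_matched = vapply(res, `[[`, integer(1), "n_matched")
  )
}

#' Per-forum quartile retention
#'
#' Within each forum independently, posts are sorted by sentiment score
#' (ties broken by a stable sort on `post_id`) and the middle is discarded:
#' the lowest `floor(retain_fraction * n)` are retained with `negative = 1`,
#' the highest `floor(retain_fraction * n)` with `negative = 0`. Forums with
#' fewer than 4 scores are skipped with a warning.
#'
#' @param scores Tibble from [score_corpus()] (needs `post_id`, `forum_id`,
#'   `score`).
#' @param retain_fraction Fraction retained in each tail (default 0.25).
#' @return The retained subset with a `negative` 0/1 column.
#' @export
quartile_retain <- function(scores, retain_fraction = 0.25) {
  stopifnot(retain_fraction > 0, retain_fraction <= 0.5)
  out <- list()
  for (forum in unique(scores$forum_id)) {
    s <- scores[scores$forum_id == forum, , drop = FALSE]
    n <- nrow(s)
    if (n < 4) {
      warning("forum ", forum, " has fewer than 4 scores; skipped",
              call. = FALSE)
      next
    }
    k <- floor(retain_fraction * n)
    s <- s[order(s$score, s$post_id), , drop = FALSE]
    lo <- s[seq_len(k), , drop = FALSE]
    hi <- s[seq(n - k + 1, n), , drop = FALSE]
    lo$negative <- 1L
    hi$negative <- 0L
    out[[forum]] <- dplyr::bind_rows(lo, hi)
  }
  dplyr::bind_rows(out)
}

#' Mann-Whitney concordance (AUC)
#'
#' Probability that a randomly chosen positive outcome receives a higher
#' fitted value than a randomly chosen negative one, with ties counting a
#' half — the area under the ROC curve.
#'
#' @param fitted Numeric fitted probabilities (or any monotone score).
#' @param y 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @export
auc_concordance <- function(fitted, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(fitted)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Logistic regression with the model summary the analysis reports
#'
#' Maximum likelihood via iteratively reweighted least squares (epsilon
#' 1e-8, at most 100 iterations). Reports per-covariate coefficients, odds
#' ratios with Wald confidence intervals and p-values, and model-level
#' log-likelihood, AIC (`2k - 2*loglik`), BIC (`k*ln(n) - 2*loglik`), the
#' likelihood-ratio-test p-value against the intercept-only model, the AUC
#' of the fitted probabilities and `n`. A coefficient diverging beyond 15
#' in magnitude signals (quasi-)complete separation and is an error, as is
#' a rank-deficient design.
#'
#' @param design Data frame of numeric (typically 0/1) covariates.
#' @param y 0/1 outcome vector (1 = negative-sentiment post).
#' @param ci_level Confidence level for the Wald intervals.
#' @return A `logistic_fit` list: `coefficients` tibble (`covariate`,
#'   `estimate`, `se`, `or`, `ci_low`, `ci_high`, `p`), `loglik`, `aic`,
#'   `bic`, `lrt_p`, `auc`, `n`, `n_covariates`, and the underlying `glm`.
#' @export
fit_logistic <- function(design, y, ci_level = 0.95) {
  design <- as.data.frame(design)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(design) == length(y) || ncol(design) == 0)
  n <- length(y)
  k_cov <- ncol(design)
  if (k_cov > 0) {
    if (n <= k_cov + 1) stop("more parameters than observations", call. = FALSE)
    constant <- vapply(design, function(x) length(unique(x)) == 1, logical(1))
    if (any(constant)) {
      stop("constant covariate(s): ",
           paste(names(design)[constant], collapse = ", "), call. = FALSE)
    }
    mm <- cbind(`(Intercept)` = 1, as.matrix(design))
    if (qr(mm)$rank < ncol(mm)) {
      stop("singular design matrix (collinear covariates)", call. = FALSE)
    }
    dat <- cbind(.y = y, design)
    fit <- suppressWarnings(stats::glm(
      .y ~ ., family = stats::binomial(), data = dat,
      control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  } else {
    dat <- data.frame(.y = y)
    fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = dat,
                      control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  }
  co <- stats::coef(fit)
  slope <- co[names(co) != "(Intercept)"]
  if (any(abs(slope) > 15)) {
    stop("perfect separation suspected for covariate(s): ",
         paste(names(slope)[abs(slope) > 15], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  coefs <- tibble::tibble(
    covariate = rownames(sm),
    estimate = unname(est),
    se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est - z * se)),
    ci_high = exp(unname(est + z * se)),
    p = unname(sm[, "Pr(>|z|)"])
  )
  ll <- as.numeric(stats::logLik(fit))
  k <- length(co)
  null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  ll0 <- as.numeric(stats::logLik(null_fit))
  lrt_p <- if (k_cov == 0) 1 else
    stats::pchisq(2 * (ll - ll0), df = k_cov, lower.tail = FALSE)
  structure(list(
    coefficients = coefs,
    loglik = ll,
    aic = 2 * k - 2 * ll,
    bic = k * log(n) - 2 * ll,
    lrt_p = lrt_p,
    auc = if (k_cov == 0) 0.5 else auc_concordance(stats::fitted(fit), y),
    n = n, n_covariates = k_cov,
    glm = fit
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic model: n = %d, loglik = %.2f, AIC = %.1f, BIC = %.1f\n",
              x$n, x$loglik, x$aic, x$bic))
  cat(sprintf("LRT vs intercept-only: p = %.4g; AUC = %.3f\n", x$lrt_p, x$auc))
  print(x$coefficients)
  invisible(x)
}

#' Univariable screening
#'
#' Fits each candidate covariate alone and retains those whose global
#' (likelihood-ratio) p-value is below `screen_alpha`. Candidates whose fit
#' fails are dropped with a warning.
#'
#' @param candidates Data frame of candidate covariates.
#' @param y 0/1 outcome.
#' @param screen_alpha Retention threshold (default 0.1).
#' @return Character vector of retained covariate names.
#' @export
screen_univariable <- function(candidates, y, screen_alpha = 0.1) {
  candidates <- as.data.frame(candidates)
  keep <- character()
  for (nm in names(candidates)) {
    fit <- tryCatch(fit_logistic(candidates[, nm, drop = FALSE], y),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("screening dropped '", nm, "': ", conditionMessage(fit),
              call. = FALSE)
      next
    }
    if (fit$lrt_p < screen_alpha) keep <- c(keep, nm)
  }
  keep
}

#' Stepwise backward elimination by information criterion
#'
#' From the full model, repeatedly removes the single covariate whose
#' removal most improves the criterion (AIC by default; BIC by config), and
#' stops when no removal improves it. Both criteria are recorded at every
#' step in the elimination trace. Covariates in `protected` (e.g. the
#' mandatory first-post indicator) are never considered for removal.
#'
#' @param design Data frame of covariates (the full model).
#' @param y 0/1 outcome.
#' @param criterion `"aic"` or `"bic"`.
#' @param protected Covariate names exempt from elimination.
#' @param ci_level Confidence level passed to [fit_logistic()].
#' @return List `fit` (final [fit_logistic()] result), `trace` (tibble:
#'   step, removed, aic, bic, n_covariates), `covariates` (kept names).
#' @export
backward_eliminate <- function(design, y, criterion = c("aic", "bic"),
                               protected = character(), ci_level = 0.95) {
  criterion <- match.arg(criterion)
  design <- as.data.frame(design)
  current <- names(design)
  fit <- fit_logistic(design[, current, drop = FALSE], y, ci_level)
  crit <- function(f) if (criterion == "aic") f$aic else f$bic
  trace <- list(tibble::tibble(step = 0L, removed = NA_character_,
                               aic = fit$aic, bic = fit$bic,
                               n_covariates = length(current)))
  step <- 0L
  repeat {
    removable <- setdiff(current, protected)
    if (length(removable) == 0) break
    fits <- lapply(removable, function(nm) {
      kept <- setdiff(current, nm)
      tryCatch(fit_logistic(design[, kept, drop = FALSE], y, ci_level),
               error = function(e) e)
    })
    ok <- !vapply(fits, inherits, logical(1), "error")
    if (!any(ok)) break
    vals <- vapply(fits[ok], crit, numeric(1))
    best <- which.min(vals)
    if (vals[best] >= crit(fit)) break
    step <- step + 1L
    removed <- removable[ok][best]
    current <- setdiff(current, removed)
    fit <- fits[ok][[best]]
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = step, removed = removed, aic = fit$aic, bic = fit$bic,
      n_covariates = length(current))
    if (length(current) == 0) break
  }
  list(fit = fit, trace = dplyr::bind_rows(trace), covariates = current)
}

#' End-to-end sentiment association analysis
#'
#' The full downstream pipeline on a tagged corpus: score every post with
#' the lexicon, retain the per-forum sentiment quartiles, build a 0/1 design
#' of class-mention indicators plus the mandatory first-post indicator,
#' screen candidates univariably at `screen_alpha`, and backward-eliminate
#' the multivariable model (first-post protected).
#'
#' @param corpus A [forum_corpus()].
#' @param tags Tag table from [tag_corpus()] (its classes become candidate
#'   covariates); may be `NULL` for a first-post-only model.
#' @param lexicon Sentiment lexicon.
#' @param retain_fraction,screen_alpha,criterion,ci_level Analysis
#'   parameters (defaults 0.25, 0.1, `"aic"`, 0.95).
#' @return List `fit`, `trace`, `covariates`, `retained` (scored subset),
#'   `screened` (candidates passing the screen).
#' @export
analyse_sentiment <- function(corpus, tags = NULL,
                              lexicon = read_sentiment_lexicon(),
                              retain_fraction = 0.25, screen_alpha = 0.1,
                              criterion = "aic", ci_level = 0.95) {
  scores <- score_corpus(corpus, lexicon)
  retained <- quartile_retain(scores, retain_fraction)
  design <- data.frame(first_post = as.integer(retained$first_post))
  if (!is.null(tags) && nrow(tags) > 0) {
    for (cls in unique(tags$class_id)) {
      mentioned <- unique(tags$post_id[tags$class_id == cls])
      col <- make.names(cls)
      design[[col]] <- as.integer(retained$post_id %in% mentioned)
    }
  }
  y <- retained$negative
  candidates <- setdiff(names(design), "first_post")
  screened <- if (length(candidates) > 0) {
    usable <- candidates[vapply(candidates, function(nm)
      length(unique(design[[nm]])) > 1, logical(1))]
    screen_univariable(design[, usable, drop = FALSE], y, screen_alpha)
  } else {
    character()
  }
  final_design <- design[, c("first_post", screened), drop = FALSE]
  res <- backward_eliminate(final_design, y, criterion = criterion,
                            protected = "first_post", ci_level = ci_level)
  c(res, list(retained = retained, screened = screened))
}
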