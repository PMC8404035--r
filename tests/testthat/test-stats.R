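test_that("uncorrected chi-square matches the Pearson formula", {
  r <- chi2_2x2(333, 2176 - 333, 937, 6855 - 937)
  o <- pearson_chi2(333, 2176 - 333, 937, 6855 - 937)
  expect_equal(r$statistic, o$statistic)
  expect_equal(r$p, o$p)
  expect_equal(round(r$statistic, 2), 3.65)

  # proportional table: statistic 0, p 1
  r <- chi2_2x2(10, 90, 20, 180)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  expect_error(chi2_2x2(0, 0, 5, 5), "margin")
  expect_error(chi2_2x2(0, 5, 0, 5), "margin")
})

test_that("chi-square is invariant under simultaneous row and column swap", {
  set.seed(21)
  for (i in 1:1000) {
    x <- rpois(4, lambda = sample(3:40, 1)) + 1
    r <- chi2_2x2(x[1], x[2], x[3], x[4])
    o <- pearson_chi2(x[1], x[2], x[3], x[4])
    expect_equal(r$statistic, o$statistic)
    sw <- chi2_2x2(x[4], x[3], x[2], x[1])
    expect_equal(sw$statistic, r$statistic)
    expect_equal(sw$p, r$p)
  }
})

test_that("the lexicon-mean scorer averages matched polarities", {
  lex <- tibble::tibble(token = c("good", "bad"), polarity = c(0.7, -0.5))
  expect_equal(sentiment_score("nothing matches here", lex),
               list(score = 0, n_matched = 0L))
  expect_equal(sentiment_score("good", lex)$score, 0.7)
  # symmetric polarities cancel
  lex2 <- tibble::tibble(token = c("up", "down"), polarity = c(0.5, -0.5))
  expect_equal(sentiment_score("up and down", lex2)$score, 0)
  # tokenization without stemming or stopword removal: "the" never matches,
  # punctuation-adjacent tokens do
  expect_equal(sentiment_score("the bad, day", lex)$n_matched, 1L)
  # scores stay in [-1, 1] for any text
  g <- generate_forum(forum_sim_config(n_threads = c(OV = 25), seed = 3))
  s <- score_corpus(g$corpus)
  expect_true(all(s$score >= -1 & s$score <= 1))
})

test_that("quartile retention keeps the floored tails per forum", {
  scores <- tibble::tibble(post_id = sprintf("p%02d", 1:8), forum_id = "OV",
                           score = c(-0.9, -0.5, -0.1, 0, 0.1, 0.2, 0.6, 0.8))
  ret <- quartile_retain(scores)
  expect_equal(sum(ret$negative == 1), 2)
  expect_equal(sum(ret$negative == 0), 2)
  expect_setequal(ret$post_id[ret$negative == 1], c("p01", "p02"))
  expect_setequal(ret$post_id[ret$negative == 0], c("p07", "p08"))

  # all-tied scores: sizes still floor(n/4), resolved by post_id order
  tied <- tibble::tibble(post_id = sprintf("p%02d", 1:8), forum_id = "OV",
                         score = 0.5)
  ret <- quartile_retain(tied)
  expect_equal(sum(ret$negative == 1), 2)
  expect_equal(ret$post_id[ret$negative == 1], c("p01", "p02"))
  expect_equal(ret$post_id[ret$negative == 0], c("p07", "p08"))

  # forums retained independently
  two <- tibble::tibble(post_id = sprintf("p%03d", 1:200),
                        forum_id = rep(c("OV", "UVE"), each = 100),
                        score = stats::runif(200))
  ret <- quartile_retain(two)
  expect_equal(nrow(ret), 100)
  expect_equal(unname(table(ret$forum_id)["OV"]), 50L)

  small <- tibble::tibble(post_id = "p1", forum_id = "tiny", score = 0)
  expect_warning(ret <- quartile_retain(small), "fewer than 4")
  expect_equal(nrow(ret), 0)
})

test_that("a single binary covariate reproduces the closed-form odds ratio", {
  # cells: (y=1,x=1)=20, (y=0,x=1)=10, (y=1,x=0)=10, (y=0,x=0)=20
  x <- c(rep(1, 30), rep(0, 30))
  y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  fit <- fit_logistic(data.frame(x = x), y)
  or <- fit$coefficients$or[fit$coefficients$covariate == "x"]
  expect_equal(or, (20 * 20) / (10 * 10), tolerance = 1e-6)  # ad/bc = 4
  expect_true(fit$coefficients$ci_low[2] <= or &&
                or <= fit$coefficients$ci_high[2])
  # information criteria follow their definitions
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  expect_equal(fit$bic, 2 * log(60) - 2 * fit$loglik)
})

test_that("degenerate designs are rejected with named errors", {
  y <- rep(c(0L, 1L), 20)
  expect_error(fit_logistic(data.frame(x = y), y), "separation")
  expect_error(fit_logistic(data.frame(x = rep(1, 40)), y), "constant")
  x <- rep(c(0, 1), 20)
  expect_error(fit_logistic(data.frame(a = x, b = x), y), "singular")
})

test_that("the intercept-only model is the chance baseline", {
  y <- rep(c(0L, 1L), 25)
  fit <- fit_logistic(data.frame()[seq_along(y), , drop = FALSE], y)
  expect_equal(fit$auc, 0.5)
  expect_equal(fit$lrt_p, 1)
  expect_equal(fit$n_covariates, 0L)
})

test_that("AUC concordance matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- rbinom(200, 1, 0.4)
  sc <- stats::rnorm(200) + y
  got <- auc_concordance(sc, y)
  want <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE)))
  expect_equal(got, want)
})

test_that("univariable screening has the LRT's type-I and power behaviour", {
  set.seed(55)
  n <- 2000
  null_kept <- 0L; signal_kept <- 0L
  reps <- 100
  for (i in seq_len(reps)) {
    x_null <- rbinom(n, 1, 0.3)
    x_sig <- rbinom(n, 1, 0.3)
    eta <- -0.5 + log(3.3) * x_sig
    y <- rbinom(n, 1, stats::plogis(eta))
    kept <- screen_univariable(data.frame(noise = x_null, signal = x_sig), y,
                               screen_alpha = 0.1)
    null_kept <- null_kept + ("noise" %in% kept)
    signal_kept <- signal_kept + ("signal" %in% kept)
  }
  expect_gte(reps - null_kept, 0.85 * reps)   # independent covariate excluded
  expect_gte(signal_kept, 0.99 * reps)        # OR 3.3 at n=2000 retained
  expect_equal(screen_univariable(data.frame()[1:10, , drop = FALSE],
                                  rep(0:1, 5)), character())
})

test_that("backward elimination drops noise and keeps structure", {
  # AIC keeps a pure-noise covariate only when its likelihood-ratio
  # chi-square exceeds 2, which happens with probability ~0.157, so the
  # per-replicate elimination rate is ~0.84; the bound below sits 3
  # binomial standard errors under that. Whenever the covariate is kept,
  # the stopping rule must be the reason: removing it would raise the AIC.
  set.seed(66)
  eliminated <- 0L
  reps <- 50
  for (i in seq_len(reps)) {
    n <- 2000
    x1 <- rbinom(n, 1, 0.4)
    noise <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, stats::plogis(-0.3 + 1.0 * x1))
    res <- backward_eliminate(data.frame(x1 = x1, noise = noise), y)
    if (!("noise" %in% res$covariates)) {
      eliminated <- eliminated + 1L
    } else {
      without <- fit_logistic(data.frame(x1 = x1), y)
      expect_gte(without$aic, res$fit$aic)
    }
  }
  expect_gte(eliminated, 0.7 * reps)

  # a single strong covariate survives untouched
  set.seed(67)
  x <- rbinom(500, 1, 0.5)
  y <- rbinom(500, 1, stats::plogis(-0.5 + 1.5 * x))
  res <- backward_eliminate(data.frame(x = x), y)
  expect_equal(res$covariates, "x")
  expect_equal(nrow(res$trace), 1)

  # covariates exactly independent of the outcome in-sample eliminate
  # down to the intercept-only model
  y <- rep(0:1, each = 200)
  noise <- data.frame(a = rep(c(0, 1), 200), b = rep(c(0, 0, 1, 1), 100),
                      c = rep(c(0, 1, 1, 0), 100))
  res <- backward_eliminate(noise, y)
  expect_length(res$covariates, 0)
  # AIC and BIC recorded at every elimination step
  expect_equal(nrow(res$trace), 4)
  expect_true(all(is.finite(res$trace$aic)) && all(is.finite(res$trace$bic)))
  expect_true(all(diff(res$trace$aic) < 0))

  # protected covariates are never removed
  res <- backward_eliminate(noise, y, protected = "a")
  expect_true("a" %in% res$covariates)
})

test_that("the planted first-post odds ratio is recovered end to end", {
  cfg <- forum_sim_config(n_threads = c(OV = 300), seed = 404)
  g <- generate_forum(cfg)
  res <- analyse_sentiment(g$corpus)
  co <- res$fit$coefficients
  row <- co[co$covariate == "first_post", ]
  expect_true(row$ci_low <= cfg$first_post_negativity_or &&
                cfg$first_post_negativity_or <= row$ci_high)
  expect_lt(res$fit$lrt_p, 0.001)
  expect_gt(res$fit$auc, 0.5)
})
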