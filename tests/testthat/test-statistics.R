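test_that("satisfaction standardization maps 10-point ratings by ceiling(raw/2)", {
  expect_identical(standardize_satisfaction(c(1L, 10L), 10L), c(1L, 5L))
  expect_identical(standardize_satisfaction(7L, 10L), 4L)
  expect_identical(standardize_satisfaction(3L, 5L), 3L)
  expect_identical(standardize_satisfaction(NA_integer_, 10L), NA_integer_)
  expect_error(standardize_satisfaction(6L, 5L), class = "emospect_input_error")
  expect_error(standardize_satisfaction(0L, 10L), class = "emospect_input_error")
  expect_error(standardize_satisfaction(3L, 7L), class = "emospect_input_error")
  # every 10-point level lands on a valid Likert level
  expect_true(all(standardize_satisfaction(1:10, 10L) %in% 1:5))
})

test_that("prevalence percentages and SEs recompute from flag sums exactly", {
  dat <- flags_corpus(k = 1830, n = 3070, emotion = "joy")
  pt <- prevalence_table(dat$profiles, dat$records, NULL)
  joy <- pt$rows[pt$rows$emotion == "joy", ]
  expect_equal(joy$pct, 100 * 1830 / 3070, tolerance = 1e-12)
  p <- 1830 / 3070
  expect_equal(joy$se, sqrt(p * (1 - p) / 3070), tolerance = 1e-15)
  # zero-flag emotion: percent 0, SE 0
  love <- pt$rows[pt$rows$emotion == "love", ]
  expect_identical(love$pct, 0)
  expect_identical(love$se, 0)
})

test_that("stratified prevalence computes within-level denominators and chi-squares", {
  set.seed(1)
  n <- 300
  ids <- sprintf("r%03d", 1:n)
  drug <- factor(rep(c("sildenafil", "tadalafil"), each = n / 2),
                 levels = c("sildenafil", "vardenafil", "tadalafil"))
  profiles <- tibble::tibble(review_id = ids, joy = rbinom(n, 1, 0.5),
                             love = 0L, surprise = 0L,
                             sadness = rbinom(n, 1, ifelse(drug == "tadalafil", 0.6, 0.2)),
                             fear = rbinom(n, 1, 0.1), anger = rbinom(n, 1, 0.05))
  records <- tibble::tibble(review_id = ids, drug = drug)
  pt <- suppressWarnings(prevalence_table(profiles, records, "drug"))
  rows <- pt$rows
  for (lv in c("sildenafil", "tadalafil")) {
    sub <- profiles[drug == lv, ]
    expect_equal(rows$pct[rows$level == lv & rows$emotion == "sadness"],
                 100 * mean(sub$sadness), tolerance = 1e-12)
    expect_identical(unique(rows$n[rows$level == lv]), nrow(sub))
  }
  # overall chi-square equals the textbook oracle on the mention-count table
  counts <- matrix(rows$k, nrow = 2, byrow = TRUE)
  want <- oracle_chisq(counts)
  expect_equal(pt$chi_square$statistic, want$statistic, tolerance = 1e-10)
  expect_identical(as.integer(pt$chi_square$df), as.integer(want$df))
  expect_identical(nrow(pt$chi_square_per_emotion), 6L)
})

test_that("chi-square equals the textbook formula on random tables up to 6x6", {
  set.seed(99)
  # hand-derived anchor: N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) on [[20,10],[10,20]]
  tab0 <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  got0 <- suppressWarnings(chisq.test(tab0, correct = FALSE))
  expect_equal(unname(got0$statistic), 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-10)
  expect_equal(unname(got0$statistic), 6.6667, tolerance = 1e-4)
  expect_equal(oracle_chisq(tab0)$statistic, 6.66667, tolerance = 1e-5)
  for (rep in 1:20) {
    r <- sample(2:6, 1); cc <- sample(2:6, 1)
    tab <- matrix(rpois(r * cc, 20) + 1, r, cc)
    got <- suppressWarnings(chisq.test(tab, correct = FALSE))
    want <- oracle_chisq(tab)
    expect_equal(unname(got$statistic), want$statistic, tolerance = 1e-10)
    expect_identical(as.integer(got$parameter), as.integer(want$df))
  }
})

test_that("logistic fit on a 2x2 design matches the closed-form odds ratio", {
  for (counts in list(c(30, 45, 70, 55), c(120, 60, 80, 140), c(15, 5, 25, 40))) {
    a <- counts[1]; b <- counts[2]; c_ <- counts[3]; d <- counts[4]
    dat <- logit_2x2_data(a, b, c_, d)
    fit <- fit_emotion_logit(dat$profiles, dat$records, "joy", covariates = "drug")
    or_closed <- (b * c_) / (a * d)  # tadalafil vs sildenafil
    or_fit <- fit$terms$or[fit$terms$term == "drugtadalafil"]
    expect_equal(or_fit, or_closed, tolerance = 1e-4)
    # Wald CI brackets the estimate
    expect_lte(fit$terms$ci_lo[2], or_fit)
    expect_gte(fit$terms$ci_hi[2], or_fit)
  }
})

test_that("degenerate and separated logistic designs raise typed errors", {
  dat <- logit_2x2_data(30, 30, 0, 0)  # all outcomes 1
  expect_error(fit_emotion_logit(dat$profiles, dat$records, "joy",
                                 covariates = "drug"),
               class = "emospect_separation_error")
  dat2 <- logit_2x2_data(40, 0, 0, 40)  # complete separation by drug
  expect_error(fit_emotion_logit(dat2$profiles, dat2$records, "joy",
                                 covariates = "drug"),
               class = "emospect_separation_error")
})

test_that("logistic reference levels are sildenafil, 65+, short-term", {
  corp <- generate_corpus(generator_config(n_reviews = 600, seed = 21))
  profiles <- suppressMessages(annotate_corpus(corp$records, demo_lexicon()))
  fit <- fit_emotion_logit(profiles, corp$records, "sadness")
  expect_identical(unname(fit$reference_levels["drug"]), "sildenafil")
  expect_identical(unname(fit$reference_levels["age_band"]), ">=65")
  expect_identical(unname(fit$reference_levels["duration_band"]), "short")
  expect_true(all(c("drugtadalafil", "age_band<44", "duration_bandlong")
                  %in% fit$terms$term))
  expect_true(all(fit$terms$or > 0))
  expect_true(all(fit$terms$ci_lo <= fit$terms$or & fit$terms$or <= fit$terms$ci_hi))
})

test_that("sentiment regression recovers planted emotion coefficients", {
  cfg <- generator_config(n_reviews = 3000, seed = 123)
  cfg$sentiment_model$emotions[] <- c(0.45, 0, 0, -0.40, 0, 0)
  corp <- generate_corpus(cfg)
  records <- preprocess_reviews(corp$records)
  profiles <- suppressMessages(annotate_corpus(records, demo_lexicon()))
  sentiments <- score_corpus(records)
  fit <- fit_sentiment_on_emotions(profiles, sentiments, records)
  tb <- fit$terms
  for (term_val in list(c("joy", 0.45), c("sadness", -0.40), c("love", 0),
                        c("fear", 0))) {
    est <- tb$estimate[tb$term == term_val[1]]
    se <- tb$se[tb$term == term_val[1]]
    expect_lt(abs(est - as.numeric(term_val[2])), 3 * se)
  }
  expect_gt(fit$r_squared, 0.3)
})

test_that("constant sentiment yields zero slopes and zero R-squared", {
  corp <- generate_corpus(generator_config(n_reviews = 400, seed = 5))
  profiles <- suppressMessages(annotate_corpus(corp$records, demo_lexicon()))
  sentiments <- tibble::tibble(review_id = corp$records$review_id,
                               compound = 0.25, raw_sum = 1)
  fit <- suppressWarnings(fit_sentiment_on_emotions(profiles, sentiments, corp$records))
  slopes <- fit$terms$estimate[fit$terms$term != "(Intercept)"]
  expect_true(all(abs(slopes) < 1e-10))
  expect_identical(fit$r_squared, 0)
})

test_that("duplicated predictor columns raise a collinearity error naming them", {
  corp <- generate_corpus(generator_config(n_reviews = 400, seed = 9))
  profiles <- suppressMessages(annotate_corpus(corp$records, demo_lexicon()))
  profiles$fear <- profiles$sadness  # inject perfect duplication
  sentiments <- score_corpus(corp$records)
  err <- expect_error(
    fit_sentiment_on_emotions(profiles, sentiments, corp$records),
    class = "emospect_collinearity_error"
  )
  expect_match(conditionMessage(err), "fear")
})

test_that("nested satisfaction models share rows and delta R2 is non-negative", {
  corp <- generate_corpus(generator_config(n_reviews = 2000, seed = 31))
  sentiments <- score_corpus(corp$records)
  res <- fit_satisfaction_models(corp$records, sentiments)
  expect_identical(res$model_with$n_used, res$model_without$n_used)
  expect_identical(res$n_used, res$model_with$n_used)
  expect_equal(res$delta, res$r2_with - res$r2_without, tolerance = 1e-15)
  expect_gte(res$delta, 0)
  expect_true("compound" %in% res$model_with$terms$term)
  expect_false("compound" %in% res$model_without$terms$term)
})

test_that("fitted delta R2 matches the generator's variance decomposition", {
  cfg <- generator_config(n_reviews = 3000, seed = 77)
  cfg$satisfaction_model$intercept <- 3
  cfg$satisfaction_model$sentiment_beta <- 1.0
  cfg$satisfaction_model$age[] <- 0
  cfg$satisfaction_model$drug[] <- 0
  cfg$satisfaction_model$duration[] <- 0
  cfg$satisfaction_model$year_beta <- 0
  cfg$satisfaction_model$noise_sd <- 0.5
  corp <- generate_corpus(cfg)
  sentiments <- score_corpus(corp$records)
  res <- fit_satisfaction_models(corp$records, sentiments)
  # population delta from the variance decomposition, computed on the rows
  # the models used: b^2 var(s | covariates) / var(y)
  used <- stats::model.frame(res$model_with$fit)
  s_resid <- stats::resid(lm(compound ~ drug + age_band + duration_band +
                               rating_year, data = used))
  pop_delta <- 1.0^2 * var(s_resid) / var(used$satisfaction_5)
  expect_lt(abs(res$delta - pop_delta), 0.05)
})

test_that("tidy and glance expose broom-style summaries", {
  corp <- generate_corpus(generator_config(n_reviews = 500, seed = 13))
  profiles <- suppressMessages(annotate_corpus(corp$records, demo_lexicon()))
  sentiments <- score_corpus(corp$records)
  fit <- fit_sentiment_on_emotions(profiles, sentiments, corp$records)
  td <- tidy(fit)
  expect_true(all(c("model_id", "term", "estimate", "se", "p_value") %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$r_squared >= 0 && gl$r_squared <= 1)
  res <- fit_satisfaction_models(corp$records, sentiments)
  expect_true(all(c("r2_with", "r2_without", "delta") %in% names(glance(res))))
  lfit <- fit_emotion_logit(profiles, corp$records, "joy")
  expect_true(all(c("or", "ci_lo", "ci_hi") %in% names(tidy(lfit))))
})
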