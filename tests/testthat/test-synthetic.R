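test_that("same config and seed reproduce the corpus exactly", {
  cfg <- generator_config(n_reviews = 200, seed = 17)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$truth$per_review, c2$truth$per_review)
  # a different seed changes the corpus
  c3 <- generate_corpus(cfg, seed = 18)
  expect_false(identical(c1$records$text, c3$records$text))
})

test_that("planted flags equal annotator output when filler is lexicon-disjoint", {
  cfg <- generator_config(n_reviews = 500, seed = 29)
  corp <- generate_corpus(cfg)
  profiles <- suppressMessages(annotate_corpus(corp$records, demo_lexicon()))
  truth <- corp$truth$per_review
  truth <- truth[match(profiles$review_id, truth$review_id), ]
  for (e in c("joy", "love", "surprise", "sadness", "fear", "anger")) {
    expect_identical(profiles[[e]], truth[[e]])
  }
})

test_that("scorer reproduces the generator's realized compound exactly", {
  corp <- generate_corpus(generator_config(n_reviews = 300, seed = 41))
  s <- score_corpus(corp$records)
  truth <- corp$truth$per_review
  expect_equal(s$compound, truth$compound_realized[match(s$review_id, truth$review_id)],
               tolerance = 1e-12)
  # realized compound tracks the planted target within steering resolution
  r_target <- truth$compound_target
  raw_t <- r_target * sqrt(15 / (1 - r_target^2))
  raw_r <- truth$compound_realized * sqrt(15 / (1 - truth$compound_realized^2))
  expect_lt(max(abs(raw_t - raw_r)), 0.13 + 1e-9)
})

test_that("an emotion planted at zero prevalence never appears", {
  cfg <- generator_config(n_reviews = 300, seed = 53)
  cfg$emotion_model$anger$intercept <- -Inf
  corp <- generate_corpus(cfg)
  profiles <- suppressMessages(annotate_corpus(corp$records, demo_lexicon()))
  expect_identical(sum(profiles$anger), 0L)
})

test_that("planted prevalence is recovered within the binomial sampling bound", {
  n <- 2000
  cfg <- generator_config(n_reviews = n, seed = 61)
  # flat 0.60 joy prevalence regardless of stratum
  cfg$emotion_model$joy$intercept <- qlogis(0.60)
  cfg$emotion_model$joy$drug[] <- 0
  cfg$emotion_model$joy$age[] <- 0
  cfg$emotion_model$joy$duration[] <- 0
  corp <- generate_corpus(cfg)
  profiles <- suppressMessages(annotate_corpus(corp$records, demo_lexicon()))
  expect_lt(abs(mean(profiles$joy) - 0.60), 3 * sqrt(0.6 * 0.4 / n))
})

test_that("raising an emotion's intercept never lowers its empirical prevalence", {
  prev <- numeric(0)
  for (int_p in c(0.05, 0.2, 0.4, 0.6, 0.8)) {
    cfg <- generator_config(n_reviews = 400, seed = 71)
    cfg$emotion_model$fear$intercept <- qlogis(int_p)
    cfg$emotion_model$fear$drug[] <- 0
    cfg$emotion_model$fear$age[] <- 0
    cfg$emotion_model$fear$duration[] <- 0
    corp <- generate_corpus(cfg)
    prev <- c(prev, mean(corp$truth$per_review$fear))
  }
  expect_true(all(diff(prev) >= 0))
})

test_that("filler vocabulary overlapping lexicon resources is a config error", {
  cfg <- generator_config(n_reviews = 10, seed = 1)
  cfg$filler_vocab <- c(cfg$filler_vocab, "happy")
  expect_error(generate_corpus(cfg), class = "emospect_config_error")
  cfg2 <- generator_config(n_reviews = 10, seed = 1)
  cfg2$filler_vocab <- c(cfg2$filler_vocab, "good")
  expect_error(generate_corpus(cfg2), class = "emospect_config_error")
  # lemmatization-level collision: "blues" is a lexicon term
  cfg3 <- generator_config(n_reviews = 10, seed = 1)
  cfg3$filler_vocab <- c(cfg3$filler_vocab, "blues")
  expect_error(generate_corpus(cfg3), class = "emospect_config_error")
})

test_that("roundtrip check recovers a planted drug odds ratio inside its CI", {
  cfg <- generator_config(n_reviews = 3000, seed = 83)
  rt <- suppressMessages(roundtrip_check(cfg))
  row <- rt$logit[rt$logit$term == "drugtadalafil", ]
  expect_equal(row$planted_log_or, log(3.85), tolerance = 1e-12)
  expect_gt(exp(row$planted_log_or), row$ci_lo)
  expect_lt(exp(row$planted_log_or), row$ci_hi)
  # prevalence recovered exactly (generator guarantee)
  expect_equal(rt$prevalence$recovered, rt$prevalence$planted, tolerance = 1e-12)
})

test_that("null satisfaction slope yields near-zero delta R2", {
  cfg <- generator_config(n_reviews = 3000, seed = 97)
  cfg$satisfaction_model$sentiment_beta <- 0
  corp <- generate_corpus(cfg)
  sentiments <- score_corpus(corp$records)
  res <- fit_satisfaction_models(corp$records, sentiments)
  expect_lte(res$delta, 0.01)
})
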