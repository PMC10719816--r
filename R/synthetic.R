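# Default filler vocabulary: neutral drug-review tokens, disjoint by
# construction from the demo emotion lexicon, the valence lexicon, the
# boosters and the negators (validated at generation time).
DEFAULT_FILLER <- c(
  "tablet", "capsule", "dose", "doctor", "pharmacy", "refill", "insurance",
  "breakfast", "evening", "routine", "schedule", "glass", "water", "kitchen",
  "tuesday", "ordered", "shipment", "bottle", "pack", "generic", "brand",
  "copay", "appointment", "clinic", "nurse", "counter", "online", "website",
  "account", "entry", "record", "update", "version", "batch", "packet",
  "cabinet", "drawer", "wallet", "calendar", "reminder"
)

# Calibration words used to steer a review's summed valence toward its
# target; all must exist in the valence lexicon and stay out of the emotion
# lexicon. Coarse-to-fine magnitudes give a worst-case residual of half the
# smallest magnitude.
CALIBRATION_WORDS <- c("superb", "solid", "decent", "okay",
                       "awful", "poor", "mediocre", "iffy")

#' Configuration for the synthetic review-corpus generator
#'
#' Defines the ground-truth data-generating process: stratum frequencies
#' (drug, age band, duration band, rating year, source site), a per-emotion
#' logistic model (reference-stratum intercept on the log-odds scale plus
#' log-odds-ratio effects of drug, age, and duration), a linear sentiment
#' model mapping planted emotion flags and covariates to a mean compound
#' score, and a linear satisfaction model on sentiment and covariates. The
#' defaults echo the marginal structure and effect sizes typical of public
#' PDE5-inhibitor review corpora (drug mix roughly 973/406/1691; joy around
#' 60% prevalence; a strongly elevated sadness odds ratio for tadalafil;
#' sentiment slopes near 0.5 in magnitude for the dominant emotions; a
#' satisfaction slope near 1 on sentiment). They are fixed study
#' conditions, not tuning knobs.
#'
#' @param n_reviews Number of reviews to generate.
#' @param drug_probs,age_probs,duration_probs,year_probs,source_probs Named
#'   sampling weights for the strata (normalized internally). Age and
#'   duration weights are conditional on the band being observed;
#'   missingness is applied separately.
#' @param emotion_model Named list (one element per primary emotion), each
#'   a list with `intercept` (log-odds at sildenafil / age 65+ /
#'   short-term), `drug`, `age`, `duration` (named log-OR vectors).
#' @param sentiment_model List: `intercept`, `emotions` (named vector of
#'   slopes on the six flags), `drug`, `duration` (named vectors),
#'   `year_beta` (per year since 2001), `noise_sd`.
#' @param satisfaction_model List: `intercept`, `sentiment_beta`, `age`,
#'   `duration`, `drug` (named vectors), `year_beta`, `noise_sd`.
#' @param filler_vocab Character vector of neutral tokens; must be disjoint
#'   from all lexicon resources.
#' @param missing_rates Named vector: probabilities that `age_band`,
#'   `duration_band`, `satisfaction_raw` are unobserved in the emitted
#'   record (the latent value still drives generation).
#' @param n_filler Integer range (length 2) of filler tokens per review.
#' @param seed Default seed used by [generate_corpus()].
#' @return A validated list of class `emospect_config`.
#' @export
generator_config <- function(
    n_reviews = 3070,
    drug_probs = c(sildenafil = 973, vardenafil = 406, tadalafil = 1691),
    age_probs = c("<44" = 547, "45-64" = 1252, ">=65" = 361),
    duration_probs = c(short = 1001, mid = 676, long = 665),
    year_probs = c(rep(759 / 9, 9), rep(2020 / 10, 10), rep(291 / 3, 3)) |>
      setNames(2001:2022),
    source_probs = c(webmd = 0.4, askapatient = 0.2, drugscom = 0.4),
    emotion_model = default_emotion_model(),
    sentiment_model = default_sentiment_model(),
    satisfaction_model = default_satisfaction_model(),
    filler_vocab = DEFAULT_FILLER,
    missing_rates = c(age = 0.296, duration = 0.237, satisfaction = 0.04),
    n_filler = c(6L, 14L),
    seed = 1L) {
  cfg <- list(
    n_reviews = as.integer(n_reviews),
    drug_probs = drug_probs / sum(drug_probs),
    age_probs = age_probs / sum(age_probs),
    duration_probs = duration_probs / sum(duration_probs),
    year_probs = year_probs / sum(year_probs),
    source_probs = source_probs / sum(source_probs),
    emotion_model = emotion_model,
    sentiment_model = sentiment_model,
    satisfaction_model = satisfaction_model,
    filler_vocab = filler_vocab,
    missing_rates = missing_rates,
    n_filler = as.integer(n_filler),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_reviews >= 0,
    identical(names(cfg$drug_probs), DRUG_LEVELS),
    identical(names(cfg$age_probs), AGE_LEVELS),
    identical(names(cfg$duration_probs), DURATION_LEVELS),
    all(cfg$missing_rates >= 0 & cfg$missing_rates <= 1),
    length(cfg$n_filler) == 2L, cfg$n_filler[1] <= cfg$n_filler[2]
  )
  ors <- unlist(lapply(cfg$emotion_model, function(m) exp(unlist(m[c("drug", "age", "duration")]))))
  stopifnot(all(ors > 0))
  structure(cfg, class = "emospect_config")
}

#' @rdname generator_config
#' @export
default_emotion_model <- function() {
  mk <- function(int_p, vard, tada, a44, a4564, mid, long) {
    list(
      intercept = qlogis(int_p),
      drug = c(vardenafil = log(vard), tadalafil = log(tada)),
      age = c("<44" = log(a44), "45-64" = log(a4564)),
      duration = c(mid = log(mid), long = log(long))
    )
  }
  list(
    joy = mk(0.50, 1.15, 1.12, 1.69, 1.54, 1.40, 1.41),
    love = mk(0.18, 0.95, 1.07, 1.05, 1.03, 1.06, 1.11),
    surprise = mk(0.11, 0.75, 0.79, 2.00, 1.49, 0.90, 0.82),
    sadness = mk(0.18, 1.06, 3.85, 1.86, 1.98, 0.49, 0.61),
    fear = mk(0.10, 0.49, 0.71, 2.25, 1.28, 0.72, 0.51),
    anger = mk(0.055, 1.06, 1.22, 1.07, 0.93, 0.74, 0.91)
  )
}

#' @rdname generator_config
#' @export
default_sentiment_model <- function() {
  list(
    intercept = -0.16,
    emotions = c(joy = 0.467, love = 0.249, surprise = 0.287,
                 sadness = -0.433, fear = -0.139, anger = -0.114),
    drug = c(vardenafil = 0, tadalafil = -0.067),
    duration = c(mid = 0.155, long = 0.141),
    year_beta = 0.005,
    noise_sd = 0.2
  )
}

#' @rdname generator_config
#' @export
default_satisfaction_model <- function() {
  list(
    intercept = 3.04,
    sentiment_beta = 0.97,
    age = c("<44" = 0.32, "45-64" = 0.26),
    drug = c(vardenafil = -0.07, tadalafil = 0.04),
    duration = c(mid = 0.43, long = 0.57),
    year_beta = 0.01,
    noise_sd = 0.65
  )
}

effect_of <- function(vec, level) {
  out <- vec[as.character(level)]
  out[is.na(out)] <- 0
  unname(out)
}

#' Generate a synthetic review corpus with known ground truth
#'
#' Builds a corpus whose statistical structure is fully known: strata are
#' sampled from the configured weights; per-review emotion flags are drawn
#' from the per-stratum logistic model; review text is a token bag of
#' neutral filler, at least one lexicon term from each active emotion's
#' branch, and calibration valence words whose sum steers the rule-based
#' scorer to the sentiment model's target; satisfaction is drawn from the
#' satisfaction model and discretized to the source's Likert scale;
#' missingness is applied last. Because the filler vocabulary is disjoint
#' from every lexicon resource, the annotator recovers the planted flags
#' exactly — the generator's defining guarantee. Text realism is
#' deliberately sacrificed for this exactness.
#'
#' @param config An [generator_config()] object.
#' @param lex Emotion lexicon to plant terms from (default [demo_lexicon()]).
#' @param vlex Valence lexicon used to steer sentiment (default
#'   [default_valence_lexicon()]).
#' @param seed Integer seed; defaults to `config$seed`. One stream seeds the
#'   stratum draws, and per-review substreams (derived from it by review
#'   index) drive text assembly.
#' @param alpha Sentiment normalization constant (must match scoring).
#' @return A list of class `emospect_corpus`: `records` (review tibble) and
#'   `truth` (list: `per_review` tibble of planted flags and targets,
#'   `config`).
#' @export
generate_corpus <- function(config = generator_config(), lex = demo_lexicon(),
                            vlex = default_valence_lexicon(),
                            seed = config$seed, alpha = 15) {
  stopifnot(inherits(config, "emospect_config"))
  validate_generator_inputs(config, lex, vlex)
  n <- config$n_reviews
  set.seed(seed)

  drug <- sample(DRUG_LEVELS, n, TRUE, prob = config$drug_probs)
  age_band <- sample(AGE_LEVELS, n, TRUE, prob = config$age_probs)
  duration_band <- sample(DURATION_LEVELS, n, TRUE, prob = config$duration_probs)
  year <- as.integer(sample(names(config$year_probs), n, TRUE,
                            prob = config$year_probs))
  source <- sample(names(config$source_probs), n, TRUE,
                   prob = config$source_probs)

  # per-emotion logistic model -> planted flags
  flags <- matrix(0L, n, 6L, dimnames = list(NULL, EMOTION_COLS))
  for (e in EMOTION_COLS) {
    m <- config$emotion_model[[e]]
    lp <- m$intercept + effect_of(m$drug, drug) + effect_of(m$age, age_band) +
      effect_of(m$duration, duration_band)
    flags[, e] <- rbinom(n, 1L, plogis(lp))
  }

  # sentiment target per review
  sm <- config$sentiment_model
  mu_s <- sm$intercept + as.vector(flags %*% sm$emotions[EMOTION_COLS]) +
    effect_of(sm$drug, drug) + effect_of(sm$duration, duration_band) +
    sm$year_beta * (year - 2001)
  target <- pmin(pmax(mu_s + rnorm(n, 0, sm$noise_sd), -0.93), 0.93)

  # per-review substreams for text assembly
  review_seeds <- sample.int(.Machine$integer.max - 1L, n)

  branch_terms <- split(lex$term_index$term, lex$term_index$primary)
  calib <- vlex$valence[CALIBRATION_WORDS]
  texts <- character(n)
  realized <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(review_seeds[i])
    toks <- sample(config$filler_vocab,
                   sample(config$n_filler[1]:config$n_filler[2], 1L),
                   replace = TRUE)
    planted <- character(0)
    for (e in EMOTION_COLS[flags[i, ] == 1L]) {
      pool <- branch_terms[[e]]
      planted <- c(planted, sample(pool, min(length(pool), 1L + rbinom(1, 1, 0.3))))
    }
    planted_tokens <- unlist(strsplit(planted, " ", fixed = TRUE))
    v0 <- sum(vlex$valence[planted_tokens], na.rm = TRUE)
    r_target <- target[i] * sqrt(alpha / (1 - target[i]^2))
    cal <- steer_valence(r_target - v0, calib)
    raw <- v0 + sum(calib[cal])
    realized[i] <- raw / sqrt(raw^2 + alpha)
    all_toks <- c(toks, planted, cal)
    texts[i] <- paste(sample(all_toks), collapse = " ")
  }

  # satisfaction from realized compound
  sat <- config$satisfaction_model
  sat_mu <- sat$intercept + sat$sentiment_beta * realized +
    effect_of(sat$age, age_band) + effect_of(sat$drug, drug) +
    effect_of(sat$duration, duration_band) + sat$year_beta * (year - 2001)
  sat_cont <- sat_mu + rnorm(n, 0, sat$noise_sd)
  scale <- ifelse(source == "drugscom", 10L, 5L)
  raw_sat <- ifelse(scale == 5L,
                    pmin(pmax(round(sat_cont), 1), 5),
                    pmin(pmax(round(2 * sat_cont), 1), 10))

  # observation-level missingness (latent values already consumed above)
  mr <- config$missing_rates
  age_obs <- ifelse(stats::runif(n) < mr[["age"]], NA_character_, age_band)
  dur_obs <- ifelse(stats::runif(n) < mr[["duration"]], NA_character_, duration_band)
  sat_obs <- ifelse(stats::runif(n) < mr[["satisfaction"]], NA_integer_,
                    as.integer(raw_sat))

  records <- tibble::tibble(
    review_id = sprintf("r%05d", seq_len(n)),
    source = factor(source, levels = SOURCE_LEVELS),
    drug = factor(drug, levels = DRUG_LEVELS),
    text = texts,
    age_band = factor(age_obs, levels = AGE_LEVELS),
    duration_band = factor(dur_obs, levels = DURATION_LEVELS),
    rating_year = year,
    satisfaction_raw = sat_obs,
    satisfaction_scale = scale
  )
  records$satisfaction_5 <- standardize_satisfaction(records$satisfaction_raw,
                                                     records$satisfaction_scale)

  truth_tbl <- tibble::tibble(review_id = records$review_id)
  for (e in EMOTION_COLS) truth_tbl[[e]] <- flags[, e]
  truth_tbl$compound_target <- target
  truth_tbl$compound_realized <- realized
  truth_tbl$satisfaction_mean <- sat_mu
  truth_tbl$age_band_true <- factor(age_band, levels = AGE_LEVELS)
  truth_tbl$duration_band_true <- factor(duration_band, levels = DURATION_LEVELS)

  structure(list(records = records,
                 truth = list(per_review = truth_tbl, config = config)),
            class = "emospect_corpus")
}

#' @export
print.emospect_corpus <- function(x, ...) {
  cat("<emospect_corpus> ", nrow(x$records), " synthetic reviews\n", sep = "")
  print(head(x$records, 3))
  invisible(x)
}

# Greedy approximation of a raw-valence target with calibration words;
# residual is bounded by half the smallest calibration magnitude.
steer_valence <- function(r, calib) {
  out <- character(0)
  guard <- 0L
  repeat {
    cand <- calib[sign(calib) == sign(r) & abs(calib) <= abs(r) + 0.125]
    if (!length(cand) || abs(r) <= 0.13 || guard > 200L) break
    pick <- names(cand)[which.max(abs(cand))]
    out <- c(out, pick)
    r <- r - calib[[pick]]
    guard <- guard + 1L
  }
  out
}

validate_generator_inputs <- function(config, lex, vlex) {
  reserved <- unique(c(
    lex$term_index$term,
    unlist(strsplit(lex$term_index$term, " ", fixed = TRUE)),
    names(vlex$valence), names(vlex$boosters), vlex$negators
  ))
  clash <- intersect(tolower(config$filler_vocab), reserved)
  if (length(clash)) {
    abort(paste0("Filler vocabulary overlaps lexicon resources: ",
                 paste(clash, collapse = ", "), "."),
          class = "emospect_config_error")
  }
  # filler must also survive cleaning unchanged into non-lexicon tokens
  cleaned <- lemmatize_tokens(tolower(config$filler_vocab))
  clash2 <- intersect(cleaned, lex$term_index$term)
  if (length(clash2)) {
    abort(paste0("Filler vocabulary lemmatizes into lexicon terms: ",
                 paste(clash2, collapse = ", "), "."),
          class = "emospect_config_error")
  }
  missing_cal <- setdiff(CALIBRATION_WORDS, names(vlex$valence))
  if (length(missing_cal)) {
    abort(paste0("Calibration words absent from valence lexicon: ",
                 paste(missing_cal, collapse = ", "),
                 "; sentiment targets are unreachable."),
          class = "emospect_config_error")
  }
  cal_clash <- intersect(CALIBRATION_WORDS, lex$term_index$term)
  if (length(cal_clash)) {
    abort(paste0("Calibration words collide with emotion lexicon terms: ",
                 paste(cal_clash, collapse = ", "), "."),
          class = "emospect_config_error")
  }
  invisible(TRUE)
}

#' Planted-versus-recovered check over the full pipeline
#'
#' Generates a corpus, runs annotation, sentiment scoring and the full
#' statistical layer, and reports planted quantities next to their
#' recovered estimates: per-emotion prevalence, the log-odds-ratio terms of
#' a chosen emotion's logistic model, the sentiment-model slopes, and the
#' satisfaction delta R-squared.
#'
#' @inheritParams generate_corpus
#' @param logit_emotions Emotions whose logistic fits to compare (default
#'   `"sadness"`, the emotion with the largest planted drug effect).
#' @return A list of class `emospect_roundtrip` with tibbles `prevalence`,
#'   `logit`, `sentiment_betas`, and scalar `delta_r2`, plus `fits`.
#' @export
roundtrip_check <- function(config = generator_config(), lex = demo_lexicon(),
                            vlex = default_valence_lexicon(),
                            seed = config$seed,
                            logit_emotions = "sadness") {
  corpus <- generate_corpus(config, lex, vlex, seed = seed)
  records <- preprocess_reviews(corpus$records)
  truth <- corpus$truth$per_review
  profiles <- annotate_corpus(records, lex)
  sentiments <- score_corpus(records, vlex)

  prevalence <- purrr::map_dfr(EMOTION_COLS, function(e) {
    tibble::tibble(
      emotion = e,
      planted = mean(truth[[e]]),
      recovered = mean(profiles[[e]])
    )
  })

  logit <- purrr::map_dfr(logit_emotions, function(e) {
    m <- config$emotion_model[[e]]
    planted <- c(m$drug, m$age, m$duration)
    names(planted) <- c("drugvardenafil", "drugtadalafil",
                        "age_band<44", "age_band45-64",
                        "duration_bandmid", "duration_bandlong")
    fit <- fit_emotion_logit(profiles, records, e)
    tb <- tidy(fit)
    tb$planted_log_or <- unname(planted[tb$term])
    tb$emotion <- e
    tb[!is.na(tb$planted_log_or),
       c("emotion", "term", "planted_log_or", "estimate", "se",
         "or", "ci_lo", "ci_hi")]
  })

  sfit <- fit_sentiment_on_emotions(profiles, sentiments, records)
  stb <- tidy(sfit)
  planted_s <- config$sentiment_model$emotions
  sentiment_betas <- stb[stb$term %in% names(planted_s),
                         c("term", "estimate", "se", "p_value")]
  sentiment_betas$planted <- unname(planted_s[sentiment_betas$term])

  dfit <- fit_satisfaction_models(records, sentiments)

  structure(
    list(prevalence = prevalence, logit = logit,
         sentiment_betas = sentiment_betas, delta_r2 = dfit$delta,
         fits = list(sentiment = sfit, satisfaction = dfit)),
    class = "emospect_roundtrip"
  )
}

#' @export
print.emospect_roundtrip <- function(x, ...) {
  cat("<emospect_roundtrip>\nPrevalence (planted vs recovered):\n")
  print(x$prevalence)
  cat("\nLogistic terms:\n")
  print(x$logit)
  cat("\nSentiment slopes:\n")
  print(x$sentiment_betas)
  cat(sprintf("\nSatisfaction delta R2: %.4f\n", x$delta_r2))
  invisible(x)
}
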