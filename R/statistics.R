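WALD_Z <- 1.959964

#' Standardize a satisfaction rating to the 1-5 Likert scale
#'
#' Ratings collected on a 1-5 scale pass through unchanged; ratings on a
#' 1-10 scale are mapped by `ceiling(raw / 2)`, which preserves the integer
#' Likert levels and the endpoints (1 -> 1, 10 -> 5).
#'
#' @param raw Integer vector of raw ratings.
#' @param scale Integer vector (5 or 10), recycled, giving each rating's
#'   original scale.
#' @return Integer vector on the 1-5 scale; `NA` propagates.
#' @examples
#' standardize_satisfaction(c(1, 7, 10), 10)
#' @export
standardize_satisfaction <- function(raw, scale) {
  scale <- rep_len(scale, length(raw))
  if (!all(scale %in% c(5L, 10L), na.rm = TRUE)) {
    abort("`scale` must be 5 or 10.", class = "emospect_input_error")
  }
  ok <- is.na(raw) | (raw >= 1 & raw <= scale)
  if (!all(ok)) {
    abort(paste0("Rating out of range for its scale (first offender: raw=",
                 raw[!ok][1], ", scale=", scale[!ok][1], ")."),
          class = "emospect_input_error")
  }
  out <- ifelse(scale == 5L, raw, ceiling(raw / 2))
  as.integer(out)
}

#' Prevalence of a binary outcome with its binomial standard error
#'
#' @param k Number of reviews expressing the outcome.
#' @param n Total reviews in the stratum.
#' @return A tibble: `pct` (percentage, 0-100) and `se` (standard error of
#'   the proportion, `sqrt(p(1-p)/n)`, on the 0-1 scale).
#' @examples
#' binomial_prevalence(1830, 3070) # pct 59.61...
#' @export
binomial_prevalence <- function(k, n) {
  stopifnot(all(n > 0), all(k >= 0), all(k <= n))
  p <- k / n
  tibble::tibble(pct = 100 * p, se = sqrt(p * (1 - p) / n))
}

join_profiles <- function(profiles, records) {
  stopifnot(is.data.frame(profiles), is.data.frame(records))
  recs <- dplyr::mutate(tibble::as_tibble(records),
                        review_id = as.character(.data$review_id))
  profs <- dplyr::mutate(tibble::as_tibble(profiles),
                         review_id = as.character(.data$review_id))
  dplyr::inner_join(profs, recs, by = "review_id")
}

#' Stratified emotion prevalence with chi-square tests
#'
#' Joins emotion profiles to review records and computes, within each level
#' of the stratifier, the percentage of reviews expressing each primary
#' emotion together with its binomial standard error. Records missing the
#' stratifier are excluded from that stratification. Two chi-square
#' summaries are computed without continuity correction: one statistic per
#' stratifier on the level-by-emotion mention-count table (the
#' one-p-per-characteristic layout used in prevalence reporting), plus the
#' statistically cleaner per-emotion presence-by-level tests.
#'
#' @param profiles Emotion-profile tibble ([annotate_corpus()]).
#' @param records Review-record tibble with the stratifier column.
#' @param stratifier One of `"drug"`, `"age_band"`, `"duration_band"`, or
#'   `NULL` for the pooled corpus (no test).
#' @return An object of class `emospect_prevalence`: list with `rows`
#'   (tibble: level, emotion, n, k, pct, se), `chi_square` (overall),
#'   `chi_square_per_emotion` (tibble), and `stratifier`.
#' @export
prevalence_table <- function(profiles, records,
                             stratifier = c("drug", "age_band", "duration_band")) {
  pooled <- is.null(stratifier)
  if (!pooled) stratifier <- match.arg(stratifier)
  d <- join_profiles(profiles, records)
  if (pooled) {
    d$.level <- factor(rep("all", nrow(d)))
  } else {
    if (!stratifier %in% names(d)) {
      abort(paste0("Records lack stratifier column '", stratifier, "'."),
            class = "emospect_input_error")
    }
    d$.level <- d[[stratifier]]
    d <- d[!is.na(d$.level), ]
  }
  if (!nrow(d)) {
    abort("No records left after removing missing stratifier values.",
          class = "emospect_input_error")
  }
  d$.level <- droplevels(as.factor(d$.level))
  empties <- setdiff(levels(as.factor(if (pooled) "all" else records[[stratifier]])),
                     levels(d$.level))
  if (length(empties)) {
    warn(paste0("Dropping empty stratifier level(s): ",
                paste(empties, collapse = ", "), "."))
  }

  rows <- d |>
    dplyr::group_by(level = .data$.level) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(EMOTION_COLS), sum),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(EMOTION_COLS),
                        names_to = "emotion", values_to = "k") |>
    dplyr::mutate(emotion = factor(.data$emotion, levels = EMOTION_COLS)) |>
    dplyr::arrange(.data$level, .data$emotion)
  rows <- dplyr::bind_cols(rows, binomial_prevalence(rows$k, rows$n))
  rows <- rows[, c("level", "emotion", "n", "k", "pct", "se")]

  chi_overall <- NULL
  chi_per <- NULL
  if (!pooled && nlevels(d$.level) >= 2L) {
    counts <- matrix(rows$k, nrow = nlevels(d$.level), byrow = TRUE,
                     dimnames = list(levels(d$.level), EMOTION_COLS))
    if (sum(counts) == 0) {
      abort("All emotion counts are zero; chi-square statistic undefined.",
            class = "emospect_degenerate_error")
    }
    ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
    chi_overall <- tibble::tibble(
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p_value = unname(ct$p.value)
    )
    chi_per <- purrr::map_dfr(EMOTION_COLS, function(e) {
      tab <- table(d$.level, factor(d[[e]], levels = c(0, 1)))
      res <- suppressWarnings(chisq.test(tab, correct = FALSE))
      tibble::tibble(emotion = e, statistic = unname(res$statistic),
                     df = unname(res$parameter), p_value = unname(res$p.value))
    })
  }

  structure(
    list(rows = rows, chi_square = chi_overall,
         chi_square_per_emotion = chi_per,
         stratifier = if (pooled) "pooled" else stratifier),
    class = "emospect_prevalence"
  )
}

#' @export
print.emospect_prevalence <- function(x, ...) {
  cat("<emospect_prevalence> stratifier: ", x$stratifier, "\n", sep = "")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x$rows, cell = sprintf("%.2f (%.3f)", .data$pct, .data$se)),
    id_cols = c("level", "n"), names_from = "emotion", values_from = "cell"
  )
  print(wide)
  if (!is.null(x$chi_square)) {
    cat(sprintf("chi-square %.3f on %d df, p = %.3g\n", x$chi_square$statistic,
                x$chi_square$df, x$chi_square$p_value))
  }
  invisible(x)
}

#' @export
tidy.emospect_prevalence <- function(x, ...) x$rows

# Shared model-frame builder: joins, selects, listwise-deletes, sets
# reference levels (drug: sildenafil; age: >=65; duration: short).
build_model_frame <- function(d, vars) {
  d <- d[, unique(c("review_id", vars)), drop = FALSE]
  d <- d[stats::complete.cases(d[, vars, drop = FALSE]), , drop = FALSE]
  if ("drug" %in% vars) {
    d$drug <- droplevels(factor(d$drug, levels = DRUG_LEVELS))
    if ("sildenafil" %in% levels(d$drug)) {
      d$drug <- stats::relevel(d$drug, ref = "sildenafil")
    }
  }
  if ("age_band" %in% vars) {
    d$age_band <- droplevels(factor(d$age_band, levels = AGE_LEVELS))
    if (">=65" %in% levels(d$age_band)) {
      d$age_band <- stats::relevel(d$age_band, ref = ">=65")
    }
  }
  if ("duration_band" %in% vars) {
    d$duration_band <- droplevels(factor(d$duration_band, levels = DURATION_LEVELS))
    if ("short" %in% levels(d$duration_band)) {
      d$duration_band <- stats::relevel(d$duration_band, ref = "short")
    }
  }
  d
}

reference_levels <- function(frame) {
  fac <- names(frame)[vapply(frame, is.factor, logical(1))]
  setNames(vapply(fac, function(v) levels(frame[[v]])[1], character(1)), fac)
}

new_fit <- function(model_id, fit, terms, n_used, refs,
                    r_squared = NA_real_, adj_r_squared = NA_real_,
                    subclass = character(0)) {
  structure(
    list(model_id = model_id, fit = fit, terms = terms, n_used = n_used,
         reference_levels = refs, r_squared = r_squared,
         adj_r_squared = adj_r_squared),
    class = c(subclass, "emospect_fit")
  )
}

#' Per-emotion logistic regression with odds ratios
#'
#' Fits a maximum-likelihood logistic regression of one primary emotion's
#' presence flag on patient characteristics, with reference levels
#' sildenafil, age 65+, and short-term use. Odds ratios are `exp(beta)`
#' with Wald 95% confidence intervals `exp(beta +/- 1.96 se)`. Records
#' missing any covariate are listwise-deleted.
#'
#' @inheritParams prevalence_table
#' @param emotion One of the six primary-emotion labels.
#' @param covariates Character vector of covariate columns (default
#'   `drug`, `age_band`, `duration_band`).
#' @return An `emospect_fit` (subclass `emospect_logit`) with a `terms`
#'   tibble: term, estimate, se, p_value, or, ci_lo, ci_hi.
#' @export
fit_emotion_logit <- function(profiles, records, emotion,
                              covariates = c("drug", "age_band", "duration_band")) {
  stopifnot(emotion %in% EMOTION_COLS)
  d <- join_profiles(profiles, records)
  frame <- build_model_frame(d, c(emotion, covariates))
  if (!nrow(frame) || !length(covariates)) {
    abort("Empty design after listwise deletion.",
          class = "emospect_input_error")
  }
  y <- frame[[emotion]]
  if (length(unique(y)) < 2L) {
    abort(paste0("Outcome '", emotion,
                 "' has a single class after listwise deletion; ",
                 "logistic model is degenerate."),
          class = "emospect_separation_error")
  }
  fml <- as.formula(paste(emotion, "~", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(glm(fml, data = frame, family = binomial()))
  est <- coef(fit)
  if (!fit$converged || any(abs(est[-1]) > 15, na.rm = TRUE)) {
    worst <- names(which.max(abs(est[-1])))
    abort(paste0("Logistic fit did not converge (complete or quasi-complete ",
                 "separation); offending term: ", worst, "."),
          class = "emospect_separation_error")
  }
  sm <- summary(fit)$coefficients
  terms <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    se = unname(sm[, "Std. Error"]),
    p_value = unname(sm[, "Pr(>|z|)"]),
    or = exp(estimate),
    ci_lo = exp(estimate - WALD_Z * se),
    ci_hi = exp(estimate + WALD_Z * se)
  )
  new_fit(paste0("logit_", emotion), fit, terms, nrow(frame),
          reference_levels(frame), subclass = "emospect_logit")
}

# OLS fit shared by the sentiment and satisfaction models; errors on
# rank deficiency, naming the aliased columns.
fit_ols <- function(frame, response, predictors, model_id) {
  fml <- as.formula(paste(response, "~", paste(predictors, collapse = " + ")))
  fit <- lm(fml, data = frame)
  est <- coef(fit)
  if (anyNA(est)) {
    abort(paste0("Rank-deficient design; aliased term(s): ",
                 paste(names(est)[is.na(est)], collapse = ", "), "."),
          class = "emospect_collinearity_error")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    se = unname(co[, "Std. Error"]),
    p_value = unname(co[, "Pr(>|t|)"])
  )
  r2 <- sm$r.squared
  adj <- sm$adj.r.squared
  if (var(frame[[response]]) == 0) {
    # constant response: no variance to explain
    r2 <- 0
    adj <- 0
  }
  new_fit(model_id, fit, terms, nrow(frame), reference_levels(frame),
          r_squared = r2, adj_r_squared = adj, subclass = "emospect_ols")
}

#' Linear regression of sentiment on the six emotions
#'
#' Ordinary least squares of the compound sentiment score on the six
#' primary-emotion flags, controlling for drug, age band, duration band and
#' rating year (continuous). Listwise deletion on all model variables.
#'
#' @inheritParams prevalence_table
#' @param sentiments Tibble from [score_corpus()] (`review_id`, `compound`).
#' @return An `emospect_fit` (subclass `emospect_ols`).
#' @export
fit_sentiment_on_emotions <- function(profiles, sentiments, records) {
  d <- join_profiles(profiles, records)
  d <- dplyr::inner_join(
    d, dplyr::mutate(tibble::as_tibble(sentiments),
                     review_id = as.character(.data$review_id)),
    by = "review_id"
  )
  vars <- c("compound", EMOTION_COLS, "drug", "age_band", "duration_band",
            "rating_year")
  frame <- build_model_frame(d, vars)
  if (!nrow(frame)) {
    abort("No complete records for the sentiment model.",
          class = "emospect_input_error")
  }
  fit_ols(frame, "compound",
          c(EMOTION_COLS, "drug", "age_band", "duration_band", "rating_year"),
          "sentiment_on_emotions")
}

#' Nested satisfaction models and the sentiment delta R-squared
#'
#' Fits two nested OLS models of treatment satisfaction (1-5 scale) on the
#' same listwise-complete rows: the full model includes the compound
#' sentiment score plus drug, age band, duration band, and rating year; the
#' reduced model omits sentiment. The increase in (unadjusted) R-squared
#' measures the variance in satisfaction explained by review sentiment over
#' and above patient characteristics; on identical rows it is non-negative
#' by construction. Adjusted R-squared values are also reported.
#'
#' @param records Review tibble with `satisfaction_5` and covariates.
#' @param sentiments Tibble from [score_corpus()].
#' @return An object of class `emospect_delta_r2`: list with `model_with`,
#'   `model_without` (both `emospect_fit`), `r2_with`, `r2_without`,
#'   `delta`, `adj_r2_with`, `adj_r2_without`, `n_used`.
#' @export
fit_satisfaction_models <- function(records, sentiments) {
  d <- dplyr::inner_join(
    dplyr::mutate(tibble::as_tibble(records),
                  review_id = as.character(.data$review_id)),
    dplyr::mutate(tibble::as_tibble(sentiments),
                  review_id = as.character(.data$review_id)),
    by = "review_id"
  )
  vars <- c("satisfaction_5", "compound", "drug", "age_band", "duration_band",
            "rating_year")
  frame <- build_model_frame(d, vars)
  if (!nrow(frame)) {
    abort("No complete records for the satisfaction models.",
          class = "emospect_input_error")
  }
  covs <- c("drug", "age_band", "duration_band", "rating_year")
  m1 <- fit_ols(frame, "satisfaction_5", c("compound", covs), "satisfaction_full")
  m2 <- fit_ols(frame, "satisfaction_5", covs, "satisfaction_reduced")
  structure(
    list(
      model_with = m1, model_without = m2,
      r2_with = m1$r_squared, r2_without = m2$r_squared,
      delta = m1$r_squared - m2$r_squared,
      adj_r2_with = m1$adj_r_squared, adj_r2_without = m2$adj_r_squared,
      n_used = nrow(frame)
    ),
    class = "emospect_delta_r2"
  )
}

#' Increase in R-squared between nested models
#'
#' The arithmetic behind the nested-model comparison: the difference
#' between the R-squared of the model including sentiment and the model
#' excluding it.
#'
#' @param r2_with,r2_without R-squared values of the full and reduced model.
#' @return `r2_with - r2_without`.
#' @examples
#' delta_r2(0.259, 0.06928)
#' @export
delta_r2 <- function(r2_with, r2_without) r2_with - r2_without

#' @export
print.emospect_fit <- function(x, ...) {
  cat("<emospect_fit> ", x$model_id, " (n = ", x$n_used, ")\n", sep = "")
  print(x$terms)
  if (!is.na(x$r_squared)) {
    cat(sprintf("R-squared %.4f (adjusted %.4f)\n", x$r_squared, x$adj_r_squared))
  }
  invisible(x)
}

#' @export
print.emospect_delta_r2 <- function(x, ...) {
  cat("<emospect_delta_r2> n =", x$n_used, "\n")
  cat(sprintf("  R2 with sentiment    %.5f (adjusted %.5f)\n", x$r2_with, x$adj_r2_with))
  cat(sprintf("  R2 without sentiment %.5f (adjusted %.5f)\n", x$r2_without, x$adj_r2_without))
  cat(sprintf("  delta R2             %.5f\n", x$delta))
  invisible(x)
}

#' Tidy an emospect model fit
#'
#' @param x An `emospect_fit` (or `emospect_delta_r2`).
#' @param ... Unused.
#' @return A tibble of per-term coefficients (ORs and Wald CIs for logistic
#'   fits).
#' @export
tidy.emospect_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(model_id = x$model_id), x$terms)
}

#' @export
tidy.emospect_delta_r2 <- function(x, ...) {
  dplyr::bind_rows(tidy(x$model_with), tidy(x$model_without))
}

#' @rdname tidy.emospect_fit
#' @export
glance.emospect_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, n_used = x$n_used,
    r_squared = x$r_squared, adj_r_squared = x$adj_r_squared
  )
}

#' @export
glance.emospect_delta_r2 <- function(x, ...) {
  tibble::tibble(
    n_used = x$n_used, r2_with = x$r2_with, r2_without = x$r2_without,
    delta = x$delta, adj_r2_with = x$adj_r2_with,
    adj_r2_without = x$adj_r2_without
  )
}
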