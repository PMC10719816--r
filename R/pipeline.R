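#' Configuration for a full pipeline run
#'
#' Exactly one of `reviews` (a path or tibble of real review data) or
#' `simulate` (a [generator_config()]) must be supplied. Lexicon arguments
#' accept loaded objects or file paths; the packaged demonstration
#' resources are the defaults.
#'
#' @param reviews Review table (tibble) or path readable by
#'   [read_reviews()], or `NULL` when simulating.
#' @param simulate A [generator_config()], or `NULL` when reading reviews.
#' @param emotion_lexicon An `emotion_lexicon` or a lexicon file path.
#' @param valence_lexicon A `valence_lexicon` or a TSV path (boosters and
#'   negators are then taken from the packaged defaults).
#' @param seed Integer seed for any randomness (simulation).
#' @param alpha Sentiment normalization constant.
#' @param out_dir Optional directory where every intermediate table and the
#'   report are persisted.
#' @param stopwords Stopword list for the annotation cleaning profile.
#' @return A list of class `emospect_run_config`.
#' @export
run_config <- function(reviews = NULL, simulate = NULL,
                       emotion_lexicon = demo_lexicon(),
                       valence_lexicon = default_valence_lexicon(),
                       seed = 1L, alpha = 15, out_dir = NULL,
                       stopwords = emospect_stopwords()) {
  if (is.null(reviews) == is.null(simulate)) {
    abort("Provide exactly one of `reviews` or `simulate`.",
          class = "emospect_config_error")
  }
  if (is.character(emotion_lexicon)) emotion_lexicon <- load_lexicon(emotion_lexicon)
  if (is.character(valence_lexicon)) {
    valence_lexicon <- load_valence_lexicon(
      valence_lexicon,
      system.file("extdata", "boosters.tsv", package = "emospect"),
      system.file("extdata", "negators.txt", package = "emospect")
    )
  }
  structure(
    list(reviews = reviews, simulate = simulate,
         emotion_lexicon = emotion_lexicon, valence_lexicon = valence_lexicon,
         seed = as.integer(seed), alpha = alpha, out_dir = out_dir,
         stopwords = stopwords),
    class = "emospect_run_config"
  )
}

#' Run the full emotion-and-sentiment analysis pipeline
#'
#' Orchestrates ingest (or simulation), preprocessing, deduplication,
#' exclusion of nontextual records, emotion annotation, sentiment scoring,
#' and the complete statistical layer. Duplicates are defined as records
#' sharing (source, normalized cleaned text, drug) — a conservative key
#' that cannot merge distinct patients' different texts; records whose
#' cleaned text is empty are excluded as nontextual. Both exclusions are
#' enumerated in the run log so corpus accounting is mechanically
#' reproducible. The run is deterministic given config + seed.
#'
#' @param config An [run_config()] object.
#' @return An object of class `emospect_report`; see Details.
#' @details The report carries: `corpus_summary` (per-drug characteristic
#'   distribution), `prevalence` (one [prevalence_table()] per stratifier),
#'   `logit_fits` (one logistic fit per emotion; fit errors are recorded,
#'   not fatal), `sentiment_fit`, `satisfaction` (nested models and delta
#'   R-squared), `accounting` (records in/out at each stage), `provenance`
#'   (config hash, lexicon manifest, package version, seed), and `hash`, a
#'   digest over all result tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "emospect_run_config"))
  lex <- config$emotion_lexicon
  vlex <- config$valence_lexicon
  manifest <- validate_lexicon(lex)

  truth <- NULL
  if (!is.null(config$simulate)) {
    corpus <- generate_corpus(config$simulate, lex, vlex, seed = config$seed,
                              alpha = config$alpha)
    records <- corpus$records
    truth <- corpus$truth
  } else {
    records <- if (is.character(config$reviews)) {
      read_reviews(config$reviews)
    } else {
      tibble::as_tibble(config$reviews)
    }
  }
  n_initial <- nrow(records)

  records <- preprocess_reviews(records, stopwords = config$stopwords)

  norm_text <- vapply(records$clean,
                      function(x) paste(x$tokens_annotation, collapse = " "),
                      character(1))
  dedup_key <- paste(as.character(records$source %||% ""), norm_text,
                     as.character(records$drug %||% ""), sep = "\r")
  dup <- duplicated(dedup_key)
  n_dup <- sum(dup)
  if (n_dup) {
    inform(paste0("run_pipeline: excluded ", n_dup, " duplicate record(s)."))
  }
  records <- records[!dup, ]
  norm_text <- norm_text[!dup]

  nontextual <- !nzchar(norm_text)
  n_empty <- sum(nontextual)
  if (n_empty) {
    inform(paste0("run_pipeline: excluded ", n_empty, " nontextual record(s)."))
  }
  excluded_ids <- tibble::tibble(
    review_id = c(records$review_id[nontextual]),
    reason = rep("nontextual", n_empty)
  )
  records <- records[!nontextual, ]

  profiles <- annotate_corpus(records, lex)
  sentiments <- score_corpus(records, vlex, alpha = config$alpha)

  corpus_summary <- summarize_corpus(records)
  prevalence <- list(
    pooled = prevalence_table(profiles, records, NULL),
    drug = prevalence_table(profiles, records, "drug"),
    age_band = prevalence_table(profiles, records, "age_band"),
    duration_band = prevalence_table(profiles, records, "duration_band")
  )
  logit_fits <- lapply(setNames(EMOTION_COLS, EMOTION_COLS), function(e) {
    tryCatch(fit_emotion_logit(profiles, records, e), error = function(err) err)
  })
  sentiment_fit <- tryCatch(
    fit_sentiment_on_emotions(profiles, sentiments, records),
    error = function(err) err
  )
  satisfaction <- tryCatch(
    fit_satisfaction_models(records, sentiments),
    error = function(err) err
  )

  accounting <- tibble::tibble(
    stage = c("input", "after_dedup", "after_nontextual_exclusion"),
    n = c(n_initial, n_initial - n_dup, n_initial - n_dup - n_empty)
  )

  tables <- list(
    corpus_summary = corpus_summary,
    prevalence = lapply(prevalence, function(p) p$rows),
    chi_square = lapply(prevalence, function(p) p$chi_square),
    logit = lapply(logit_fits, function(f) if (inherits(f, "emospect_fit")) f$terms else conditionMessage(f)),
    sentiment = if (inherits(sentiment_fit, "emospect_fit")) sentiment_fit$terms else conditionMessage(sentiment_fit),
    satisfaction = if (inherits(satisfaction, "emospect_delta_r2")) glance(satisfaction) else conditionMessage(satisfaction),
    accounting = accounting
  )

  report <- structure(
    list(
      corpus_summary = corpus_summary,
      prevalence = prevalence,
      logit_fits = logit_fits,
      sentiment_fit = sentiment_fit,
      satisfaction = satisfaction,
      accounting = accounting,
      excluded = excluded_ids,
      records = records[, setdiff(names(records), "clean")],
      profiles = profiles,
      sentiments = sentiments,
      truth = truth,
      provenance = list(
        config_hash = rlang::hash(strip_environments(config)),
        lexicon_manifest = manifest,
        package_version = as.character(utils::packageVersion("emospect")),
        seed = config$seed
      ),
      hash = rlang::hash(tables)
    ),
    class = "emospect_report"
  )
  if (!is.null(config$out_dir)) persist_report(report, config$out_dir)
  report
}

# config carries closures (stopword defaults etc.) whose environments would
# make hashing unstable; hash only the data.
strip_environments <- function(x) {
  if (is.function(x)) return(deparse(x))
  if (is.list(x)) return(lapply(x, strip_environments))
  x
}

#' Summarize corpus characteristics
#'
#' The per-drug distribution table: counts and percentages of age bands,
#' duration bands and rating-year bins, mean (SD) satisfaction on the
#' 1-5 scale, and mean (SD) characters and sentences per review.
#'
#' @param records A banded review tibble (see [preprocess_reviews()]).
#' @return A list of class `emospect_summary` with tibbles `counts` (drug,
#'   characteristic, level, n, pct) and `continuous` (drug, measure, mean,
#'   sd), each including a `total` pseudo-drug column.
#' @export
summarize_corpus <- function(records) {
  d <- tibble::as_tibble(records)
  d$drug <- factor(d$drug, levels = DRUG_LEVELS)
  if (!"n_chars" %in% names(d)) {
    st <- purrr::map_dfr(d$text, text_stats)
    d$n_chars <- st$n_chars
    d$n_sentences <- st$n_sentences
  }
  d$year_bin <- cut(d$rating_year, breaks = c(-Inf, 2009, 2019, Inf),
                    labels = c("2001-2009", "2010-2019", "2020-2022"))
  groups <- list(drug = levels(droplevels(d$drug)), total = "total")

  one_block <- function(sub, drug_label) {
    n_drug <- nrow(sub)
    cat_tbl <- purrr::map_dfr(
      c(age_band = "age_band", duration_band = "duration_band",
        year_bin = "year_bin"),
      function(v) {
        f <- addNA(sub[[v]], ifany = TRUE)
        tab <- table(f)
        tibble::tibble(
          characteristic = v,
          level = ifelse(is.na(names(tab)) | names(tab) == "NA",
                         "missing", names(tab)),
          n = as.integer(tab),
          pct = 100 * as.integer(tab) / n_drug
        )
      }
    )
    cat_tbl$drug <- drug_label
    cont <- tibble::tibble(
      drug = drug_label,
      measure = c("satisfaction_5", "n_chars", "n_sentences"),
      mean = c(mean(sub$satisfaction_5, na.rm = TRUE), mean(sub$n_chars),
               mean(sub$n_sentences)),
      sd = c(sd(sub$satisfaction_5, na.rm = TRUE), sd(sub$n_chars),
             sd(sub$n_sentences)),
      n = n_drug
    )
    list(counts = cat_tbl, continuous = cont)
  }

  blocks <- c(
    lapply(levels(droplevels(factor(d$drug))), function(g) one_block(d[d$drug == g, ], g)),
    list(one_block(d, "total"))
  )
  structure(
    list(
      counts = dplyr::bind_rows(lapply(blocks, `[[`, "counts"))[
        , c("drug", "characteristic", "level", "n", "pct")],
      continuous = dplyr::bind_rows(lapply(blocks, `[[`, "continuous"))
    ),
    class = "emospect_summary"
  )
}

#' @export
print.emospect_summary <- function(x, ...) {
  cat("<emospect_summary>\n")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x$counts, cell = sprintf("%d (%.1f)", .data$n, .data$pct)),
    id_cols = c("characteristic", "level"),
    names_from = "drug", values_from = "cell"
  )
  print(wide, n = 30)
  print(x$continuous, n = 20)
  invisible(x)
}

#' @export
print.emospect_report <- function(x, ...) {
  cat("<emospect_report>\n")
  print(x$accounting)
  cat("\nPooled emotion prevalence (%):\n")
  pooled <- x$prevalence$pooled$rows
  print(setNames(round(pooled$pct, 2), as.character(pooled$emotion)))
  if (inherits(x$satisfaction, "emospect_delta_r2")) {
    cat(sprintf("\nSatisfaction delta R2: %.5f (R2 %.5f -> %.5f, n = %d)\n",
                x$satisfaction$delta, x$satisfaction$r2_without,
                x$satisfaction$r2_with, x$satisfaction$n_used))
  }
  cat("\nreport hash:", x$hash, "\n")
  invisible(x)
}

persist_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(report$records, p("records.csv"), row.names = FALSE)
  utils::write.csv(report$profiles, p("profiles.csv"), row.names = FALSE)
  utils::write.csv(report$sentiments, p("sentiments.csv"), row.names = FALSE)
  for (nm in names(report$prevalence)) {
    utils::write.csv(report$prevalence[[nm]]$rows,
                     p(paste0("prevalence_", nm, ".csv")), row.names = FALSE)
  }
  bundle <- list(
    accounting = report$accounting,
    chi_square = lapply(report$prevalence, function(pv) pv$chi_square),
    logit = lapply(report$logit_fits, function(f) {
      if (inherits(f, "emospect_fit")) f$terms else conditionMessage(f)
    }),
    sentiment = if (inherits(report$sentiment_fit, "emospect_fit")) {
      report$sentiment_fit$terms
    } else conditionMessage(report$sentiment_fit),
    satisfaction = if (inherits(report$satisfaction, "emospect_delta_r2")) {
      glance(report$satisfaction)
    } else conditionMessage(report$satisfaction),
    provenance = list(
      config_hash = report$provenance$config_hash,
      package_version = report$provenance$package_version,
      seed = report$provenance$seed,
      n_subclasses = report$provenance$lexicon_manifest$n_subclasses,
      n_synonyms = report$provenance$lexicon_manifest$n_synonyms
    ),
    hash = report$hash
  )
  jsonlite::write_json(bundle, p("report.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}
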