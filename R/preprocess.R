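#' Text preprocessing for medication reviews
#'
#' Review text passes through one of two cleaning profiles before analysis.
#' The `"annotation"` profile applies the full cleaning stack — URL removal,
#' number removal, lowercasing, stopword removal, and lemmatization — and
#' feeds the emotion annotator. The `"sentiment"` profile removes URLs only,
#' preserving casing, stopwords and word order, because the rule-based
#' sentiment scorer depends on negators ("not") and boosters ("very") that a
#' stopword list would strip.
#'
#' @param text Character scalar, the raw review text (UTF-8).
#' @param stopwords Character vector of stopwords used by the annotation
#'   profile. Defaults to the list packaged with emospect.
#' @return An object of class `emospect_clean`: a list with
#'   `tokens_annotation`, `tokens_sentiment`, `sentences`, `n_chars`,
#'   `n_sentences`.
#' @examples
#' ct <- clean_text("Check https://x.com 100mg GREAT results")
#' ct$tokens_annotation
#' @export
clean_text <- function(text, stopwords = emospect_stopwords()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) text <- ""
  no_url <- strip_urls(text)

  tokens_sent <- tokenize(no_url)

  tok <- tolower(tokens_sent)
  tok <- tok[!grepl("[0-9]", tok)]
  tok <- tok[!tok %in% tolower(stopwords)]
  tok <- lemmatize_tokens(tok)
  tok <- tok[nzchar(tok)]

  sentences <- split_sentences(text)

  structure(
    list(
      tokens_annotation = tok,
      tokens_sentiment = tokens_sent,
      sentences = sentences,
      n_chars = nchar(text),
      n_sentences = length(sentences)
    ),
    class = "emospect_clean"
  )
}

#' @export
print.emospect_clean <- function(x, ...) {
  cat("<emospect_clean> ", x$n_chars, " chars, ", x$n_sentences, " sentences\n",
      "  annotation tokens: ", paste(head(x$tokens_annotation, 12), collapse = " "),
      if (length(x$tokens_annotation) > 12) " ..." else "", "\n", sep = "")
  invisible(x)
}

strip_urls <- function(text) {
  gsub("(https?://\\S+)|(www\\.\\S+)", " ", text, perl = TRUE)
}

# Word tokenizer: runs of letters/digits with internal apostrophes kept
# ("don't" stays one token, so the negator list can include contractions).
tokenize <- function(text) {
  m <- strsplit(text, "[^A-Za-z0-9']+")[[1]]
  m <- gsub("^'+|'+$", "", m)
  m[nzchar(m)]
}

# Irregular forms mapped before the plural rules. Deliberately small: the
# lexicon passes through the same function, so dictionary and text meet in
# one canonical space regardless of linguistic completeness.
LEMMA_EXCEPTIONS <- c(
  felt = "feel", feelings = "feeling", worries = "worry", worried = "worry",
  men = "man", women = "woman", children = "child", teeth = "tooth",
  loved = "love", loving = "love", pleased = "pleased", blues = "blues"
)

#' Lemmatize tokens
#'
#' A light, deterministic lemmatizer shared by the lexicon loader and the
#' annotator: an irregular-form map followed by noun-plural stripping
#' (-ies to -y, -es after sibilants, trailing -s). It is idempotent by
#' construction; verb inflections that matter are carried as explicit
#' lexicon synonyms rather than stripped here.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of the same length.
#' @export
lemmatize_tokens <- function(tokens) {
  if (!length(tokens)) return(character(0))
  out <- tokens
  hit <- out %in% names(LEMMA_EXCEPTIONS)
  out[hit] <- LEMMA_EXCEPTIONS[out[hit]]
  reg <- !hit
  n <- nchar(out)
  ies <- reg & n > 4 & endsWith(out, "ies")
  out[ies] <- paste0(substr(out[ies], 1, n[ies] - 3L), "y")
  es <- reg & !ies & grepl("(ses|xes|zes|ches|shes)$", out)
  out[es] <- substr(out[es], 1, nchar(out[es]) - 2L)
  s <- reg & !ies & !es & n > 3 & endsWith(out, "s") &
    !grepl("(ss|us|is)$", out)
  out[s] <- substr(out[s], 1, nchar(out[s]) - 1L)
  out
}

# Normalize a term (possibly multiword) into canonical matching space:
# lowercase, collapse whitespace, lemmatize each token.
normalize_term <- function(term) {
  toks <- tokenize(tolower(term))
  paste(lemmatize_tokens(toks), collapse = " ")
}

#' Packaged English stopword list
#'
#' The stopword list is versioned inside the package (never fetched at run
#' time) so that cleaning is reproducible. It excludes sentiment-bearing
#' function words ("not", "no") and particles that occur inside multiword
#' emotion terms ("down", as in "let down").
#'
#' @return Character vector of stopwords.
#' @export
emospect_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "emospect")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

# Abbreviations whose trailing period does not end a sentence.
ABBREVIATIONS <- c("mr", "mrs", "ms", "dr", "st", "vs", "etc", "approx",
                   "e.g", "i.e")

#' Split text into sentences
#'
#' Terminal punctuation (`.`, `!`, `?`) followed by whitespace or end of
#' string ends a sentence, except after a guarded abbreviation. Non-empty
#' text without terminal punctuation counts as one sentence.
#'
#' @param text Character scalar.
#' @return Character vector of sentences (length 0 for empty text).
#' @export
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  if (!grepl("[.!?]", text)) return(trimws(text))
  # protect abbreviation periods with a placeholder, split, then restore
  ph <- "\uE000"
  protected <- text
  for (ab in ABBREVIATIONS) {
    protected <- gsub(paste0("(?i)\\b", gsub(".", "\\.", ab, fixed = TRUE), "\\."),
                      paste0(ab, ph), protected, perl = TRUE)
  }
  parts <- strsplit(protected, "(?<=[.!?])\\s+|(?<=[.!?])$", perl = TRUE)[[1]]
  parts <- gsub(ph, ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Character and sentence counts of raw text
#'
#' @param text Character scalar.
#' @return A tibble with `n_chars` and `n_sentences`.
#' @examples
#' text_stats("It worked. I am pleased.")
#' @export
text_stats <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) text <- ""
  tibble::tibble(n_chars = nchar(text), n_sentences = length(split_sentences(text)))
}

# Age patterns, tried in order; first match in [18, 99] wins.
AGE_PATTERNS <- c(
  "\\b([0-9]{2})[ -]*(?:year|yr)s?[ -]*old\\b",
  "\\b([0-9]{2})[ -]*y/?o\\b",
  "\\bage[d]?[ :]+([0-9]{2})\\b",
  "\\bi am (?:a )?([0-9]{2})\\b(?![ -]*(?:mg|mgs|ml|mm|kg|lb|%))"
)

#' Extract a reviewer age from free text
#'
#' Used for sources that carry no structured age field, where reviewers often
#' state their age inside the comment. Matches patterns such as
#' "52 year old", "52 yo", or "age 52", bounded to 18-99; unit-suffixed
#' numbers ("100 mg") never match.
#'
#' @param text Character scalar.
#' @return Integer age, or `NA_integer_` when no pattern matches.
#' @examples
#' extract_age("I am a 52 year old male") # 52
#' extract_age("took 100 mg nightly")     # NA
#' @export
extract_age <- function(text) {
  if (is.na(text) || !nzchar(text)) return(NA_integer_)
  low <- tolower(text)
  for (pat in AGE_PATTERNS) {
    m <- regmatches(low, regexec(pat, low, perl = TRUE))[[1]]
    if (length(m) >= 2L) {
      age <- as.integer(m[2])
      if (!is.na(age) && age >= 18L && age <= 99L) return(age)
    }
  }
  NA_integer_
}

#' Band ages and durations of medication use
#'
#' Ages are banded as `<44` (ages up to and including 44, so the bands
#' partition), `45-64`, and `>=65`. Duration in months is banded as
#' `short` (under 1 month), `mid` (1 month to under 1 year), `long`
#' (1 year or more). Missing input propagates to `NA`.
#'
#' @param age Integer vector of ages (or `NA`).
#' @param months Numeric vector of durations in months (or `NA`).
#' @return Factor vector with the band levels.
#' @examples
#' band_age(c(44, 45, 65, NA))
#' band_duration(c(0.5, 11.9, 12, NA))
#' @export
band_age <- function(age) {
  out <- rep(NA_character_, length(age))
  out[!is.na(age) & age <= 44] <- "<44"
  out[!is.na(age) & age >= 45 & age <= 64] <- "45-64"
  out[!is.na(age) & age >= 65] <- ">=65"
  factor(out, levels = AGE_LEVELS)
}

#' @rdname band_age
#' @export
band_duration <- function(months) {
  if (any(months < 0, na.rm = TRUE)) {
    abort("`months` must be non-negative.", class = "emospect_input_error")
  }
  out <- rep(NA_character_, length(months))
  out[!is.na(months) & months < 1] <- "short"
  out[!is.na(months) & months >= 1 & months < 12] <- "mid"
  out[!is.na(months) & months >= 12] <- "long"
  factor(out, levels = DURATION_LEVELS)
}

#' Preprocess a review table
#'
#' Data-frame-first wrapper over [clean_text()], [band_age()] and
#' [band_duration()]: takes the standard review table and returns it with
#' banded covariates, text statistics, and a list-column of cleaned text.
#'
#' @param reviews A tibble with at least `review_id` and `text`; optional
#'   `age`, `duration_months`, `satisfaction_raw`, `satisfaction_scale`.
#' @inheritParams clean_text
#' @return The input tibble with added columns `age_band`, `duration_band`,
#'   `satisfaction_5`, `n_chars`, `n_sentences`, and list-column `clean`.
#' @export
preprocess_reviews <- function(reviews, stopwords = emospect_stopwords()) {
  stopifnot(is.data.frame(reviews), all(c("review_id", "text") %in% names(reviews)))
  out <- tibble::as_tibble(reviews)
  if (!"age" %in% names(out) && !"age_band" %in% names(out)) {
    out$age <- vapply(out$text, extract_age, integer(1))
  }
  out$clean <- lapply(out$text, clean_text, stopwords = stopwords)
  out$n_chars <- vapply(out$clean, function(x) x$n_chars, integer(1))
  out$n_sentences <- vapply(out$clean, function(x) x$n_sentences, integer(1))
  if (!"age_band" %in% names(out)) out$age_band <- band_age(out$age)
  if (!"duration_band" %in% names(out) && "duration_months" %in% names(out)) {
    out$duration_band <- band_duration(out$duration_months)
  }
  if (all(c("satisfaction_raw", "satisfaction_scale") %in% names(out)) &&
      !"satisfaction_5" %in% names(out)) {
    out$satisfaction_5 <- standardize_satisfaction(out$satisfaction_raw,
                                                   out$satisfaction_scale)
  }
  out
}
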