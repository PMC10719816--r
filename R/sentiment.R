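#' Load a valence lexicon for rule-based sentiment scoring
#'
#' The valence lexicon has three parts: a term-to-valence map (TSV:
#' `term`, `valence`), a booster map of degree modifiers (TSV: `term`,
#' `increment`), and a newline-separated list of negators that flip
#' polarity. Validation requires finite valences and a negator set disjoint
#' from the valence terms.
#'
#' @param valence_path,booster_path,negator_path File paths; `#` lines are
#'   comments.
#' @return An object of class `valence_lexicon`: list with `valence` (named
#'   numeric), `boosters` (named numeric), `negators` (character).
#' @export
load_valence_lexicon <- function(valence_path, booster_path = NULL,
                                 negator_path = NULL) {
  read_pairs <- function(path) {
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    setNames(as.numeric(df[[2]]), tolower(trimws(df[[1]])))
  }
  valence <- read_pairs(valence_path)
  boosters <- if (is.null(booster_path)) numeric(0) else read_pairs(booster_path)
  negators <- if (is.null(negator_path)) character(0) else {
    ln <- readLines(negator_path, warn = FALSE)
    tolower(trimws(ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]))
  }
  if (any(!is.finite(valence))) {
    abort("Valence lexicon contains non-finite values.",
          class = "emospect_schema_error")
  }
  clash <- intersect(negators, names(valence))
  if (length(clash)) {
    abort(paste0("Negator set overlaps valence terms: ",
                 paste(clash, collapse = ", "), "."),
          class = "emospect_schema_error")
  }
  structure(list(valence = valence, boosters = boosters, negators = negators),
            class = "valence_lexicon")
}

#' The mini valence lexicon shipped with emospect
#'
#' A compact, package-versioned valence resource (about 270 terms, with
#' boosters and negators) so sentiment scoring is testable without any
#' download. A full-size external lexicon can be loaded by path with
#' [load_valence_lexicon()].
#'
#' @return A `valence_lexicon`.
#' @export
default_valence_lexicon <- function() {
  ext <- function(f) system.file("extdata", f, package = "emospect")
  load_valence_lexicon(ext("valence_lexicon.tsv"), ext("boosters.tsv"),
                       ext("negators.txt"))
}

#' @export
print.valence_lexicon <- function(x, ...) {
  cat("<valence_lexicon> ", length(x$valence), " terms, ",
      length(x$boosters), " boosters, ", length(x$negators), " negators\n",
      sep = "")
  invisible(x)
}

#' Rule-based compound sentiment score
#'
#' Scores the lightly cleaned (sentiment-profile) token stream of a review.
#' Each token found in the valence lexicon contributes its valence,
#' adjusted by the increment of an immediately preceding booster
#' (sign-aligned with the valence) and sign-flipped when a negator occurs
#' within the three preceding tokens. The raw valence sum `s` is mapped to
#' the bounded compound score `s / sqrt(s^2 + alpha)`, which lies strictly
#' inside (-1, 1), is antisymmetric, and increases monotonically in `s`.
#' Punctuation and capitalization emphasis are deliberately not modeled.
#'
#' @param clean An `emospect_clean` object (or a character vector of raw
#'   tokens in original order).
#' @param vlex A `valence_lexicon`.
#' @param alpha Positive normalization constant (default 15).
#' @return A one-row tibble: `compound`, `raw_sum`.
#' @examples
#' vlex <- default_valence_lexicon()
#' score_text(clean_text("the results were really good"), vlex)
#' score_text(clean_text("the results were not good"), vlex)
#' @export
score_text <- function(clean, vlex, alpha = 15) {
  stopifnot(inherits(vlex, "valence_lexicon"), alpha > 0)
  tokens <- if (inherits(clean, "emospect_clean")) clean$tokens_sentiment else clean
  raw <- raw_valence_sum(tolower(tokens), vlex)
  tibble::tibble(compound = raw / sqrt(raw^2 + alpha), raw_sum = raw)
}

# raw valence sum over lowercase tokens: booster at distance 1, negator
# window of 3 preceding tokens flips sign
raw_valence_sum <- function(tokens, vlex) {
  n <- length(tokens)
  if (!n) return(0)
  vals <- unname(vlex$valence[tokens])
  scored <- which(!is.na(vals) & vals != 0)
  if (!length(scored)) return(0)
  is_neg <- tokens %in% vlex$negators
  raw <- 0
  for (i in scored) {
    v <- vals[i]
    if (i > 1L) {
      b <- vlex$boosters[tokens[i - 1L]]
      if (!is.na(b)) v <- v + sign(v) * unname(b)
      if (any(is_neg[max(1L, i - 3L):(i - 1L)])) v <- -v
    }
    raw <- raw + v
  }
  raw
}

#' Score a review corpus
#'
#' Batch driver over [score_text()]; order-preserving and deterministic.
#' An `adapter` function can replace the native scorer (for example to call
#' an external sentiment tool); it receives the raw review text and must
#' return a single compound score in `[-1, 1]`.
#'
#' @inheritParams annotate_corpus
#' @param vlex A `valence_lexicon`.
#' @param alpha Normalization constant passed to [score_text()].
#' @param adapter Optional `function(text) -> numeric(1)` overriding the
#'   native scorer.
#' @return A tibble: `review_id`, `compound`, `raw_sum` (`raw_sum` is `NA`
#'   under an adapter).
#' @export
score_corpus <- function(reviews, vlex = default_valence_lexicon(), alpha = 15,
                         adapter = NULL, stopwords = emospect_stopwords()) {
  stopifnot(is.data.frame(reviews))
  if (!nrow(reviews)) {
    return(tibble::tibble(review_id = character(0), compound = numeric(0),
                          raw_sum = numeric(0)))
  }
  if (!is.null(adapter)) {
    comp <- vapply(reviews$text, function(tx) as.numeric(adapter(tx)), numeric(1))
    return(tibble::tibble(review_id = as.character(reviews$review_id),
                          compound = unname(comp), raw_sum = NA_real_))
  }
  cleans <- if ("clean" %in% names(reviews)) {
    reviews$clean
  } else {
    lapply(reviews$text, clean_text, stopwords = stopwords)
  }
  raw <- vapply(cleans, function(x) {
    raw_valence_sum(tolower(x$tokens_sentiment), vlex)
  }, numeric(1))
  tibble::tibble(review_id = as.character(reviews$review_id),
                 compound = raw / sqrt(raw^2 + alpha), raw_sum = raw)
}
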