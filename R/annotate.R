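#' Gazetteer annotation of emotion terms
#'
#' Matches lexicon terms (including multiword synonyms) against the
#' annotation-profile token stream of a cleaned review. Candidate matches
#' are resolved to a set of non-overlapping spans by the standard gazetteer
#' convention: longer spans win, ties broken leftmost-first. Matching is
#' purely lexical — no negation or modality handling, so "not happy" still
#' annotates joy; this mirrors dictionary-lookup pipelines and is a
#' documented limitation.
#'
#' @param clean An `emospect_clean` object (or a character vector of
#'   already-normalized tokens).
#' @param lex A validated `emotion_lexicon`.
#' @return A tibble with one row per annotation: `span_start`, `span_end`
#'   (0-based, half-open token indices), `matched_term`, `tertiary`,
#'   `secondary`, `primary`.
#' @examples
#' lex <- demo_lexicon()
#' annotate_text(clean_text("what a delight, but I felt let down"), lex)
#' @export
annotate_text <- function(clean, lex) {
  stopifnot(inherits(lex, "emotion_lexicon"))
  tokens <- if (inherits(clean, "emospect_clean")) clean$tokens_annotation else clean
  nt <- length(tokens)
  if (!nt) return(EMPTY_ANNOTATION)
  idx <- lex$term_index
  max_len <- min(max(idx$n_tokens), nt)

  # enumerate candidate matches per n-gram length (plain vectors for speed)
  c_start <- integer(0); c_len <- integer(0); c_row <- integer(0)
  for (n in seq_len(max_len)) {
    in_len <- which(idx$n_tokens == n)
    if (!length(in_len) || nt < n) next
    grams <- if (n == 1L) {
      tokens
    } else {
      starts <- seq_len(nt - n + 1L)
      g <- tokens[starts]
      for (k in seq_len(n - 1L)) g <- paste(g, tokens[starts + k])
      g
    }
    hit <- match(grams, idx$term[in_len])
    pos <- which(!is.na(hit))
    if (length(pos)) {
      c_start <- c(c_start, pos)
      c_len <- c(c_len, rep.int(n, length(pos)))
      c_row <- c(c_row, in_len[hit[pos]])
    }
  }
  if (!length(c_start)) return(EMPTY_ANNOTATION)

  # longest span first, leftmost on ties; accept non-overlapping
  ord <- order(-c_len, c_start)
  occupied <- logical(nt)
  keep <- logical(length(ord))
  for (i in ord) {
    span <- c_start[i]:(c_start[i] + c_len[i] - 1L)
    if (!any(occupied[span])) {
      occupied[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  sel <- which(keep)
  sel <- sel[order(c_start[sel])]
  tibble::new_tibble(
    list(
      span_start = c_start[sel] - 1L,
      span_end = c_start[sel] - 1L + c_len[sel],
      matched_term = idx$term[c_row[sel]],
      tertiary = idx$tertiary[c_row[sel]],
      secondary = idx$secondary[c_row[sel]],
      primary = idx$primary[c_row[sel]]
    ),
    nrow = length(sel)
  )
}

EMPTY_ANNOTATION <- tibble::new_tibble(
  list(
    span_start = integer(0), span_end = integer(0),
    matched_term = character(0), tertiary = character(0),
    secondary = character(0), primary = character(0)
  ),
  nrow = 0L
)

#' Aggregate annotations into a primary-emotion profile
#'
#' Reduces a review's annotations to the six-dimensional profile used by all
#' downstream statistics: one binary flag per primary emotion (present at
#' least once) plus per-primary match counts. Emotions are non-exclusive; a
#' review can raise several flags.
#'
#' @param annotations A tibble as returned by [annotate_text()].
#' @param review_id The review identifier the annotations belong to. If the
#'   annotations carry a `review_id` column it must be constant and equal.
#' @return A one-row tibble: `review_id`, flag columns `joy`, `love`,
#'   `surprise`, `sadness`, `fear`, `anger` (0/1 integers), and count
#'   columns `n_joy`, ..., `n_anger`.
#' @export
profile_annotations <- function(annotations, review_id) {
  if ("review_id" %in% names(annotations) && nrow(annotations)) {
    ids <- unique(annotations$review_id)
    if (length(ids) > 1L || !identical(ids, review_id)) {
      abort("Annotations carry mixed or mismatching review_ids.",
            class = "emospect_input_error")
    }
  }
  counts <- vapply(EMOTION_COLS, function(e) {
    sum(annotations$primary == e)
  }, integer(1))
  flags <- as.integer(counts >= 1L)
  out <- tibble::tibble(review_id = review_id)
  out[EMOTION_COLS] <- as.list(flags)
  out[paste0("n_", EMOTION_COLS)] <- as.list(counts)
  out
}

#' Annotate a review corpus into emotion profiles
#'
#' Batch driver: cleans, annotates and profiles each review in order.
#' Records whose text is empty after cleaning carry no lexical signal and
#' are skipped; skipped records are reported via a message and the
#' `"excluded"` attribute of the result, never silently dropped.
#'
#' @param reviews A review tibble with `review_id` and `text` columns, or an
#'   already-preprocessed table carrying a `clean` list-column.
#' @param lex A validated `emotion_lexicon`.
#' @param stopwords Stopword list for cleaning (ignored if `reviews` already
#'   carries a `clean` column).
#' @return A tibble of emotion profiles (one row per non-skipped review),
#'   with attribute `excluded`: a tibble of `review_id`, `reason`.
#' @export
annotate_corpus <- function(reviews, lex, stopwords = emospect_stopwords()) {
  stopifnot(is.data.frame(reviews))
  if (!nrow(reviews)) {
    out <- profile_annotations(annotate_text(character(0), lex), character(0))[0, ]
    attr(out, "excluded") <- tibble::tibble(review_id = character(0),
                                            reason = character(0))
    return(out)
  }
  cleans <- if ("clean" %in% names(reviews)) {
    reviews$clean
  } else {
    lapply(reviews$text, clean_text, stopwords = stopwords)
  }
  empty <- vapply(cleans, function(x) length(x$tokens_annotation) == 0L, logical(1))
  excluded <- tibble::tibble(
    review_id = as.character(reviews$review_id[empty]),
    reason = "empty text after cleaning"
  )
  if (nrow(excluded)) {
    inform(paste0("annotate_corpus: skipped ", nrow(excluded),
                  " record(s) with empty cleaned text."))
  }
  kept <- which(!empty)
  counts <- matrix(0L, nrow = length(kept), ncol = 6L,
                   dimnames = list(NULL, EMOTION_COLS))
  for (j in seq_along(kept)) {
    ann <- annotate_text(cleans[[kept[j]]], lex)
    if (nrow(ann)) {
      counts[j, ] <- tabulate(match(ann$primary, EMOTION_COLS), nbins = 6L)
    }
  }
  profiles <- tibble::tibble(review_id = as.character(reviews$review_id[kept]))
  for (e in EMOTION_COLS) profiles[[e]] <- as.integer(counts[, e] >= 1L)
  for (e in EMOTION_COLS) profiles[[paste0("n_", e)]] <- counts[, e]
  attr(profiles, "excluded") <- excluded
  profiles
}
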