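# Independent oracles and fixture builders shared across the test files.

# Brute-force gazetteer oracle: enumerate every token n-gram (n up to the
# longest lexicon term), keep all lexicon hits, then resolve overlaps by
# (longer span first, then leftmost). Deliberately naive and independent of
# the package's matcher.
oracle_annotate <- function(tokens, lex) {
  idx <- lex$term_index
  max_len <- max(idx$n_tokens)
  hits <- list()
  for (start in seq_along(tokens)) {
    for (len in seq_len(min(max_len, length(tokens) - start + 1L))) {
      gram <- paste(tokens[start:(start + len - 1L)], collapse = " ")
      row <- which(idx$term == gram)
      if (length(row) == 1L) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = start, len = len, term = gram,
          primary = idx$primary[row], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), len = integer(0),
                      term = character(0), primary = character(0)))
  }
  hits <- do.call(rbind, hits)
  hits <- hits[order(-hits$len, hits$start), , drop = FALSE]
  taken <- logical(length(tokens))
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    span <- hits$start[i]:(hits$start[i] + hits$len[i] - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# Textbook chi-square oracle: sum((O - E)^2 / E) with E from the margins.
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - e)^2 / e),
       df = (nrow(tab) - 1L) * (ncol(tab) - 1L))
}

# Random small lexicon for property tests: invented letter-strings (no
# trailing 's' so lemmatization is the identity), some multiword.
random_test_lexicon <- function(n_terms = 30, p_multi = 0.25) {
  word <- function() {
    paste0(paste(sample(letters[1:20], sample(4:7, 1), TRUE), collapse = ""), "o")
  }
  prim <- emospect:::PRIMARY_EMOTIONS
  classes <- tibble::tibble(
    label = prim, tier = "primary", parent = NA_character_,
    synonyms = replicate(6, character(0), simplify = FALSE)
  )
  secs <- paste0("sec_", prim)
  classes <- rbind(classes, tibble::tibble(
    label = secs, tier = "secondary", parent = prim,
    synonyms = replicate(6, character(0), simplify = FALSE)
  ))
  terms <- character(0)
  syn_lists <- replicate(6, character(0), simplify = FALSE)
  while (length(terms) < n_terms) {
    t <- if (stats::runif(1) < p_multi) paste(word(), word()) else word()
    if (t %in% terms) next
    terms <- c(terms, t)
    k <- sample(6, 1)
    syn_lists[[k]] <- c(syn_lists[[k]], t)
  }
  classes$synonyms[seq(7, 12)] <- syn_lists
  lex <- emospect:::build_lexicon(classes)
  validate_lexicon(lex)
  lex
}

# Minimal lexicon written to a temp file, for loader tests.
write_test_lexicon <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("label\ttier\tparent\tsynonyms", lines), path)
  path
}

# Review/profile pair with prescribed joy flags, for prevalence arithmetic.
flags_corpus <- function(k, n, emotion = "joy") {
  ids <- sprintf("r%05d", seq_len(n))
  profiles <- tibble::tibble(review_id = ids)
  for (e in c("joy", "love", "surprise", "sadness", "fear", "anger")) {
    profiles[[e]] <- 0L
  }
  profiles[[emotion]] <- as.integer(seq_len(n) <= k)
  records <- tibble::tibble(
    review_id = ids,
    drug = factor("sildenafil", levels = c("sildenafil", "vardenafil", "tadalafil"))
  )
  list(profiles = profiles, records = records)
}

# Records + profiles realizing prescribed 2x2 counts (outcome x binary drug
# covariate), for the closed-form odds-ratio identity.
logit_2x2_data <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  drug <- c(rep("sildenafil", a + c_), rep("tadalafil", b + d))
  flag <- c(rep(1L, a), rep(0L, c_), rep(1L, b), rep(0L, d))
  ids <- sprintf("r%05d", seq_len(n))
  profiles <- tibble::tibble(review_id = ids, joy = flag, love = 0L,
                             surprise = 0L, sadness = 0L, fear = 0L, anger = 0L)
  records <- tibble::tibble(
    review_id = ids,
    drug = factor(drug, levels = c("sildenafil", "vardenafil", "tadalafil"))
  )
  list(profiles = profiles, records = records)
}
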