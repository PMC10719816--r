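lex <- demo_lexicon()

test_that("out-of-lexicon tokens produce no annotations", {
  expect_identical(nrow(annotate_text(c("tablet", "dissolve", "quickly"), lex)), 0L)
  expect_identical(nrow(annotate_text(character(0), lex)), 0L)
})

test_that("single-term match carries its full class lineage", {
  ann <- annotate_text(c("what", "delight"), lex)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$matched_term, "delight")
  expect_identical(ann$tertiary, "delight")
  expect_identical(ann$secondary, "cheerfulness")
  expect_identical(ann$primary, "joy")
  expect_identical(ann$span_start, 1L)
  expect_identical(ann$span_end, 2L)
})

test_that("longest match wins over an overlapping shorter match", {
  # "down" (gloom) and "let down" (disappointment) both available
  ann <- annotate_text(c("feel", "let", "down"), lex)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$matched_term, "let down")
  expect_identical(ann$span_start, 1L)
  expect_identical(ann$span_end, 3L)
  expect_identical(ann$secondary, "disappointment")
  # bare "down" still matches when not covered by the longer term
  ann2 <- annotate_text(c("feeling", "down"), lex)
  expect_identical(ann2$matched_term, "down")
  expect_identical(ann2$secondary, "gloom")
})

test_that("matched spans never overlap", {
  ann <- annotate_text(c("let", "down", "down", "heartbroken", "happy"), lex)
  expect_true(all(ann$span_start[-1] >= head(ann$span_end, -1)))
  expect_identical(ann$matched_term, c("let down", "down", "heartbroken", "happy"))
})

test_that("annotator equals the brute-force oracle on randomized corpora", {
  set.seed(42)
  for (rep in 1:25) {
    rlex <- random_test_lexicon(n_terms = sample(10:40, 1))
    vocab <- c(rlex$term_index$term,
               unlist(strsplit(rlex$term_index$term, " ")),
               replicate(10, paste(sample(letters, 5), collapse = "")))
    tokens <- sample(vocab, sample(5:60, 1), replace = TRUE)
    tokens <- unlist(strsplit(tokens, " "))
    got <- annotate_text(tokens, rlex)
    want <- oracle_annotate(tokens, rlex)
    expect_identical(got$span_start, want$start - 1L)
    expect_identical(got$span_end - got$span_start, want$len)
    expect_identical(got$matched_term, want$term)
    expect_identical(got$primary, want$primary)
  }
})

test_that("adding a non-overlapping synonym never removes annotations", {
  set.seed(7)
  for (rep in 1:5) {
    rlex <- random_test_lexicon(n_terms = 15)
    tokens <- sample(c(rlex$term_index$term, "zzfiller", "qqfiller"),
                     30, replace = TRUE)
    tokens <- unlist(strsplit(tokens, " "))
    before <- annotate_text(tokens, rlex)
    classes <- rlex$classes
    classes$synonyms[[7]] <- c(classes$synonyms[[7]], "zznewsyno")
    rlex2 <- emospect:::build_lexicon(classes)
    after <- annotate_text(tokens, rlex2)
    # "zznewsyno" never occurs in the text, so annotations are unchanged
    expect_identical(after, before)
  }
})

test_that("profiles flag presence, count matches, and reject mixed ids", {
  ann <- annotate_text(c("happy", "delighted", "heartbroken"), lex)
  prof <- profile_annotations(ann, "r1")
  expect_identical(prof$joy, 1L)
  expect_identical(prof$n_joy, 2L)
  expect_identical(prof$sadness, 1L)
  expect_identical(prof$love + prof$surprise + prof$fear + prof$anger, 0L)

  empty_prof <- profile_annotations(annotate_text(character(0), lex), "r2")
  expect_identical(sum(empty_prof$joy, empty_prof$love, empty_prof$surprise,
                       empty_prof$sadness, empty_prof$fear, empty_prof$anger), 0L)

  all6 <- annotate_text(c("happy", "adore", "amazed", "sad", "scared", "angry"), lex)
  prof6 <- profile_annotations(all6, "r3")
  expect_identical(unlist(prof6[c("joy", "love", "surprise", "sadness",
                                  "fear", "anger")], use.names = FALSE),
                   rep(1L, 6))

  bad <- annotate_text(c("happy"), lex)
  bad$review_id <- "other"
  expect_error(profile_annotations(bad, "r4"), class = "emospect_input_error")
})

test_that("profile flags are invariant under term duplication", {
  once <- profile_annotations(annotate_text(c("happy"), lex), "r")
  thrice <- profile_annotations(annotate_text(rep("happy", 3), lex), "r")
  expect_identical(once$joy, thrice$joy)
  expect_identical(thrice$n_joy, 3L)
})

test_that("corpus annotation skips empty-text records and keeps order", {
  reviews <- tibble::tibble(
    review_id = sprintf("r%02d", 1:10),
    text = c("happy pill", "", "let down badly", "100 50", "fine tablet",
             "heartbroken", "nothing notable", "angry and scared", "", "delight")
  )
  expect_message(
    profiles <- annotate_corpus(reviews, lex),
    "skipped 3"
  )
  # records 2 and 9 are empty; record 4 is digits only (empty after cleaning)
  expect_identical(nrow(profiles), 7L)
  excl <- attr(profiles, "excluded")
  expect_setequal(excl$review_id, c("r02", "r04", "r09"))
  expect_identical(profiles$review_id,
                   setdiff(reviews$review_id, excl$review_id))
  expect_identical(profiles$joy[profiles$review_id == "r01"], 1L)
  expect_identical(profiles$sadness[profiles$review_id == "r03"], 1L)

  empty <- annotate_corpus(reviews[0, ], lex)
  expect_identical(nrow(empty), 0L)
})
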