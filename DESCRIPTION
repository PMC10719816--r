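Package: emospect
Title: Ontology-Based Emotion and Sentiment Analysis of Patient Medication Reviews
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lexicon-driven pipeline for mining patient medication reviews:
    a three-tier (primary/secondary/tertiary) emotion lexicon in the Parrot
    taxonomy, a gazetteer annotator that reduces each review to a
    six-dimensional primary-emotion profile, a rule-based compound sentiment
    scorer bounded in [-1, 1], and the stratified prevalence, logistic
    odds-ratio, and nested linear-regression analyses that link emotions to
    sentiment and sentiment to treatment satisfaction. Includes a synthetic
    review-corpus generator with planted ground truth so every stage of the
    pipeline can be validated without access to scraped social-media data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
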