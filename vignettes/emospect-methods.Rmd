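---
title: "emospect: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{emospect: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

emospect turns free-text patient medication reviews into three linked
statistical analyses: stratified emotion prevalence, emotion-to-sentiment
regression, and sentiment-to-satisfaction nested models. This vignette
documents the underlying models, every tunable that matters, the design
decisions taken where the methodology was genuinely open, and what the
synthetic test bed does and does not demonstrate.

## The emotion lexicon and annotator

The lexicon is a 3-tier taxonomy in the Parrot tradition: exactly six
primary emotions (*surprise, anger, love, joy, sadness, fear*), secondary
classes below them, tertiary classes below those, and synonym lists
(possibly multiword) attached to any class. It is serialized as flat
tab-separated text (`label`, `tier`, `parent`, `synonyms`) rather than an
ontology format: the pipeline consumes only the tree and the surface
forms, and a flat schema makes the resource diffable and versionable. The
file header may declare its own subclass and synonym counts; the manifest
returned by `validate_lexicon()` recomputes both so any lexicon can verify
itself.

Three structural rules are enforced at load time and are hard errors, not
warnings:

* the primary tier is exactly the six fixed labels;
* every secondary class has one primary parent, every tertiary class one
  secondary parent (a tree — a term reaches its primary in at most two
  hops);
* no surface form may map to two classes after normalization. There is no
  principled disambiguation rule for a gazetteer, so ambiguity fails
  loudly rather than resolving silently; determinism is worth more than
  lexicon convenience.

Annotation is dictionary lookup over the cleaned token stream: all n-gram
candidates are collected and overlaps are resolved by the standard
gazetteer convention — **longest span wins, ties go to the leftmost
span**. So in "feel let down", the bigram "let down" (disappointment)
suppresses the unigram "down" (gloom). A review's *emotion profile* is
binary presence per primary emotion (match counts are kept but do not feed
the statistics): prevalence analyses are about the share of reviews
expressing an emotion, and presence is invariant to verbosity. Emotions
are non-exclusive; a review can raise several flags.

Deliberately, the annotator has **no negation or modality handling**:
"not happy" still flags *joy*. Dictionary annotators of this kind have no
negation stage, and adding one would change the construct being measured.
The sentiment scorer, which does model negation, is the component that
distinguishes the two phrases.

## Text cleaning: two profiles

Cleaning is split into two profiles because its two consumers have
incompatible needs:

* **annotation profile** — URLs removed, digit-bearing tokens removed,
  lowercased, stopwords removed, lemmatized. This is the stream the
  gazetteer matches against.
* **sentiment profile** — URLs removed, nothing else. Negators ("not",
  "don't") and degree boosters ("very") are exactly the words a stopword
  list would destroy, and the scorer needs token order intact.

The stopword list ships inside the package and is versioned with it; it
deliberately excludes polarity-bearing function words and particles that
occur inside multiword emotion terms ("down").

The lemmatizer is a small deterministic rule system: an irregular-form map
followed by noun-plural stripping (-ies to -y, -es after sibilants,
trailing -s with guards). It is applied identically to lexicon entries and
review text, so both sides meet in one canonical space — which is the only
property the pipeline needs from it. It is idempotent by construction
(cleaning its own output changes nothing), which is why -ed/-ing stripping
is omitted: those rules cannot be made idempotent without a dictionary,
and verb inflections that matter are instead carried as explicit lexicon
synonyms. A spell-check hook can be inserted before cleaning but is off by
default: third-party spellers drift across versions and would make runs
irreproducible.

Sentence splitting uses terminal punctuation with an abbreviation guard
("Dr.", "e.g."); a non-empty text without terminal punctuation is one
sentence. Ages are recovered from the comment body (for sources without a
structured age field) by a bounded pattern set — "52 year old", "52 yo",
"age 52" — restricted to 18–99 so dosages ("100 mg") can never match. Age
bands follow the convention `<44` / `45-64` / `>=65`; the first band is
inclusive of 44 so the bands partition all adult ages. Durations band as
short (<1 month), mid (1 month to <1 year), long (>=1 year).

## Sentiment scoring

The scorer is a compact rule-based model in the VADER family, reimplemented
natively so that it is small, deterministic and fully testable:

* each token found in the valence lexicon contributes its valence
  (authored scale −4…+4);
* a booster immediately before a scored token adds its increment,
  sign-aligned ("very good" > "good"; "slightly good" < "good");
* a negator within the three preceding tokens flips the sign — a pure
  polarity flip, so "not good" and "good" have equal magnitude;
* the raw sum `s` is normalized to `s / sqrt(s² + alpha)` with
  `alpha = 15`, giving a compound score strictly inside (−1, 1),
  antisymmetric and monotone in `s`.

Punctuation emphasis, capitalization emphasis and contrastive-conjunction
reweighting are deliberately **not** modeled; they would add little to
corpus-level statistics while complicating the contract. An `adapter`
argument on `score_corpus()` lets any external scorer (e.g. the original
tool) replace the native one for full-fidelity runs. `alpha` is exposed in
the configuration but fixed at 15 by default, matching the published
normalization constant of the tool family.

The packaged valence lexicon (~270 terms plus boosters and negators) is a
self-contained resource authored for this package so tests never download
anything; a full-size external lexicon can be loaded by path.

## The statistical layer

All fits go through `stats::glm`/`stats::lm`; the package's contribution
is the surrounding contracts.

* **Prevalence** (`prevalence_table()`): within each stratifier level,
  percent of reviews with the flag set and binomial standard error
  `sqrt(p(1-p)/n)`. One chi-square statistic per stratifier is computed on
  the level-by-emotion mention-count table (no continuity correction),
  reproducing the one-p-value-per-characteristic layout customary in this
  literature; because the six outcomes are non-exclusive, that table is
  not a true contingency table, so the statistically cleaner per-emotion
  presence-by-level chi-squares are always emitted alongside. Empty levels
  are dropped with a warning; an all-zero table is an error.
* **Logistic models** (`fit_emotion_logit()`): flag ~ drug + age band +
  duration band, reference levels sildenafil / 65+ / short-term, odds
  ratios with Wald 95% CIs using z = 1.959964. No small-sample correction
  and no multiplicity adjustment, matching standard reporting in the
  field. Complete or quasi-complete separation is detected (non-converged
  fit or runaway coefficient) and raised as a typed error naming the
  offending term.
* **Sentiment model** (`fit_sentiment_on_emotions()`): OLS of the
  compound score on the six flags plus drug, age band, duration band and
  rating year. Rating year enters as a continuous covariate (a single
  slope). A rank-deficient design raises a collinearity error naming the
  aliased columns. A constant response is reported as R² = 0.
* **Satisfaction models** (`fit_satisfaction_models()`): satisfaction on
  the 1–5 scale (10-point ratings converted by `ceiling(raw/2)`, which
  preserves integer Likert levels and both endpoints) regressed on
  sentiment plus covariates, and on covariates alone, **on identical
  listwise-complete rows** — nesting on the same rows is what makes the
  unadjusted ΔR² non-negative by construction. Both unadjusted and
  adjusted R² are reported, since published tables are not always explicit
  about which is shown.

Missing data policy is listwise deletion per model throughout: the
simplest policy consistent with analysis ns that shrink relative to the
corpus.

## The synthetic corpus generator

`generate_corpus()` exists because the motivating corpora are scraped and
not redistributable. It emulates the *statistical* structure of such data:

* strata (drug, age band, duration band, rating year, source site)
  sampled from configured weights; the defaults echo a realistic corpus
  shape — drug mix 973/406/1691, roughly 18/41/12/30% age bands
  (with missing), 33/22/22/24% duration bands, reviews concentrated in
  2010–2019, satisfaction scales 1–5 or 1–10 by source;
* per-review emotion flags drawn from per-stratum logistic models. The
  intercepts are reference-stratum log-odds and the effects are planted
  log odds ratios; the defaults use effect sizes characteristic of this
  literature (e.g. a sadness odds ratio near 4 for tadalafil versus
  sildenafil, elevated joy for long-term users). Because most planted
  effects are positive relative to the reference stratum, pooled marginal
  prevalences sit a few points above the reference values — the defaults
  are fixed study conditions, chosen once, not calibration targets;
* text assembled as a token bag: neutral filler (validated disjoint from
  every lexicon resource, including after lemmatization), at least one
  term from each active emotion's branch of the lexicon, and calibration
  valence words chosen greedily so the summed valence hits the sentiment
  model's target for that review (valence already carried by the planted
  emotion terms is accounted for first). The steering residual is bounded
  by half the smallest calibration magnitude (0.125 on the raw-valence
  scale);
* satisfaction drawn from a linear model on the realized compound score
  (default slope 0.97) plus covariate effects and Gaussian noise
  (sd 0.65, chosen from the variance decomposition so that the planted
  ΔR² lands in the 0.15–0.20 range after Likert discretization), then
  rounded and clamped to the source's scale;
* missingness applied last, at the observation level (the latent values
  still drive generation), at rates 0.296 / 0.237 / 0.04 for age,
  duration and satisfaction.

One seed drives the stratum draws; per-review substreams derived from it
drive text assembly, so generation is reproducible independent of
evaluation order. Two guarantees are the point of the design: the
annotator recovers the planted flags **exactly** (filler-disjointness),
and the scorer reproduces the realized compound **exactly** (the
generator computes it with the scoring rules themselves).

What the generator does *not* emulate: fluent prose, sarcasm and irony,
negated emotion mentions, rater selection bias, demographic skew of who
posts, temporal posting dynamics. Passing tests on synthetic corpora
therefore demonstrate the pipeline's internal correctness — matching,
scoring, model fitting, accounting — not the ecological validity of
lexicon matching on real social-media text. One visible consequence: on
token-bag corpora the sentiment model explains far more variance
(R² around 0.7) than is typical for real prose, where unmatched
vocabulary and syntax act as noise.

## Pipeline conventions

`run_pipeline()` deduplicates on the key (source, normalized cleaned
text, drug) — conservative enough that two patients writing different
texts can never be merged — then excludes records whose cleaned text is
empty ("nontextual"). Both exclusions are enumerated in the report's
accounting table, so corpus bookkeeping of the form "N collected →
n analyzed" is mechanically reproducible on any input. Every intermediate
table (records, profiles, sentiments, prevalence tables, model terms) is
persisted when an output directory is configured, and the report carries a
hash over all result tables plus a config hash, package version and seed;
identical config + seed gives identical hashes. Per-emotion model
failures (e.g. separation on a rare emotion) are recorded in the report
rather than aborting the run.

There is no shell entry point: the package functions (`run_pipeline()`,
`generate_corpus()`, `validate_lexicon()`, `roundtrip_check()`) and this
vignette are the interface, in keeping with how analysis packages in this
ecosystem are used.

## Verification strategy and problem sizes

The test suite checks every layer against an independent oracle: the
annotator against a brute-force n-gram matcher on randomized lexica and
corpora (up to 50 terms, 200 reviews); logistic fits against the
closed-form 2×2 odds ratio to 1e-4 relative error; chi-squares against
the textbook formula on random tables up to 6×6; the sentiment
normalization against its closed form, bounds, antisymmetry and
saturation limit; and the full pipeline against its planted ground truth —
95% CI coverage of planted odds ratios and sentiment slopes is verified
at ≥93% over 50 corpora of 3000 reviews, planted-null ΔR² at ≤0.01, and
end-to-end determinism by report hash. These sizes keep the default suite
in the low minutes on one core while leaving the binomial and Wald
approximations comfortably in their asymptotic regime.

## Known limitations

* Gazetteer matching is purely lexical: negated, hypothetical or quoted
  emotion terms all count as expressed emotion.
* The demonstration lexicon is illustrative (47 classes, 142 synonyms),
  not a reconstruction of any published resource; real deployments should
  load a full lexicon through the same schema.
* The native sentiment scorer omits punctuation/capitalization emphasis;
  use the adapter for full-fidelity external scoring.
* Wald intervals and no multiplicity control mirror common reporting
  practice, not optimal inference; rare emotions in small strata can
  separate, which the package surfaces as typed errors.
* Likert satisfaction is modeled by OLS, not ordinal regression, to match
  the analyses it reimplements.
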