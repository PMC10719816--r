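# emospect

Ontology-based emotion and sentiment analysis of patient medication
reviews, with a fully synthetic, ground-truthed test bed.

## The problem

Patients describe their medication experiences on rating sites (WebMD,
Ask-a-Patient, Drugs.com) in free text plus a 1–5 or 1–10 satisfaction
score. For sensitive indications — the motivating case is the
phosphodiesterase type 5 (PDE5) inhibitors sildenafil, vardenafil and
tadalafil, used for erectile dysfunction — these anonymous reviews carry
emotional signal that patients rarely volunteer in the clinic. emospect is
for pharmacovigilance and health-services researchers who want to turn such
review corpora into three quantitative statements:

1. **Which emotions do patients express, and for whom?** Each review is
   reduced to a 6-dimensional binary profile over the primary emotions of
   the Parrot taxonomy (*joy, love, surprise, sadness, fear, anger*), via a
   gazetteer annotator driven by a 3-tier emotion lexicon
   (primary → secondary → tertiary classes, each with synonym lists).
   Prevalences are stratified by drug, age band (`<44`, `45-64`, `≥65`)
   and duration of use (`<1 month`, `1 month–<1 year`, `≥1 year`), with
   chi-square tests and per-emotion logistic regressions reporting odds
   ratios `exp(β)` with Wald 95% CIs `exp(β ± 1.96·SE)`.
2. **How do emotions drive the review's sentiment?** A rule-based scorer
   maps each review to a compound sentiment score in (−1, 1): summed term
   valences `s` (with a 3-token negation window and degree boosters) are
   normalized as `s / sqrt(s² + 15)`. OLS of the compound score on the six
   emotion flags, controlling for drug, age, duration and rating year,
   gives per-emotion sentiment contributions.
3. **Does sentiment predict treatment satisfaction?** Two nested OLS
   models of the 1–5 satisfaction score — with and without the sentiment
   score, on identical listwise-complete rows — quantify the added
   explained variance ΔR².

Because real review corpora of this kind are scraped and cannot be
redistributed, emospect ships a **synthetic corpus generator**
(`generate_corpus()`) whose statistical structure is fully known: emotion
flags are drawn from per-stratum logistic models, texts are token bags
with planted lexicon terms and valence-steering words, and satisfaction is
linearly linked to sentiment plus noise. The filler vocabulary is disjoint
from every lexicon resource, so the annotator provably recovers the
planted flags exactly — every downstream statistic can be validated
against its planted value.

## Worked example

```r
library(emospect)

# annotate and score one review
txt <- "I was not happy with the results, really disappointed"
annotate_text(clean_text(txt), demo_lexicon())
#>   span_start span_end matched_term tertiary       secondary      primary
#> 1          1        2 happy        happiness      cheerfulness   joy
#> 2          4        5 disappointed disappointment disappointment sadness
score_text(clean_text(txt), default_valence_lexicon())
#>   compound raw_sum
#> 1   -0.788   -4.95
```

Note the division of labour: the gazetteer has no negation handling, so
"not happy" still flags *joy* (a documented limitation of dictionary
annotation), while the sentiment scorer's negation window turns the same
phrase negative.

```r
# full pipeline on a simulated corpus
cfg <- run_config(simulate = generator_config(n_reviews = 1000), seed = 42)
rep <- run_pipeline(cfg)
rep
#> Pooled emotion prevalence (%):
#>      joy     love surprise  sadness     fear    anger
#>     65.3     19.9     11.7     37.5      9.0      4.6
#> Satisfaction delta R2: 0.21803 (R2 0.18586 -> 0.40389, n = 513)

tidy(rep$logit_fits$sadness)[2:3, c("term", "or", "ci_lo", "ci_hi")]
#>   term              or ci_lo ci_hi
#> 1 drugvardenafil 0.954 0.495  1.84
#> 2 drugtadalafil  3.19  2.03   5.01
```

Joy and sadness dominate, sadness is strongly elevated for tadalafil
(the generator plants an odds ratio of 3.85 for this contrast; the fit
recovers 3.19 with a CI covering it), and adding the sentiment score to
the satisfaction model raises R² by about 0.2. `n = 513` reflects
listwise deletion over the simulated missingness in age, duration and
satisfaction. Result objects support `tidy()`, `glance()` and
`autoplot()`.

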