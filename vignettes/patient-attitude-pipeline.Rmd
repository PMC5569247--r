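---
title: "Mining patient attitudes from social-media posts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining patient attitudes from social-media posts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infodem)
```

## The problem

Patients with chronic conditions such as Crohn's disease discuss their
treatments — drugs like infliximab (Remicade), adalimumab or
azathioprine — openly on social platforms. Those spontaneous, unprompted
messages are a complementary source of evidence about treatment
satisfaction, but turning a raw scrape of posts into a defensible claim
about patient attitude requires several stages, each with failure modes of
its own:

1. **Spam filtering.** Many accounts on disease-related pages are news
   feeds or advertisers, not patients. They betray themselves by reposting
   identical messages.
2. **Subtopic tagging.** Posts are characterized by curated dictionaries
   of terms for four subtopics: lifestyle, symptoms, treatments and
   side-effects.
3. **Term discrimination.** The Gini index of a term's class-conditional
   probabilities quantifies how well it discriminates among post classes.
4. **Sentiment scoring.** Each post is classified positive (+1), neutral
   (0) or negative (-1).
5. **Term–sentiment association.** Granger causality asks whether a drug
   term's daily mention count *predicts* subsequent daily sentiment.
6. **Validation by human raters.** Expert ratings of the same posts are
   compared with a quadratically weighted Cohen's kappa.

`infodem` implements this pipeline as composable, individually tested
functions, plus a seeded synthetic-corpus generator whose ground truth
makes every stage exactly checkable.

## Spam filtering

A *duplicate* is an exact match of normalized text (lowercased,
punctuation stripped, whitespace collapsed). We deliberately rejected
near-duplicate (edit-distance) detection: exact matching is auditable, and
bulk posters in practice repost verbatim. `flag_spam_accounts()` flags
authors with strictly more than `max_duplicates` duplicate posts; the
default tolerance of 1 allows a human user one verbatim repost while an
account posting the same message three or more times is flagged. The
prolific-author audit (`top_authors()`) remains a human-in-the-loop
report: deciding whether a highly active account is a patient is a
judgment call we do not automate.

## Subtopic dictionaries and the Gini index

The four packaged dictionaries are shipped verbatim (lowercased) as
plain-text word lists under `extdata/dictionaries/`. Matching is
token-exact, with two-word entries ("health care", "reaction allergy")
matched as adjacent token bigrams. We do not stem: the lists mix stems and
full words ("bleed", "complications"), and stemming would silently change
their semantics — the documented cost is that "bleeding" does not match
"bleed". Terms occurring at least 50 times (`select_terms()`, inclusive
threshold) are retained as analysis candidates.

For a term $w$ and $k$ post classes, with $p_i(w)$ the probability that a
post belongs to class $i$ given that it contains $w$,

$$G(w) = \sum_{i=1}^{k} p_i(w)^2 .$$

$G$ ranges over $[1/k, 1]$: $1/k$ at the uniform vector (uninformative
term) and 1 when the term is confined to a single class. Both bounds are
mathematically attainable, so the implementation treats the range as
closed. The class set defaults to the four subtopics but any labeling with
configurable $k$ is accepted.

## Sentiment scoring

`score_post()` is a transparent word-count polarity scorer: count token
hits in a positive and a negative word list, label by the sign of the
difference, ties and zero hits neutral. Trained sentiment tools are
external artifacts we cannot redistribute; the lexicon interface accepts
any plain word list, so a subjectivity-clue lexicon can be dropped in via
`load_lexicon()`. The small packaged lexicon is a synthetic stand-in
written for this package (and kept disjoint from the dictionary terms so
that generator ground truth stays exactly recoverable). Negation ("not
better") is deliberately not handled in this version; on real text this
inflates neutral/misclassified counts, which is consistent with automated
tools agreeing only slightly with human raters.

## Daily series and Granger association

Granger analysis operates on daily aggregates: for a term, `daily_series()`
produces one row per calendar day of the corpus date range (zero-mention
days included) with the mention count, mean sentiment, and the positive
and negative shares of that day's term posts. Daily binning is our choice;
finer bins are too sparse for a corpus of this density and coarser bins
destroy the lag structure.

`granger_test()` fits, by ordinary least squares, the restricted
autoregression $y_t \sim y_{t-1..t-L}$ and the unrestricted model adding
$x_{t-1..t-L}$, and forms

$$F = \frac{(RSS_r - RSS_u)/L}{RSS_u/(n_{\mathrm{eff}} - 2L - 1)},
\qquad n_{\mathrm{eff}} = n - L,$$

referred to $F(L,\, n_{\mathrm{eff}} - 2L - 1)$. Design choices, each made
because the application gives no basis for anything more elaborate:

* **Single user-specified lag, default 1 day.** A multi-lag scan with
  Bonferroni correction is available as `granger_scan()`.
* **Separate tests against the positive-share and the negative-share
  series**, since positive and negative attitudes toward a drug are
  distinct findings; `rank_terms()` ranks candidates by the minimum of the
  two p-values.
* **No multiple-testing correction across terms by default** (raw
  p-values are the primary report for a handful of candidate drug terms);
  Benjamini–Hochberg is available via `adjust = "BH"`.
* **No stationarity pre-treatment.** The mention series are count noise
  around a stable rate in the generated setting; users with trending real
  data should difference before testing.

## Rater agreement

Two raters score each post on the 3-point Likert scale $\{-1, 0, 1\}$,
treated as equally spaced. With $k$ ordered categories the quadratic
("square") agreement weights are

$$w_{ij} = 1 - \left(\frac{i-j}{k-1}\right)^2,$$

so for $k = 3$: 1 on the diagonal, 0.75 for one-step disagreements, 0 for
the two extreme corners. Weighted observed agreement is
$P_o(w) = \sum_{ij} w_{ij} n_{ij} / N$, expected agreement
$P_e(w) = \sum_{ij} w_{ij} r_i c_j / N^2$ from the marginals, and

$$\kappa_w = \frac{P_o(w) - P_e(w)}{1 - P_e(w)},$$

interpreted on the Landis–Koch bands (0.61–0.80 "substantial"). Two
reporting conventions worth making explicit:

* The headline "weighted agreement" percentage is $P_o(w)$, **not** raw
  percent agreement; the two differ (identity weights recover raw percent
  agreement) and `agreement_report()` prints both, labeled.
* Display rounding is half-up at 4 decimals (`kappa_4dp`); computation is
  always at full precision, and on integer tables the intermediate
  quantities are exact rational arithmetic in doubles.

On the packaged expert contingency table (two raters, 261 posts) the
pipeline computes a weighted agreement numerator of 228 (87.36%) and
$\kappa_w = 0.6470$, "substantial" — these are the values the test suite
and `scripts/acceptance.R` recompute from scratch.

## The synthetic-corpus generator

The generator (`generate_corpus()`) emulates the statistical structure the
pipeline assumes, not natural language:

* **Accounts and posting rates.** Post counts per account are Poisson
  (mean 8 by default); real corpora only tell us that some users are far
  more prolific than others, and a Poisson mixture across accounts
  captures that heterogeneity at the level the spam filter and ranking
  stages care about.
* **Spam subpopulation.** A configurable fraction of accounts
  (default 10%) are bulk posters: at least 3 posts of which at most a
  third are distinct, so every spam account carries at least two
  duplicates of its lead message and is recoverable at duplicate
  tolerances 0 *and* 1. Non-spam posts are globally distinct by
  construction.
* **Closed vocabulary.** Texts are built from dictionary terms, lexicon
  words and a fixed neutral filler list, shuffled with bigram entries
  kept adjacent. Because the three vocabularies are disjoint, subtopic
  counts, sentiment labels and spam flags are all *exactly* recoverable —
  the generator's ground truth is a true oracle for every stage.
* **Sentiment encoding.** A post labeled +1 (-1) contains 1–3 positive
  (negative) lexicon words and none of the opposite polarity; neutral
  posts contain no polarity words. The label mix defaults to
  (0.37, 0.27, 0.36), the positive/neutral/negative proportions a human
  expert assigned in the motivating setting.
* **Mention–sentiment coupling.** When a coupled term is configured, its
  daily mention counts $m_d$ are Poisson (default rate 2/day across the
  default October 2011 – August 2015 window), and the polarity of that
  term's posts on day $d$ is driven by the *previous* days' mentions:
  $P(+1) = (1 + \tanh(\beta z_{d-L}))/2$ with $z$ the standardized
  mention count. This places the causal structure exactly where the
  Granger stage looks for it, at the daily-aggregate level.

What the generator does **not** emulate: fluent language, negation,
sarcasm, author demographics, platform metadata, topic drift, or
non-stationary posting rates. Green tests therefore certify the pipeline's
*mechanics* (counting, filtering, aggregation, test statistics) and its
statistical calibration, not the accuracy of lexicon scoring on real
prose.

## Numerical and degenerate-input choices

* Granger: constant response series, or series with $n \le 10L$, are
  rejected rather than fitted; the F statistic is clamped at 0 against
  floating-point cancellation when $RSS_r \approx RSS_u$.
* Kappa: degenerate marginals with $P_e(w) = 1$ raise an undefined-kappa
  error instead of returning 0/0.
* Ranking: terms with no mentions (constant share series) are carried
  through `rank_terms()` flagged `degenerate` with NA p-values, never
  silently dropped, and sort last.
* Ties in `top_authors()` break lexicographically; `select_terms()` sorts
  by count then term, so all orderings are deterministic.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the Granger calibration at
series length 500 (200 null replicates for size, 100 coupled replicates
at $\beta = 0.8$ for power) and the end-to-end recovery runs on one-year,
~50-account corpora — sizes at which the Monte-Carlo bounds are tight
while the whole suite stays quick on a single CPU.

## Limitations

Token-exact matching misses inflected forms; the lexicon scorer has no
negation or intensity handling; kappa is reported without confidence
intervals (none are needed for the exact-arithmetic validation targets);
only two raters are supported (no Fleiss generalization); and the
Granger stage assumes approximately stationary daily series.
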