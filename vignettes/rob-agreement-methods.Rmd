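---
title: "Methods: rule-based risk-of-bias assessment and weighted-kappa agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based risk-of-bias assessment and weighted-kappa agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robagree)
```

## The problem

Systematic reviews of randomized trials grade each trial with the Cochrane
risk-of-bias (RoB) tool: six bias domains, seven assessed items (blinding
contributes two), each judged **low**, **unclear** or **high** risk. These
judgements steer which evidence is trusted, yet different review teams
applying the tool to the same trials can disagree substantially. `robagree`
implements the full measurement chain needed to study that disagreement:

1. a deterministic **rules engine** mapping structured trial features to the
   seven item ratings,
2. **aggregation** from items to a trial-level overall rating and from
   trials to a meta-analysis-level rating,
3. **weighted Cohen's kappa** with confidence intervals and interpretation
   bands for panel-vs-panel comparisons, and
4. a seeded **simulator** with a closed-form agreement oracle, so every
   stage can be validated without access to anyone's unpublished ratings.

## The rating scale and its containers

All ratings live on the fixed ordinal scale `low < unclear < high` (codes
0/1/2). Ratings tables are plain tibbles in long form — one row per
`(trial_id, rater_id, domain)` — and missing ratings are *absent rows*,
never a fourth category. Agreement computations use pairwise deletion: a
trial contributes to a domain's cross-tabulation only when both raters
judged that domain, so `n` legitimately varies across domains. Rating
strings are parsed through an extensible synonym table because Cochrane
exports have used several vocabularies ("Yes/No/Unclear" in older reviews,
"Low/High/Unclear risk" later).

## The decision rules

The rules engine encodes pre-specified, reproducible operationalisations of
the Cochrane guidance. The enumerable rules are exactly as documented in
`?assess_rob`; the judgement calls worth flagging are:

* **Incomplete outcome data.** Low requires *both* an intention-to-treat
  analysis and drop-out ≤ 20%; drop-out > 20% is high regardless of ITT.
  The stated rules leave a gap — drop-out ≤ 20% without ITT — which we rate
  **unclear**: the low condition is conjunctive, and failing one conjunct
  without positive evidence of bias is precisely the tool's
  insufficient-information case.
* **Selective reporting.** "New outcomes added in the results" is
  operationalised on outcome labels as
  `reported \ (primary ∪ secondary)` being non-empty. The high threshold
  for missing secondary outcomes is *strictly* more than 70%: exactly 7 of
  10 missing is not high.
* **Blinding.** An objective outcome can excuse lack of blinding
  (`outcome_objective`, default `FALSE` per record); the override itself
  can be disabled in `rob_rules()`. This follows standard Cochrane
  convention; it is exposed as configuration because operational blinding
  criteria vary between review teams.
* **Other bias.** Low requires all three criteria (baseline comparability,
  co-intervention control, acceptable compliance) explicitly met; any
  explicit failure is high; anything else is unclear. The all/any/else
  structure is our design choice — the source guidance does not state the
  combination rule.

Both thresholds (0.20, 0.70) are `rob_rules()` parameters with those
defaults, since they are decision rules rather than mathematical constants.

## Aggregation

The trial-level overall rating is the **ordinal maximum** of the item
ratings: any high makes the trial high; otherwise any unclear makes it
unclear; low requires low everywhere. With
`require_all_domains_for_low = TRUE` (default) a trial missing items cannot
be rated low overall — absence of information must not certify absence of
bias — and falls back to unclear.

At the meta-analysis level a body of trials inherits the rating held by the
"majority of studies", with the majority cutoff set at 60% of trial overall
ratings. Two conventions were genuinely open and are resolved as
configuration with explicit defaults:

* the cutoff comparison is **inclusive** (3 of 5 trials = 60% qualifies),
  and because the cutoff exceeds 50% at most one category can qualify;
* when **no** category reaches the cutoff the meta-analysis is rated
  unclear and a classed warning (`robagree_no_majority`) is raised, so
  split panels are visible in reports rather than silently absorbed.

## Weighted kappa

For a k×k cross-tabulation with joint proportions `p_ij` and marginals
`p_i.`, `p_.j`, the chance-corrected agreement is

    kappa_w = (Po_w − Pe_w) / (1 − Pe_w),
    Po_w = Σ_ij w_ij p_ij,   Pe_w = Σ_ij w_ij p_i. p_.j

with weights `w_ij = 1 − |i−j|/(k−1)` (linear, the default),
`1 − (i−j)²/(k−1)²` (quadratic) or the identity (classic unweighted kappa).
Linear weights are the default because, applied to the bundled published
meta-analysis table with the severity ordering low(0) < unclear(1) <
high(2), they reproduce the published value −0.29 exactly at the printed
precision — which pins down the weighting the original analysis must have
used, since the alternatives do not (identity weights give −0.23 on the
same table).

When `Pe_w = 1` (e.g. both raters constant on the same category) kappa is
undefined; the package raises a classed error (`robagree_degenerate_kappa`)
carrying the marginals, and the table-level wrapper `rob_agreement()`
converts it into an `NA` row with a note so one degenerate domain cannot
sink a whole analysis. The degeneracy test uses `1 − Pe_w < 1e−12`.

Two confidence intervals are offered, neither an exactness target because
published reliability tables rarely state their method:

* **bootstrap percentile** (default, B = 2000, seeded): resamples the n
  paired units with replacement; degenerate resamples are dropped and
  counted, with a warning above 10%. This produces the asymmetric,
  boundary-respecting intervals that agreement data near ±1 require.
* **analytic**: the large-sample delta-method standard error of weighted
  kappa (Fleiss–Cohen–Everitt 1969), `kappa ± z·SE` truncated to [−1, 1].

All seeded computations restore the caller's RNG state, so a fixed seed
yields byte-identical intervals without side effects on the session.

### Interpretation bands

Kappa values are labelled on the Byrt (1996) scale: ≤ 0.00 no agreement,
0.01–0.20 poor, 0.21–0.40 slight, 0.41–0.60 fair, 0.61–0.80 good,
0.81–0.92 very good, 0.93–1.00 excellent. The bands are stated at
two-decimal resolution, so the value is **rounded to 2 dp before banding**,
which makes the bands gap-free and total on [−1, 1].

## The bundled published tables

Two small reference tables ship in `inst/extdata/` (both plain CSV with a
provenance comment):

* `published_meta_ratings()` — overall RoB ratings of 17 physiotherapy
  meta-analyses, a blinded external panel's consensus versus the original
  Cochrane review authors, with the published agreement/disagreement
  partition. One pair (Puhan 2010) is printed under *disagreements* even
  though both its ratings read "high"; the transcription is verbatim, so
  partition counts (3 agreements / 14 disagreements) and value-equality
  counts (4 identical pairs) differ by one, and `meta_agreement_report()`
  reports both rather than resolving the inconsistency either way.
* `published_domain_kappas()` — the published per-item kappas, CIs and
  interpretation labels for the same corpus. The printed labels depart
  from the Byrt bands in a small number of cells (e.g. a within-panel
  kappa of 0.32 printed as "fair" where the bands give "slight"); the
  bands are treated as normative and the fixture keeps the printed labels
  verbatim, so the discrepancy is documented and testable, not replicated.

## The simulator

`simulate_paired_ratings()` draws, for each trial and item, a latent true
rating from a three-point distribution; each of two panels then emits a
rating through its own 3×3 row-stochastic confusion matrix, conditionally
independently given the truth, and emitted ratings are deleted completely
at random. This emulates exactly the structure the analysis assumes —
independent panels, pairwise-deletion-compatible missingness — and exposes
what it omits: real raters share error sources (both read the same badly
reported manuscript), domains within a trial are correlated, and
missingness in real reviews is anything but random. Passing tests therefore
validate the *statistical machinery*, not the behaviour of human raters.

Defaults were fixed once to mirror a poorly reported physiotherapy trial
corpus: truth mass (0.2, 0.5, 0.3) over low/unclear/high, 70% per-category
rater accuracy, 109 trials, 10% missingness.

The companion oracle `population_kappa()` forms the exact joint
distribution `p_ij = Σ_t truth_t A_ti B_tj` and returns its weighted kappa
in closed form; the sample kappa must converge to it, and the test suite
checks recovery at n = 10⁴ within three delta-method standard errors, plus
closed-form limits (identity confusions → 1, truth-blind raters → 0, and
agreement with the empirical kappa at n = 10⁶ within 0.01).

`simulate_feature_records()` generates trial-feature records with known
true ratings computed by `rules_reference()`, a second implementation of
the decision rules built from exhaustive join tables rather than
conditional logic. The production engine must match it on every generated
record (the suite uses 1000), which guards each rule's boundary behaviour
against silent edits.

## Validation problem sizes

The test suite exercises: all 3⁷ = 2187 item-rating vectors for the
overall-rating rule; 200 random cross-tabulations (n ≤ 30) against a
brute-force per-unit kappa oracle at 1e−12; 1000 generated feature records
for rules-engine equivalence; 10⁴ simulated trials for parameter recovery
and 10⁶ for the Monte-Carlo convergence of the population oracle. These
sizes keep the full suite under a minute on a single core while leaving
the Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Two raters only; no Fleiss/Krippendorff multi-rater generalisation.
* The rules engine consumes *structured* feature records; extracting those
  from trial reports is upstream, manual work.
* The simulator's conditional-independence and MCAR assumptions are
  optimistic; correlation knobs are reserved in the configuration but not
  implemented.
* Rating vocabularies outside the synonym table must be added explicitly;
  RevMan XML is not parsed.
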