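---
title: "Methods: quantifying concordance between field and public survey estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying concordance between field and public survey estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svyconcord)
```

## The comparison being made

An NGO baseline survey and a public household survey (DHS/MICS-style) both
report prevalence-type indicators — the percentage of a population meeting a
definition, such as stunting or attending three or more antenatal visits.
`svyconcord` asks how well such estimates agree when matched as closely as
the data allow on indicator, country, geography, year and season, and how the
residual disagreement should be attributed.

All estimates live on the percent scale (0–100), matching how survey reports
print them. Every pairwise quantity follows one sign convention:

> difference = reference estimate − field estimate (percentage points).

## Record model and coding rules

A record is one estimate from one source at one place and time. Geography is
a `>`-joined path rooted at the country, with the administrative level coded
1 (village/town/locality/traditional authority) through 5 (country). Because
the same word denotes different levels in different countries (a Liberian
"county" is a province-level unit; a Kenyan "county" is district-level), the
word-to-level map is a user-editable synonym table (`geo_level_synonyms()`)
rather than a fixed rule.

Fieldwork spanning two calendar years is mid-coded as the first year plus
0.5 (`"2013/14"` → 2013.5); the rule is applied mechanically, with no
special-casing of single-year labels. Estimates based on fewer than ten
observations are excluded (n = 10 itself is kept; the published minimum
retained field sample of 12 is consistent with this reading). The year
plausibility window (1990–2035) is deliberately generous around the 2005–2019
era of the motivating reports: it catches typos without blocking reuse.

Reference estimates are sometimes recomputed to mirror a specific field
survey's sample definition (same age ranges, same catchment population). Two
such extractions can legitimately share a (source, geography, year,
indicator) key while differing in value, so records carry an optional
`population` tag: it participates in the uniqueness check, and pairing
requires tags to be equal when both sides have one.

## Matching

Cycle choice: the most recent reference cycle no later than the field survey
year. Matched datasets in practice contain a handful of pairs whose only
available reference cycle is slightly *after* the field survey; rather than
forbid these, the builder keeps them behind an explicit `posterior_match`
flag (default policy allows them), so callers can filter.

Geography: the reference estimate for the field unit itself if present at
the same level, otherwise the nearest ancestor in the hierarchy, climbing
one level at a time; the match is never below the field unit's level, and
the levels climbed are recorded. Composite areas ("Nghe An+Cao Bang+Kon
Tum") are declared as single opaque path components in the input tables, not
inferred, and therefore match only a reference record declared for the same
composite.

Same-source scenarios compare a source against itself: S1 holds the unit
fixed and varies the cycle (earlier cycle as reference), S2 holds the cycle
fixed and pairs a higher-level unit with each strictly contained lower unit,
S3 varies both. Published same-source examples are internally inconsistent
about which cycle S2 uses; the worked Zambia example resolves it to the
earlier cycle, which this package adopts as the default
(`s2_cycle = "earlier"`), with the later cycle available as an option.

## Concordance statistics

"Within k%" is interpreted as |difference| ≤ k percentage points,
*inclusive* — the convention is stated nowhere in the source tables, and
percentage points (not relative percent) is the only reading consistent with
tabulating differences on the percent scale. Sample SDs (n − 1) are used
throughout, the usual survey-statistics convention. All quantiles — medians,
IQRs, boxplot quartiles — use linear interpolation (R type 7); any single
declared rule would do, but it must be fixed, because IQRs of small strata
depend on it. Boxplots follow the Tukey convention: whiskers at the furthest
observation within 1.5 × IQR of the quartiles, everything beyond counted as
an outlier. Sample-size tertiles are rank-based thirds with ties broken by
stable input order and remainders allotted to the lower tertiles.

Reference-value bins are half-open `[lo, hi)` with a closed top band so that
an estimate of exactly 100 belongs to the last band.

## Variance partitioning

The partition uses sequential (Type I) sums of squares with factors entered
in a declared order — by default indicator, level-difference band (0/1/2+),
year difference as one linear continuous term, season concordance. Type I is
chosen deliberately: it is the only standard decomposition that is exactly
additive, so the factor shares plus a residual ("Other") sum to 100, which is
how such tables are presented. The cost is order dependence on correlated
factors; the entry order is therefore part of the reported result, and the
`variance_partition` object records it. Shares are invariant to the
categorical contrast coding (asserted in the test suite), a factor constant
over the pair set contributes exactly 0, and a constant response is an
error. For same-source scenario pairs season is dropped from the factor
list, since one source typically collects within a single season per
country. Pairs are unweighted. p-values, F-tests and Type II/III
decompositions are out of scope.

A brute-force one-way oracle (`one_way_oracle()`, group means only, no model
fit) provides an independent route against which the single-factor partition
is checked to 1e-9 relative error.

## Sampling-error simulation

Two independent estimates of the same true prevalence p, each a
binomial(n, p) count divided by n, differ with SD

> 100 · √(2 p (1 − p) / n) percentage points,

3.16 pp at p = 0.5, n = 500. The simulation draws both estimates
independently (no shared clusters) over the grid {1, 10, 20, ..., 90, 99}%
with n = 500 and 1,000 iterations per prevalence. The claim that pure
sampling error stays "below 10 pp" is operationalised as the Tukey *upper
whisker* of the absolute-difference boxplot rather than the absolute
maximum: at p = 0.5 the maximum over 1,000 iterations exceeds 10 pp with
non-trivial probability under the model itself, so only the whisker reading
is consistent with a figure-based claim. One root seed drives the run;
per-prevalence streams are derived from it deterministically.

## The synthetic generator

The generator exists so that matching, concordance, partitioning and
recovery can be tested end-to-end with known ground truth — the restricted
microdata behind real comparisons cannot be packaged. Its central modelling
decision is a logit-additive data-generating model:

> logit p(i, g, t, s) = μ_i + Σ level effects along g's path
> + β_i (t − t₀) + γ_i · 1[wet season]

with an emitted estimate drawn as binomial(n_eff, invlogit(logit p +
δ_source,i)) / n_eff. Additivity on the logit scale lets geographic
heterogeneity, drift, seasonality and per-source method bias compose without
leaving (0, 1).

Defaults, chosen once as a realistic small-country landscape:

* n = 500 per estimate — a typical indicator-level sample size on both
  sides of real comparisons; design effect 1.5, the order observed in
  clustered household surveys, implemented as effective-sample-size
  deflation n_eff = round(n/DEFF) rather than explicit cluster simulation
  (simpler, and sufficient to widen difference distributions realistically);
* baseline prevalences logit-uniform on [0.05, 0.95], covering the whole
  reference-value range including the extremes where agreement is best;
* geographic SDs 0.2–0.3 logit per level, modest subnational heterogeneity;
* drift SD 0.05 logit/year (slow secular trends), seasonal SD 0.1 logit,
  method-bias SD 0.25 logit per source × indicator;
* two seasons (dry/wet); "unknown" season arises only by masking a
  configured fraction of labels, mirroring reports that omit fieldwork
  dates;
* an optional field-source site-selection bias (surveying only the worse-off
  fraction of units) ships **off** by default, since its real-world
  magnitude is unquantified.

What the generator does *not* emulate: real questionnaire or definition
drift between sources, correlated cluster structure, non-binomial
measurement error, or any specific country's prevalence profile. Passing
recovery tests therefore show that the pipeline attributes variance
correctly under the stated model, not that real NGO–DHS/MICS discordance is
fully explained by it.

## Test scenarios and problem sizes

The recovery suite runs three prescribed configurations: an all-zero model
(pure binomial noise; the residual share must dominate and per-indicator
difference SDs must match the closed form within 3 Monte-Carlo SEs), a
bias-only model (method-bias SD raised to 1.0 logit; the indicator factor
must lead), and a drift-only model (drift SD 0.15 logit/year). Because a
single field cycle makes the year-difference term constant across pairs, the
drift contrast uses two field cycles 0.5 and 1 year after the reference
cycle versus two cycles 2 and 4 years after, over five matched seeds. Test
landscapes use 24 provinces × 12 indicators (60 for the prevalence-band
check) — large enough for stable shares, small enough to run in seconds; the
simulation's closed-form check uses 10,000 iterations per grid point.

## Known limitations

* Indicator harmonisation is exact-id matching; no fuzzy matching of
  indicator definitions or place names.
* The year-first matching order (choose cycle, then resolve geography) can
  report no-match for a field record whose geography exists only in an
  older reference cycle.
* Subgroup summary SDs from published tables cannot be cross-checked
  without the underlying pairs; only schema and machinery are reproduced.
* With correlated factors the Type I shares depend on entry order by
  construction; report the order alongside the shares.
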