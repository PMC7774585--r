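---
title: "The Psychosis Polyrisk Score: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Psychosis Polyrisk Score: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppscore)
```

## The model

The Psychosis Polyrisk Score treats environmental risk the way a polygenic
risk score treats variants. Each of 16 factor groups offers a set of
mutually exclusive exposure levels; a respondent selects exactly one level
per group, and the total score is the sum of the selected level weights.
Weights live on a decibel-like log-odds scale,

$$w = 10 \cdot \log_{10}(\mathrm{OR}),$$

rounded to the nearest half point, so that a total score $s$ implies a
relative risk $\mathrm{RR} = 10^{s/10}$. This makes the score additive where
odds ratios are multiplicative: `rr_from_score(a + b)` equals
`rr_from_score(a) * rr_from_score(b)` exactly. The instrument's weights are
stored constants in `default_registry()` — they were fixed a priori from an
umbrella review of meta-analyses and are never recomputed here from effect
sizes. `weight_from_or()` exposes the scale mapping for users who wish to
re-weight the instrument as evidence accumulates; every shipped weight is a
fixed point of that mapping.

The score-to-RR exponent base and the factor of 10 are reconstructions: the
instrument's published description gives the weighted-sum structure and
eight (score, RR) pairs, all of which satisfy $\mathrm{RR} = 10^{s/10}$ to
the printed two decimals (9 &rarr; 7.94, 39.5 &rarr; 8912.51, -15 &rarr;
0.03, ...). The package adopts that closed form; the acceptance suite pins
all eight pairs.

### Dependent exposures

Some underlying factors cannot be held in arbitrary conjunction — an
immigrant is first- or second-generation, not both; a North African
immigrant is necessarily an immigrant; ethnic density modifies risk only
for non-White ethnicity. Such factors are folded into single combined
groups whose cell weights are additive on the log-OR scale
(`combine_nested_weights()`): North African origin adds +1 point over other
regions within either generation, and Black Caribbean ethnicity adds +2.5
points over other non-White ethnicity at every density. The component odds
ratios behind those increments are not recoverable from the available text;
only the additive structure is, and it is what the package asserts. Counting
combined components individually, the instrument operationalises 22 factors
in 16 scored groups; the registry stores `factor_count = 22` as published
(the published selection arithmetic — 12 higher-evidence factors plus 11
lower-evidence ones — does not obviously total 22, and we deliberately do
not invent a reconciliation).

Evidence-class tags (I–IV) are carried per group because the instrument
stratifies factors by strength of evidence, but the per-factor class list is
in unavailable supplementary material; the shipped tags follow the source
umbrella review where the narrative identifies a class and default to IV
otherwise. They are metadata only and never enter a score.

### Resolution rules

`resolve_profile()` maps raw questionnaire answers to one level per group:

* **"Male & 25–35 years old"** is Yes iff sex is male and age is in the
  closed interval [25, 35].
* **Paternal age** is published with overlapping bins ("<35 / >35 / >45");
  we resolve them monotonically and exhaustively as `<35`, `35–45` (both
  boundaries included) and `>45`, assigning boundary ages to the milder bin.
* **Ethnic density** is ignored for White respondents (the instrument gives
  White a single weight).
* **Winter/spring birth** is retained with both weights 0, as published, for
  instrument fidelity and forward compatibility with re-weighting.
* Cross-group implausibilities (a non-immigrant with a region of origin;
  Black Caribbean ethnicity with North African origin) produce warning
  records, never errors — the instrument imposes no such constraint, and a
  digital questionnaire may or may not have enforced one.
* Missing data policy: `strict` (default; error naming the item — the only
  published precedent for non-completion is a drop-out, not partial data),
  `reference` (impute the group's baseline level, flagged), or, at cohort
  level, `exclude` (drop the respondent and report the exclusion).

### Cohort reporting

`score_cohort()` reports the published summary format: mean, SD, median,
quartile ranges, and the percentage of the cohort *strictly* above each
threshold (the convention "PPS > 5 (RR > 3)"). Quartile bins are formed by
linear-interpolation quantiles (type 7, R's default) at 0.25/0.5/0.75 with
boundary ties assigned to the lower bin, and each bin is reported as its
*observed* (min, max) score interval with its membership percentage — the
format "Q1 (−3 to −1.5): 26.7%".

## The population simulator

`simulate_population()` emulates the published simulation design: each of
`n` synthetic individuals ("permutations") is built by sampling one level
per factor group independently from a prevalence configuration, and the
group weights are summed. Groups are sampled independently because that is
what the published permutation scheme implies, and its limitations section
concedes the independence assumption; no dependence structure is modelled.
The simulator samples the 16 scored groups directly (not the 22 raw factors)
since a full per-level distribution over each combined group subsumes any
joint or conditional sub-question scheme. Sampling is chunked
(`chunk_size = 1e6`) so the published scale of $n = 10^7$ runs in modest
memory; the default `n` matches that scale, while tests use $n \le 10^6$.

The simulator is validated against a closed-form oracle, `expected_score()`:
under independence the total is a sum of independent categorical variables,
so its mean and variance are exactly

$$\mu = \sum_g \sum_\ell p_{g\ell} w_{g\ell}, \qquad
\sigma^2 = \sum_g \Big(\sum_\ell p_{g\ell} w_{g\ell}^2 -
\big(\sum_\ell p_{g\ell} w_{g\ell}\big)^2\Big).$$

Tests require the empirical mean to sit within 3 Monte-Carlo standard errors
of $\mu$, all scores to be half-integers, and all scores to stay inside
[-16, 54] — bounds established by an *independent* enumeration oracle that
folds the per-group weight sets through iterated unique pairwise sums
(covering every one-level-per-group combination without materialising the
~860,000 profiles). Interestingly, the published observed minima (-14 in
controls, -15 simulated) both exceed this enumerated floor of -16; whether
an undocumented constraint exists cannot be determined from the text, so the
package keeps the enumerated bound.

### What the default prevalences are — and are not

The prevalence table used in the published simulation is in unavailable
supplementary material. `default_prevalences()` therefore ships round,
plausible illustrative values (e.g. 30% childhood trauma, 5% heavy cannabis
use, 50% urban residence, 85% non-immigrant), chosen once as a realistic
stated world and documented as NOT the published configuration. Under them
the analytic moments are mean -3.75, SD 6.95. Consequently the published
simulation moments (mean 0.817, SD 6.87, AJB = 104,030) are explicitly not
reproduction targets; what a green simulator test establishes is agreement
with the closed-form oracle, determinism under a seed, and the structural
properties of the distribution (half-integer support, bounds, near-symmetric
CLT behaviour of a sum of 16 bounded independent terms), not epidemiological
realism of any particular prevalence. Real applications should supply their
own configuration via `load_prevalences()`.

### Normality testing

The published analysis names an "adjusted Jarque–Bera test".
`adjusted_jarque_bera()` implements the exact-small-sample-moment
adjustment: with biased sample skewness $S$ and kurtosis $K$,

$$\mathrm{AJB} = \frac{S^2}{\mathrm{Var}(S)} +
\frac{(K - \mathrm{E}[K])^2}{\mathrm{Var}(K)}, \qquad
\mathrm{E}[K] = \frac{3(n-1)}{n+1},$$

with $\mathrm{Var}(S) = 6(n-2)/((n+1)(n+3))$ and
$\mathrm{Var}(K) = 24n(n-2)(n-3)/((n+1)^2(n+3)(n+5))$, referred to
$\chi^2_2$. This variant was chosen because it is the standard
exact-moment ("adjusted") correction and the publication names no other.
Tests verify that a sample engineered to have $S = 0$ and
$K = 3(n-1)/(n+1)$ scores exactly 0 ($p = 1$), that heavy skew is rejected
at $p < 0.001$, and that the type-I error over 1000 seeded normal samples
of $n = 1000$ lies in [0.03, 0.07].

## Group statistics

The published between-group analyses are provided as small wrappers with
explicit conventions:

* `welch_t()` works from (n, mean, sd) triples so published summary tables
  can be re-tested without raw data. The *Welch* (unequal-variance) form was
  chosen because it reproduces the published age comparison p-value (0.006)
  from the printed summaries, while the pooled-variance form does not.
* `fisher_exact()` implements the two-sided probability-mass rule — sum the
  hypergeometric probabilities of all tables no more probable than the one
  observed (with a 1e-7 relative guard on the comparison, the dominant
  convention) — and is cross-checked against `stats::fisher.test` on random
  tables as an independent oracle.
* `one_way_anova_tukey()` wraps `stats::aov` + `stats::TukeyHSD`
  (Tukey–Kramer for unbalanced groups). With two groups, F equals the
  squared pooled t to 1e-10.
* `pearson_correlation()` wraps `stats::cor.test`.

No multiple-testing correction is applied across descriptive-table rows, as
none was applied in the source analysis. The published three-group ANOVA
with df (2, 10,000,000) is not reproduced as a target: its exact df
bookkeeping (how 15 + 66 + 10^7 observations entered) is not recoverable, so
the suite instead checks the qualitative finding — at the three published
group means with SDs near 7, all Tukey pairwise comparisons separate at
large n.

## Fixtures and IO

`generate_fixture_cohort()` produces desk-scale synthetic respondents: it
samples exposure levels with the same independence model as the simulator
and back-fills raw questionnaire fields consistent with the sampled levels
(a "Male & 25–35: Yes" draw gets male sex and an integer age in [25, 35];
a paternal-age bin gets an age inside the bin; combined levels are
decomposed into their raw categorical items). What it does *not* emulate:
exposure correlations, age structure, instrument-level measurement (the
underlying trauma/anhedonia questionnaires are out of scope — the package
consumes already-ascertained indicators), and item nonresponse. A green
round-trip or scoring test on fixtures therefore establishes the plumbing
and the sampling model, not realism of covariance between exposures.

CSV responses use yes/no booleans and lower-snake-case categorical labels;
JSON reports store full-precision numbers (display rounding — RR and
moments to 2 decimals, percentages to 1 — is applied only in printed
summaries) and embed the package version, a registry hash, the seed and n,
so every stochastic artefact can be regenerated bit-identically.

## Numerical notes and limitations

* All weights are half-integers, hence exactly representable in binary
  floating point; totals are exact sums and grid checks use a 1e-9 guard
  only defensively.
* `quantile` type 7 and strict threshold inequalities are deliberate,
  documented conventions; other choices change quartile membership for tied
  scores.
* Degenerate cases are explicit: constant samples error in
  `adjusted_jarque_bera()` (moments undefined); two constant equal groups
  give p = 1 with a note in `welch_t()`; an all-equal ANOVA is flagged
  rather than returning 0/0.
* The instrument's weights assume independent, additive log-odds
  contributions; correlated exposures will make the implied RR miscalibrated
  at the extremes (a 54-point profile implies an astronomically large RR
  that should be read as ordinal, not literal).
* The package scores the instrument; it does not validate it. Nothing here
  estimates predictive accuracy, calibration against observed transitions,
  or gene–environment interaction.
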