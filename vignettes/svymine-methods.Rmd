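---
title: "Mining multimorbidity combinations in complex-survey data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining multimorbidity combinations in complex-survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svymine)
```

## The problem

Most of what is known about chronic disease prevalence concerns single
conditions, yet a large share of adults are treated for two or more
conditions at once, and outcomes — costs, self-rated health — attach to the
*specific combination* a person carries, not merely to a condition count.
`svymine` identifies every combination of 20 primary-care-relevant chronic
conditions that is frequent in complex-survey microdata, estimates its
design-based burden, and quantifies how far each combination's frequency
exceeds what independence would predict.

The intended user is an epidemiologist or health-services researcher with
person-level survey microdata carrying a stratified cluster design
(variance stratum, PSU, person weight), self-reported treated conditions
coded to 3-character ICD-10-CM, a 5-level self-rated health item, and
annual medical expenditures.

## The pipeline

1. **Ingest** (`survey_dataset`, `read_survey_data`): conditions are mapped
   to a 20-category roster (a Fortin-style primary-care classification)
   through an editable TSV; self-rated health of fair/poor defines the
   poor-health outcome; expenditures can be deflated to base-year dollars
   (`adjust_inflation`; deflators are data, defaulting to 1 so synthetic
   runs need no economic series); pooled-year weights are annualized by
   dividing by the number of pooled years (`annualize_weights`).
2. **Mine** (`mine_frequent_itemsets`): a weighted Apriori search treats
   each person as a transaction and each condition as an item.  Counting is
   superset-inclusive ("at least", not "exactly").  Two thresholds mirror
   the two-stage design: an unweighted support pass (default 0.20%) prunes
   the lattice by downward closure, then a weighted cut (default one
   million persons) drops combinations too rare to matter nationally.
3. **Estimate** (`itemset_estimates`): Taylor-linearized prevalence,
   weighted totals, lift, domain means of expenditures, weighted medians
   and IQRs, and poor-health percentages, all with t-based CIs at the
   design degrees of freedom (PSUs minus strata).
4. **Filter** (`min_improvement_filter`): combinations whose burden
   statistic does not exceed every immediate sub-combination's by at least
   10% are set aside as redundant; `top_k_union` assembles the top-20
   rankings by mean cost and by poor-health percentage.
5. **Regress** (`fit_survey_logistic`, `batch_adjusted_or`): per-combination
   survey-weighted logistic regression of poor health on the exposure
   indicator, adjusted for an age spline, race/ethnicity, and sex, with
   linearized sandwich variances.

`run_full_pipeline` orchestrates all stages and writes CSV tables plus a
JSON manifest; every number in every report is the untransformed output of
one estimation function.

## Design-based estimation

All variances use Taylor-series linearization with the with-replacement
first-stage approximation: per-person influence values $z_i$ are summed to
PSU totals $Z_{hj}$ and

$$\widehat{\mathrm{Var}} = \sum_h \frac{n_h}{n_h-1}\sum_j
  \left(Z_{hj} - \bar Z_h\right)^2 .$$

No finite-population correction is applied — the convention for public-use
files, which suppress first-stage sampling fractions.  A stratum with one
PSU is an error by default (naming the stratum); `collapse_single = TRUE`
merges such strata rather than silently treating them as certainty units.
Confidence intervals are $t$-based with design df = #PSUs − #strata; a
pooled multi-year file treats (year, stratum) pairs as distinct variance
strata, so pooled years never share PSUs.

**Lift.** For a combination $X$, lift is
$L = \hat p_X / \prod_{c \in X} \hat p_c$ — observed over expected-under-
independence prevalence.  Its CI is built on the log scale from the
linearized influence

$$z_i = \frac{w_i}{\sum w}\left[\frac{1\{i \supseteq X\}-\hat p_X}{\hat p_X}
 - \sum_{c\in X}\frac{1\{i \ni c\}-\hat p_c}{\hat p_c}\right],$$

then exponentiated, which produces the asymmetric intervals characteristic
of ratio estimands.  The log-scale construction is this package's choice;
equally defensible alternatives (e.g. Fieller-type intervals) exist, but
log-delta intervals are standard for ratios of survey proportions, and the
simulation suite confirms 93–97% empirical coverage at the study's scale.

**Quantiles.** Weighted medians and IQRs use the lower weighted quantile
without interpolation: deterministic, invariant to weight rescaling, and
well-defined for the point-mass-at-zero expenditure distributions common in
survey data.  An interpolated variant is available behind a flag.  Medians
and IQRs are reported without CIs.

**Domain estimation.** Subpopulation estimates (per-combination means, the
sex subgroups) keep the full design and zero out non-members, the ratio
linearization handling the random domain size.  Point estimates equal
those from a physically subset file; standard errors remain valid even
when subsetting would empty PSUs.

## The minimum-improvement filter

The redundancy rule is interpretive in two places, and both readings are
deliberate:

* *Comparison set*: a combination of size $k$ is compared against **all**
  of its immediate sub-combinations of size $k-1$ (dyads against their two
  singles).  Holders of a sub-combination are a superset population of the
  holders of the combination, which is what makes the sub-combination "more
  parsimonious".
* *Improvement*: relative, one-sided — $(\mathrm{stat}_X -
  \mathrm{stat}_{parent})/\mathrm{stat}_{parent} \ge \tau$, default
  $\tau = 0.10$, must hold against every parent.  Only higher burden counts
  as information because the filter feeds highest-burden rankings.

Point estimates alone are compared (no significance test on the
improvement).  The filter is idempotent, never changes an estimate, and
its retained set is monotone non-increasing in $\tau$ — properties the test
suite asserts directly.

## Survey-weighted logistic regression

One model per combination: poor health on the exposure indicator plus an
age spline, race/ethnicity (non-Hispanic white reference, the largest
group), and sex (male reference).  Coefficients solve the weighted score
equation by IRLS (relative deviance change < 1e-8 or 25 iterations;
separation flagged at $|\beta| > 15$); the covariance is the sandwich
$A^{-1} B A^{-1}$ with $B$ the Taylor covariance of the per-person score
contributions.  Under a trivial design (equal weights, one PSU per person)
the estimates reproduce ordinary ML logistic regression to 1e-6, which the
suite checks against `glm`.

The age spline is natural cubic with interior knots at equally spaced
*weighted* age quantiles.  `df` counts age parameters including the
intercept, so `df = 2` is exactly linear-in-age — a convention chosen so
the nested-model check (spline fit collapses to the linear fit) is exact.
Default `df = 4` (two interior knots at the weighted age tertiles) is
config-exposed; the source study names splines but no basis, df, or knot
rule, so these are package choices.

Reported effect measures are odds ratios from logistic models.  (Study
materials are ambiguous between logistic and log-binomial descriptions;
the Methods-level description — logistic, odds ratios — is implemented, and
a log-binomial option is deliberately out of scope.)

## The synthetic generator

`generate_population` emulates the structure of a pooled national
household-survey file so that every stage is testable without restricted
data:

* **Design**: configurable strata (default 50) with two PSUs each — the
  minimal design for Taylor variance and the common PUF layout — and
  log-normally perturbed unequal weights ratio-calibrated so annualized
  weights sum *exactly* to the target population (default 249,221,000
  adults, pooled over 4 years).
* **Conditions**: 20 Bernoulli indicators with logistic models in age and
  one shared Gaussian frailty (SD 0.8 by default).  A single frailty
  parameter is the simplest mechanism that makes *every* pairwise lift
  exceed 1, the qualitative signature of multimorbidity clustering; it
  cannot represent negatively associated or block-structured comorbidity.
  Default baseline log-odds were calibrated once, by Monte-Carlo root
  finding under the default age mixture and frailty, so marginal treated
  prevalences land on realistic values (26% hypertension down to 0.8%
  dementia), implying roughly 38% of adults with 2+ treated conditions.
* **Outcomes**: log-normal expenditures with a per-condition-count
  increment of 0.55 on the log scale (reproducing the dose-response
  gradient of cost with condition count), a Beta-distributed out-of-pocket
  share, and self-rated health drawn so fair/poor probability follows a
  logistic model in condition count, designated conditions, age, and
  optionally a designated exposure combination.
* **Truth**: conditions are independent given (age, frailty), so true
  marginals and joint prevalences are Monte-Carlo expectations of products
  of conditional probabilities — 10^6 integration draws on a separate seed
  stream, no binary sampling.  With zero frailty *and* zero age slopes the
  true lift is exactly 1.  Note that age-driven prevalence alone induces
  lift > 1; independence test configurations therefore zero both.
* **The regression benchmark** (`regression_bench`, 50,000 persons) wires a
  designated three-condition exposure with log-OR log(6.9) into the
  poor-health model, keeps the remaining poor-health coefficients linear in
  age and free of condition-count terms, and so makes the adjusted
  logistic fit correctly specified: the designed OR is the estimand the
  fit must recover.

What passing tests on this generator do **not** show: correct behavior
under negative condition dependence, informative weighting (weights
correlated with outcomes), nonresponse, or measurement error in condition
ascertainment — none of which the generator emulates.

## Numerical and scale choices

Condition vectors are packed 20-bit integers; support counting is bitwise
containment, so the miner's memory is trivial and candidate counting is
vectorized over persons.  Zero-support itemsets are never visited: with
`min_support = 0` the search enumerates exactly the combinations observed
in the data, not the full $2^{20}$ lattice.  Ranking ties break by larger
weighted total, then label — determinism the byte-identical-output test
relies on.

Simulation sizes used by the validation suite were chosen to estimate
coverage with ~1% Monte-Carlo error while keeping the whole suite fast:
1,000 replicates at n = 10,000 for proportion CI coverage, 500 at
n = 20,000 for lift coverage (two dependence regimes), and 200 replicates
of the 50,000-person regression benchmark.  The acceptance script uses the
same designs at moderately reduced replicate counts.

## Known limitations

* The shipped ICD-10-CM map is a best-effort approximation of the Fortin
  classification assembled for this package; site-specific maps should be
  swapped in via `read_condition_map`.
* Treated prevalence is a lower bound on true prevalence; nothing in the
  pipeline corrects for under-ascertainment of less salient conditions.
* Variance estimation is with-replacement Taylor linearization only;
  replicate-weight methods (BRR, jackknife) are not implemented.
* The minimum-improvement rule compares point estimates; sampling noise in
  a parent's statistic can flip a retain/drop decision near the margin.
* No multiplicity adjustment is applied across the per-combination
  regressions, matching standard practice for descriptive combination
  screens.
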