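---
title: "Estimating disease prevalence from multi-study stratified counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating disease prevalence from multi-study stratified counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprev)
```

## The estimation problem

Prevalence estimates of chronic neurodegenerative disease in North America
come from a handful of regional studies — administrative health databases,
integrated care systems, record-linkage projects, and one long-running
closed cohort — each with its own age structure and sampling frame. A single
national figure requires three things: removing demographic differences
between study populations (direct standardization), pooling the studies while
acknowledging that their true prevalences genuinely differ (random-effects
meta-analysis), and propagating both sources of uncertainty into the
composite (Monte-Carlo interval). `metaprev` implements that pipeline, plus a
person-time estimator for closed cohorts that cannot be treated as
cross-sectional samples, and simulators that generate data with exactly the
structure the estimators assume.

## Direct standardization

For one study, each age (and sex) stratum $i$ contributes cases $x_i$ out of
a denominator $n_i$. Given reference counts $P_i$ (here the 2010 US census
structure), the expected cases are $E_i = (x_i/n_i)\,P_i$ and the
standardized rate per 100,000 is

$$ R \;=\; 10^5 \, \frac{\sum_i E_i}{\sum_i P_i}
   \;=\; 10^5 \sum_i w_i \frac{x_i}{n_i}, \qquad w_i = \frac{P_i}{\sum_j P_j}. $$

`std_rate()` computes this with full precision; printed tables round expected
cases and rates to integers (the convention of the source literature — note
that a total of per-stratum *rounded* expected cases differs from the rounded
full-precision total in general, so both are carried).

Confidence intervals use the gamma method for directly standardized rates:
treating each $x_i$ as Poisson, with per-person weights
$\tilde w_i = w_i/n_i$, $R = \sum \tilde w_i x_i$ has variance estimate
$v = \sum \tilde w_i^2 x_i$. The lower bound is the $\alpha/2$ quantile of a
gamma distribution with mean $R$ and variance $v$; the upper bound shifts to
mean $R + \bar{\tilde w}$ and variance $v + \overline{\tilde w^2}$. The shift
uses the *mean* weight and mean squared weight (the Tiwari et al. variant)
rather than the maximum weight of the original Fay–Feuer construction: it is
less conservative while retaining at-least-nominal coverage, and for a single
stratum both reduce to the exact Poisson gamma interval — which is how the
implementation is tested. Zero-case tables get a lower bound of 0 and a
finite upper bound from the same construction; no continuity correction is
applied to point estimates.

## Random-effects meta-analysis of log prevalence

Across studies, each study $j$ in a given sex × 10-year age stratum enters as
a log prevalence $y_j = \ln(x_j/n_j)$ with within-study variance
$v_j = 1/x_j$ — the large-sample Poisson variance of a log rate, appropriate
for a rare outcome. (A binomial variant $v_j = (1-p_j)/x_j$ is available via
`variance = "binomial"`; for prevalences below a few percent the two are
practically identical.) The additive model

$$ y_j = \mu + u_j + e_j, \qquad u_j \sim N(0, \tau^2), \quad e_j \sim N(0, v_j) $$

is fit by `fit_random_effects()`, which delegates the $\tau^2$ estimation and
pooling to `metafor::rma.uni` — REML by default (the conventional default of
that software), DerSimonian–Laird as an option. The test suite holds both
against independent oracles: the DL closed form written out by hand, and a
three-stage grid search of the restricted likelihood at $10^{-6}$ resolution.
The estimator used is recorded in all pipeline output metadata because it is
a genuine analytic choice.

Zero-case study strata are excluded from their cell with a warning: a study
observing no cases carries no information about *log* prevalence, and
continuity corrections would inject an arbitrary prior. Cohort-type studies
(flagged with `study_type = "cohort"`) are never pooled — person-time
prevalence from a closed cohort is a different estimand, reported alongside
for comparison.

Heterogeneity is summarized by Cochran's $Q$ (fixed-effect weights) and
$I^2 = \max\{0, (Q - (k-1))/Q\} \times 100$, the percentage of total
variation attributable to between-study differences rather than chance. Its
confidence interval is the Higgins–Thompson test-based interval on
$\ln H = \tfrac12 \ln\{Q/(k-1)\}$, back-transformed and truncated to
$[0, 100]$. For $k = 2$ with $Q \le k$ the $\ln H$ standard-error formula is
undefined and the non-informative interval $(0, 100)$ is returned — with two
studies and no excess dispersion, the data cannot rule heterogeneity in or
out.

## The composite meta-estimate and its Monte-Carlo interval

With pooled coefficients $\hat\beta_i$ per stratum and standard-population
weights $w_i$ (summing to 1), the age-standardized meta-estimate is

$$ \hat r \;=\; 10^5 \sum_i w_i\, e^{\hat\beta_i}. $$

The combined-sexes figure weights sex-specific stratum coefficients by
sex-specific population counts; this population-weighted combination is a
design choice (a simple mean of the sex estimates is the main alternative)
and is the one `run_pipeline()` reports.

The interval replaces each $\hat\beta_i$ with draws
$\beta_i \sim N(\hat\beta_i, \hat\sigma_i^2)$, independent across strata,
recomputes $\hat r$ per draw, and reports empirical percentiles
(order-statistic percentiles with linear interpolation — R's type-7
quantile). $\hat\sigma_i$ is the standard error of the pooled random-effects
coefficient, so between-study variance flows into the interval through the
pooling weights. The default is $10^6$ draws per stratum; at that size the
endpoints of a single-stratum composite match the closed-form lognormal
quantiles to well under 0.5% and endpoint variation across seeds is below
0.2%, which is what the acceptance tests assert. Draws are generated
stratum-by-stratum so memory stays flat in the number of strata.

Two properties worth noting. First, $\hat r$ is a convex combination of
exponentiated coefficients, so it is strictly increasing in every
$\hat\beta_i$. Second, $E[e^{\hat\beta}] = e^{\beta + \sigma^2/2}$: the
composite carries a positive Jensen bias of order $\hat\sigma_i^2/2$,
negligible when strata pool several large studies
($\hat\sigma^2 \lesssim 0.02$ gives < 1%) but never exactly zero. The
end-to-end recovery test therefore checks that the bias is small relative to
the estimator's own Monte-Carlo spread (within three standard deviations of
the replicate distribution) rather than asserting exact unbiasedness, which
the estimator does not possess.

## Person-time prevalence for a closed cohort

A fixed cohort followed for decades (entry in midlife, follow-up to death)
yields, within an age stratum $[a, b)$, person-years
$\mathrm{py}_s = |[e_s, x_s] \cap [a, b)|$ for each subject $s$ with entry
age $e_s$ and exit age $x_s$, and case-years
$\mathrm{cy}_s = |[\max(d_s, e_s), x_s] \cap [a, b)|$ for subjects diagnosed
at age $d_s$ (diagnosis is treated as absorbing; a diagnosis before entry
marks the subject prevalent at entry). The prevalence is
$10^5 \sum_s \mathrm{cy}_s / \sum_s \mathrm{py}_s$. Ages are reals; stratum
bounds follow the same closed-open convention as the count tables, so the
"65–74" stratum is $[65, 75)$. Person-years are exactly additive over any
partition of age, which the tests assert to $10^{-9}$.

Because years contributed by one subject are strongly dependent, Poisson
intervals are inappropriate; `pt_bootstrap_ci()` resamples *subjects* with
all their person-time, recomputes the rate per replicate (default 10,000),
and reports the percentile interval. Replicates that happen to contain no
person-time in the stratum are redrawn, up to a capped number of attempts.
BCa or studentized variants were not implemented: the estimator is a smooth
ratio, and the validation suite checks that the percentile method's
empirical coverage over 600 synthetic cohorts lies within [0.92, 0.97] at
nominal 0.95.
The ambiguity between age-time and calendar-time windows is resolved in
favour of age-time overlap, matching the stratified reporting of the other
estimators.

## What the simulators emulate — and what they do not

`simulate_multistudy()` draws, per study × stratum, a study effect
$\delta \sim N(0, \tau^2)$ on the log-prevalence scale and then cases
$\sim \mathrm{Poisson}(n\,e^{\beta + \delta})$, truncated at the denominator
— exactly the heterogeneity-plus-sampling structure the meta-engine assumes,
with the Poisson choice consistent with the $v = 1/x$ variance (a binomial
option exists for sensitivity checks). `simulate_cohort()` gives each subject
a uniform (or fixed) entry age and independent exponential onset and death
times, censored administratively.

Passing tests on these data show that the estimators recover the parameters
of their own model; they do not validate robustness to what real studies
add: diagnostic misclassification, incomplete ascertainment (one source
study's algorithm has ~72% sensitivity, so such estimates are minimum
prevalences), correlated ascertainment between studies sharing a region, or
non-exponential onset hazards. Those are explicitly out of scope for the
generators.

## Numerical and design choices

* **Stratum encoding.** Closed-open intervals $[lo, hi)$, exclusive upper
  bound stored (label "65–74" ⇒ `age_hi = 75`), `Inf` for the terminal
  open stratum. Rebinning 5-year to 10-year strata is exact summation;
  strata that straddle a bin boundary, or bins only partially tiled, are
  errors — counts are never interpolated.
* **Seeds.** Every stochastic routine takes an explicit seed and records it
  in its result object and output files; simulators derive their streams by
  sequential draws under a single `set.seed`. Pipeline outputs also embed
  the md5 of the config file, and a rerun of the same config is
  byte-identical.
* **REML convergence.** `metafor`'s Fisher-scoring iteration with its
  default relative threshold; the suite verifies agreement with the grid
  oracle to $10^{-4}$ absolute in $\tau^2$ across 50 random instances, and
  $k = 1$ cells short-circuit to the single study's effect with $\tau^2 = 0$
  and heterogeneity marked not computable.
* **Validation problem sizes.** The end-to-end recovery scenario uses 5
  studies with stratum denominators of $2\times10^6$ and age-rising true
  prevalences 0.1%–2.5% over strata 45–54 … 85+: administrative-database
  scale, where the $v = 1/x$ approximation is accurate. With small
  denominators (tens of thousands) the noisiness of $1/x$ itself inflates
  null $Q$, which tests the variance approximation rather than the
  pipeline. Coverage checks use 1,000 simulated tables (gamma interval),
  600 cohort replicates × 1,000 bootstrap replicates (person-time), and 200
  pipeline replicates per heterogeneity level.
* **Degenerate inputs.** Zero total cases: standardized rate 0 with a valid
  gamma upper bound. All-zero standard population: rejected. Empty study
  file with a header: empty table, not an error. Cohort stratum with no
  person-time: explicit undefined-rate error.

## Limitations

The pipeline estimates prevalence *as ascertained*; it has no model for
under-ascertainment and its composite should be read as a minimum. The
meta-model assumes independent studies — overlapping catchment populations
would understate uncertainty. Projections apply current stratum rates to
future population structures and carry no interval, since rising incidence
or falling mortality would shift the rates themselves. The $I^2$ interval
is test-based, not likelihood-based; with very few studies it is wide by
construction and the package reports it rather than hiding it.
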