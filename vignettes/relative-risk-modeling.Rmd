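---
title: "Estimating relative risks for common binary outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating relative risks for common binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskratio)
```

## The problem

Epidemiological studies of a binary outcome usually want the **relative
risk** (RR): the probability of the event among the exposed divided by the
probability among the unexposed. Logistic regression, the default tool for
binary outcomes, does not estimate it. Its exponentiated coefficients are
**odds ratios** (OR), and the two measures agree only when the outcome is
rare. On any 2×2 table with cells $a, b$ (exposed, with/without event) and
$c, d$ (unexposed) the two are linked *exactly* by

$$\mathrm{OR} = \frac{1 - c/(c+d)}{1 - a/(a+b)} \times \mathrm{RR},$$

so the OR overstates an RR above 1 (and understates one below 1) by a
factor that grows with the event probabilities. At the ≤10% incidence
conventionally called "rare" the factor is negligible; at the incidences
common in cohort studies and trials it is not. The package's built-in
132-patient breast-cancer example (five-year mortality by histological
type, overall incidence 48.5%) has OR = 5.13 against RR = 1.97 — an
inflation factor of 2.60.

`riskratio` provides the estimators needed to report risks rather than
odds, and a simulation harness that quantifies when the distinction
matters.

## Models

Three regressions share one IRLS engine (`irls_fit()`), distinguished by
link and working likelihood:

| model | link | working family | exp(coef) |
|---|---|---|---|
| logistic | logit | Bernoulli | OR |
| modified (robust) Poisson | log | Poisson | RR |
| log-binomial | log | Bernoulli | RR |

**Modified Poisson regression** treats the 0/1 outcome as if it were a
Poisson count with $\log p = B_0 + B_1 x_1 + \dots + B_k x_k$. The point
estimates are consistent for the log RR, but the Poisson working variance
$p$ exceeds the true Bernoulli variance $p(1-p)$, so model-based standard
errors are conservative. The HC0 sandwich covariance

$$(X'WX)^{-1}\Big[\textstyle\sum_i x_i x_i' (y_i - \mu_i)^2\Big](X'WX)^{-1}$$

repairs this and is therefore mandatory by default in
`fit_modified_poisson()`. For the saturated one-binary-predictor model the
robust SE of the exposure coefficient collapses algebraically to the
closed form $\sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$ — the same expression
the 2×2 estimator `relative_risk()` uses — and the test suite asserts that
identity to $10^{-10}$.

**Log-binomial regression** models the same $\log p$ but with the correct
Bernoulli likelihood. It is slightly more efficient when it works, but its
parameter space is constrained ($p \le 1$), and maximum likelihood
frequently fails on that boundary, especially with continuous covariates.
The engine step-halves towards the interior and reports an honest
`converged = FALSE` (a structured result, not an exception) when the
boundary wins; `fit_log_binomial()` then advises the modified Poisson
model.

**Choice of reference category matters for RRs.** The OR is reciprocal
under outcome relabelling — model survival instead of death and every
logistic coefficient just changes sign. The RR is not: on the worked
example the death RR is 1.97 while the survival RR is 0.384, not
$1/1.97 = 0.507$, and in extreme cases the two analyses can disagree on
statistical significance. `run_reciprocity()` demonstrates both behaviours.

Inference throughout is Wald on the log scale with the exact normal
quantile (1.959964 at 95%), and two-sided p-values against a ratio of 1.
Zero cells in 2×2 tables are a hard error naming the offending cell;
`correction = TRUE` opts into the Haldane–Anscombe +0.5 adjustment and
flags the estimate as corrected — silent correction hides data problems.
The Mantel–Haenszel pooled RR uses the Greenland–Robins variance for its
interval; for a single stratum it reduces exactly to the crude variance.
Both the OR→RR conversion formula
$\mathrm{RR} \approx \mathrm{OR}/((1-p_0) + p_0\,\mathrm{OR})$ and the
Greenland–Robins variance are standards adopted from the wider
epidemiological literature.

## Numerical choices

IRLS convergence requires a relative deviance change below $10^{-10}$
*and* a per-observation score below $10^{-12}$, with a cap of 100
iterations. The dual criterion is deliberate: deviance flatness alone can
stop a fit ~$3\times10^{-10}$ short of the saturated closed form, and an
*absolute* score bound does not scale — a perfectly converged $n = 10^5$
fit carries $\sim10^{-9}$ of float accumulation in its score. Dividing by
$n$ makes the criterion scale-invariant. Starting values put the
link-transformed outcome mean on the intercept and zeros elsewhere, which
for log links guarantees initial probabilities inside $(0,1)$. Step
halving (at most 30 per iteration) enforces the log-binomial boundary and
guards against overshoot; hitting the halving cap is reported as
non-convergence, never as a clamped "success". Frequency weights enter
both bread and meat of the sandwich, so fitting grouped counts is exactly
equivalent to fitting row-expanded data. The HC0 flavour (no small-sample
factor) is the default because it reproduces the closed-form robust SE
exactly; HC1 is available via `sandwich_covariance(type = "HC1")`.

## The synthetic cohort generator

The multivariable analysis that motivates the package (histology adjusted
for age, grade, lymphocytic infiltration and nodal burden) cannot be
re-derived from published information: only the 2×2 margins of the
132-patient table are public, not the individual covariates.
`generate_cohort()` therefore emulates the *structure*: covariates drawn
per spec, a binary outcome drawn under a log-link true model
$p = e^{B_0 + B_1 x_1 + \dots}$, so that the true RR per covariate is
exactly $e^{B_i}$. `breast_cohort_config()` fixes one such emulation:
histology prevalence 34/132 as observed; age $\sim N(55, 10)$ rounded to
years; grade/infiltration/nodes prevalences 0.35/0.25/0.30; true histology
RR 2; mild covariate RRs (1.10–1.15) and an age slope of 0.003/yr; an
unexposed baseline risk of 0.30 at age 55. The age distribution and
covariate prevalences are invented (no reference distributions exist) and
configurable; the baseline was chosen so the cohort sits in the
common-outcome regime (incidence ≈ 40%, where OR and RR genuinely
diverge) while the largest implied probability stays near 0.91 — below 1
without truncation.

Because the log link is not probability-coherent, arbitrary configs can
imply $p > 1$. The generator caps probabilities at 0.99, records the
truncated fraction in the dataset provenance, and warns when it exceeds
1%: truncation biases the realized RR towards 1 in the affected stratum,
and the artifact surfaces that rather than masking it. What passing tests
on these cohorts shows is that the estimators recover a *correctly
specified* multiplicative risk model; they say nothing about
misspecification, confounding structures beyond the designed ones, missing
data, or censoring, none of which the generator emulates.

## Simulation scenarios

Every stochastic scenario is paired with an exact population quantity so
that Monte-Carlo output is tested against analysis, not against itself:

* `run_inflation()` — the mean fitted OR tracks the closed form
  $\mathrm{OR} = \mathrm{RR}(1-p_0)/(1-p_0\mathrm{RR})$ across a grid of
  baseline risks while the mean fitted RR stays at the truth.
* `run_coverage()` — empirical coverage of the robust 95% interval for
  the log RR sits at nominal level, while the naive model-based Poisson
  interval over-covers (its variance is too large by construction).
* `run_collapsibility()` — a covariate that shifts risk but is
  independent of exposure (hence no confounding) is enumerated exactly
  over the eight-cell joint distribution: the adjusted RR equals the
  crude RR equals the truth, while the population-MLE adjusted OR is
  strictly further from 1 than the crude OR. The designed grid uses
  stratum baselines 0.1/0.4 with RR 2 (stratum ORs 2.25 and 6.0, crude
  OR 3.0, adjusted OR ≈ 4.29); baselines like 0.5 with RR 2 are rejected
  by validation because the exposed stratum risk would reach 1.
* `run_reciprocity()` — per-replicate event-vs-complement fits for both
  models, reporting the joint distribution of significance decisions.

Failed fits (e.g. an empty cell in a rare-outcome replicate) are counted
and excluded from aggregates, never silently dropped. Identical config
plus seed reproduces results exactly.

Default problem sizes in the shipped tests — e.g. 1000 replicates of
$n = 1000$ for coverage, 200 cohorts of $n = 2000$ for parameter
recovery — were chosen as the smallest sizes at which the binomial
Monte-Carlo error bands are tight enough to be informative (a coverage
estimate from 1000 replicates has standard error ≈ 0.7 percentage
points).

## Known limitations

* Only independent observations: no GEE clustering, offsets, or survey
  weights; no penalized or Firth-type estimation for separated data.
* Exact (conditional/mid-p) 2×2 inference and Bayesian intervals are out
  of scope; all intervals are log-scale Wald.
* The Mantel–Haenszel estimator adjusts for one categorical stratifier
  only; several confounders, or continuous ones, need the regression
  models.
* Case-control designs are not handled: the RR is not estimable from
  them, and the package refuses to pretend otherwise.
* The Cox-model-with-robust-variance route to RRs (equivalent under
  constant follow-up) is noted here for completeness but not implemented.

## A worked example

```{r worked}
t2 <- breast_cancer_table()
relative_risk(t2)
odds_ratio(t2)
or_rr_inflation_factor(t2)

cohort <- expand_counts(t2, exposure_name = "mixed", outcome_name = "death")
compare_models(cohort, outcome = "death", exposure = "mixed")
```
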