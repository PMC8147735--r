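---
title: "Measuring socioeconomic inequality in health indicators with concindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring socioeconomic inequality in health indicators with concindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concindex)
```

## The problem and the measure

Household survey programs such as DHS and MICS record, for each
respondent, a sampling weight, an asset-based household wealth index,
and health-related outcomes.  A recurring question in health-equity
monitoring is whether a favorable outcome — here, HIV awareness,
correct transmission knowledge, HIV testing, and condom use among women
aged 15–24 — concentrates among richer or poorer respondents, within a
country and across a region of countries at different income levels.

The package's core statistic is the **concentration index**.  Rank
respondents from poorest to richest and give respondent $i$ the weighted
fractional rank

$$r_i = \frac{W_{<i} + w_i/2}{W},$$

the weighted share of the population that is strictly poorer plus half
her own weight share.  Tied wealth values share one block rank, which
makes the statistic invariant to the input order of tied records.  The
index of an outcome $h$ with weighted mean $\mu$ is

$$CI = \frac{2\,\mathrm{cov}_w(h, r)}{\mu} \in [-1, 1],$$

twice the area between the concentration curve (cumulative outcome share
against cumulative population share, poorest first) and the 45° equality
line.  $CI = 0$ means no socioeconomic gradient; positive values mean
the outcome concentrates among the rich ("pro-rich").  Note the centered
covariance form: it is the standard "convenient covariance" estimator,
equivalently $(2/\mu)\sum \tilde w_i h_i r_i - 1$ with normalized
weights, and it returns exactly 0 for a constant outcome.

### Estimation and inference

`concindex()` estimates $CI$ as the slope of the weighted least-squares
regression of $y_i = 2\sigma_r^2 h_i/\mu$ on $r_i$ (the "convenient
regression"), which is algebraically identical to the covariance form;
the tests enforce agreement to $10^{-10}$ and additionally check the
geometric curve-area route.  The conventional WLS slope standard error
is used for inference: a two-sided z-test at $\alpha = 0.05$ and the
interval $CI \pm 1.96\,se$.  The package does not attempt design-based
(cluster/stratum) variance estimation — primary sampling unit
identifiers are outside its data model — so significance flags on real
survey data should be read as approximate; a respondent-level bootstrap
or a design-aware package is the alternative when PSU structure is
available.

### Bounded outcomes: the Wagstaff normalization

For bounded outcomes the attainable range of the standard index shrinks
as $\mu$ approaches a bound.  With theoretical bounds $(a, b)$ the
package rescales the outcome to $[0,1]$ and divides by $1-\mu_s$, which
in closed form multiplies the standard index by
$\mu(b-a)/((\mu-a)(b-\mu))$ — for a binary outcome, division by
$1-\mu$.  The same factor is applied to the standard error (delta
method, mean treated as fixed).  All four analysis indicators are
normalized by default: the binaries on $(0,1)$ and the 0–4 knowledge
composite on $(0,4)$.  A sample in which the outcome is constant has no
inequality: the index is reported as exactly 0 with no standard error
and no significance claim (this arises naturally in small surveys with
near-universal awareness).

### Classification thresholds

Besides the z-test, each estimate is flagged *relevant* when
$|CI| \ge 0.2$, a conventional screening threshold for a substantively
important degree of inequality, and *pro-rich* by the sign.  Both
$\alpha$ and the relevance threshold are arguments.

## From survey tables to the analysis

`read_survey_table()` reads a comma-delimited respondent table (header
row, `NA`/empty = missing) onto a canonical schema via a `column_map`,
dropping and counting rows with non-positive weights or unparseable
wealth.  Eligibility is women aged 15–24 inclusive
(`filter_eligible()`).  The 0–4 knowledge composite counts correct
answers on the four transmission items; the package's coding decisions,
both configurable, are:

* **"Don't know" counts as incorrect** (`dont_know = "incorrect"`): an
  uncertain answer is not correct knowledge.  The alternative treats it
  as missing.
* **Respondents who never heard of HIV score 0** rather than missing
  (`never_heard = "zero"`): the knowledge questions are skipped for
  them, but lack of awareness is the most extreme form of inadequate
  knowledge, and dropping these respondents would bias the scale upward.

Each indicator is analyzed on its own complete cases (per-indicator
listwise deletion), so per-indicator sample sizes differ — condom use,
asked only of the sexually active, typically has the smallest.

## Intra- versus inter-country analysis

**Within a country** respondents are ranked on the survey's own wealth
index, and weights are rescaled to mean 1 within each country-survey
(the index is invariant to weight scale; the rescaling only fixes
reported effective sizes).  Where a country fields both MICS and DHS,
the records are pooled with their program labels retained.

**Across countries** wealth indices are survey-specific and cannot be
compared directly.  The package (i) min-max rescales the wealth index to
$[0,1]$ within each country and (ii) multiplies by the country's
per-capita GDP at purchasing-power parity, yielding a common ranking
variable in which the richest household of a poor country can rank below
middle households of a rich one.  Min-max (rather than z-scoring) keeps
the product non-negative and monotone within country, composing cleanly
with the multiplicative GDP scaling; z-scoring is available through
`ranking.normalization` for sensitivity analysis, and because only the
induced ordering enters the index, any strictly increasing within-country
transform followed by a positive scale factor gives the same intra-country
ranks.  Weights are rescaled to
sum 1 within each country and multiplied by the country's share of the
regional female 15–24 population, so each country contributes in
proportion to its population, not its sample size.  When an indicator is
absent from some countries, population shares are renormalized over the
countries contributing data.  For a single-country "region" the scaled
ranking is a strictly increasing transform of the within-country one, so
the regional index equals the intra-country index exactly — a useful
consistency check that the tests enforce.

Descriptive tables report weighted means with normal-approximation 95%
intervals ($\pm 1.96\,se$, $se^2 = \sum \tilde w_i^2 (x_i - \bar x)^2$);
near-boundary percentage intervals may exceed $[0,100]$, which is the
cost of the naive approximation.  Optional direct age standardization to
the pooled single-year age distribution is available
(`age_standardize = TRUE`, off by default) to remove purely
compositional age differences between surveys; it is an interpretation
of "age-standardized indicators" rather than a reproduction of any
specific published procedure.

## The synthetic region and what it validates

`simulate_survey()` draws, per country: household wealth (lognormal by
default, $\sigma = 0.8$), sampling weights (mean-1 gamma, shape 4, drawn
independently of wealth and outcomes), and each binary indicator from
the **linear-in-rank model** $P(h=1\mid r) = a + b\,r$, where $r$ is the
respondent's true quantile in the wealth law.  This model is chosen
because it has an exact closed form,

$$CI = \frac{b}{6\mu}, \qquad \mu = a + \tfrac{b}{2},$$

(and $b/(6\mu(1-\mu))$ after Wagstaff normalization), so estimator bias,
interval coverage and type-I error can be measured against analytic
truth rather than against another implementation.  The 0–4 composite is
the sum of four such items, with truth $\sum_j b_j / (6\mu_S)$.

`lac_scenarios()` assembles the default 20-country study region.  Its
parameters are fixed once, from the study setting the package emulates:
per-country survey sizes proportional to the reference survey totals
(rescaled to `n_total`, default 20,000 — small enough that the full
pipeline runs in about a second, large enough that the regional
estimates are stable to two decimals), indicator prevalences and
within-country Wagstaff gradients encoding the reference setting
(non-significant cells get slope 0; indicators a survey lacked are
absent, e.g. condom use in Argentina), and plausible World-Bank-era
GDP-PPP values and female 15–24 population shares.  Two honest
limitations of this emulation:

* The linear probability model cannot represent the steepest reference
  gradients for near-universal outcomes (awareness above ~97%): the
  slope is capped at the feasibility bound $1.96\min(\mu, 1-\mu)$ so
  probabilities stay inside $(0,1)$.  Regional awareness inequality is
  therefore somewhat attenuated relative to the setting it emulates.
* Missingness is completely at random (5% testing, 42% condom use, the
  latter mimicking the sexually-active skip pattern), and there is no
  multi-stage cluster geometry.  Passing tests therefore demonstrate
  estimator correctness and pipeline integrity, not robustness to
  informative missingness or design effects in real microdata.

## Numerical and degenerate-input conventions

* Ties in the ranking variable: tied-block mean rank, deterministic and
  permutation-invariant.
* Constant ranking variable (a single household value): rank variance is
  zero and estimation stops with an error; constant *outcome*: index 0,
  no inference (see above).
* $\mu = 0$ (or $\mu$ on a Wagstaff bound with a non-constant outcome):
  the index is undefined and the fit errors rather than returning a
  misleading number.
* Negative outcome values are accepted by the covariance/regression
  routes (the formula is well-defined) but rejected for concentration
  curves, where the share interpretation fails.
* The 95% interval uses the conventional 1.96 multiplier; the
  significance test uses the exact normal quantile for the requested
  $\alpha$.
* All simulation seeds are explicit arguments; a region derives
  per-country seeds deterministically from one master seed.

## Problem sizes used in validation

The test suite validates the estimator at the scales where its
properties are measurable at interactive speed: exact-agreement checks
on 1,000 randomized instances of 3–500 observations; closed-form
recovery at $n = 200{,}000$ and a bias grid (14 valid $(a,b)$ cells,
12 replicates of $n = 50{,}000$ each, bias below 0.01); type-I error
over 1,000 null replicates and interval coverage over 500 replicates at
$n = 2{,}000$; and the full 20-country pipeline at 20,000 respondents.

## Worked example

```{r example, eval = FALSE}
library(concindex)

# a synthetic two-country region with a known between-country gradient
scs <- list(
  country_scenario("Poorland", 2000, pc_gdp_ppp = 5000,  pop_share = 0.5,
                   heard = c(0.30, 0.2)),
  country_scenario("Richland", 2000, pc_gdp_ppp = 20000, pop_share = 0.5,
                   heard = c(0.60, 0.2)))
sim <- simulate_region(scs, seed = 1)

# within-country inequality
fit <- concindex(heard ~ wealth, data = subset(sim$records, country == "Poorland"),
                 weights = weight)
fit
plot(fit)   # concentration curve

# regional inequality on the GDP-scaled ranking
inter_country_summary(sim$records, sim$meta, indicators = "heard")
```

## Limitations

The package measures bivariate rank inequality; it does not decompose
the index into contributing factors, implement the Erreygers correction
or extended (inequality-aversion) indices, construct wealth indices from
assets, or estimate design-based variances.  GDP-PPP and population
shares are user-supplied constants per country: no exchange-rate or
demographic modeling is attempted.
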