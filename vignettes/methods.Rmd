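---
title: "Methods: from tax-benefit reform to health value"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tax-benefit reform to health value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`bisim` estimates the population-health consequences of Basic Income (BI)
reforms by composing five stages, each usable on its own. This vignette is
the package's account of the science: the models, the assumptions they
lean on, the parameters that matter, and the places where the design was
genuinely open and a choice had to be made.

## The income-health model

The statistical core is a within-between (Mundlak) panel regression. For
person $i$ at wave $t$, with $x_{it}$ the transformed net equivalised
monthly household income and $\bar x_i$ its person mean over waves,

$$y_{it} = \alpha + \beta_w (x_{it} - \bar x_i) + \beta_b \bar x_i +
\gamma' z_{i} + u_i + \varepsilon_{it},$$

where $y$ is an SF-12 component summary score (MCS for mental, PCS for
physical health, both on a 0-100 scale), $z_i$ are controls, $u_i$ a
person-level random intercept. Splitting income into a deviation and a
mean component separates two very different quantities: $\beta_w$ captures
the effect of transitory income fluctuations, $\beta_b$ the association
with a person's durable income level, which also absorbs relative-position
(inequality) effects. A BI is a *permanent* change in income levels, so
the forecasting stage uses $\beta_b$ only; $\beta_w$ is estimated and
reported but deliberately not used to project reform effects.

Assumptions worth stating plainly: the model is linear in transformed
income (the default transform is $\log(\max(\text{income}, 1))$, encoding
the concave income-health relationship the literature supports; the GBP 1
floor makes zero incomes representable); the between association is
treated as causal and fully reversible when projecting reforms; and
controls are exogenous given the random intercept.

Two estimators are provided. `random_effects` fits the Mundlak-equivalent
formulation with `lme4::lmer`; `pooled_ols_clustered` fits the same mean
equation by OLS with person-clustered (CR1) standard errors computed in
the package and cross-checked against `sandwich::vcovCL` in the test
suite. On balanced panels the two give essentially identical income
coefficients (a property the tests assert on noise-free data); the OLS
path is the bootstrap workhorse because it refits in milliseconds.

Confidence intervals are percentile bootstrap intervals from resampling
*individuals with all their waves* (the person is the sampling unit,
never single waves), 1,000 repetitions by default. The percentile method
was chosen because the reference procedure specifies a bootstrap and a
95% level but not an interval construction; percentile bounds are simple,
transformation-respecting and adequate at these sample sizes. Replicates
with rank-deficient designs are dropped and counted; more than 5% dropped
is an error rather than a silent degradation. MCS and PCS bootstraps share
the resampling seed, so replicate $r$ uses the same resampled persons for
both outcomes and downstream quantities that combine the two (QALYs)
propagate their uncertainty jointly.

### The lagged-case control

The reference analysis controls for having been a case in the previous
period. The package implements this (`include_lagged_case = TRUE`: a
binary prior-wave case indicator enters the design and each person's
first wave is dropped), but the *default* is off, and the synthetic
generator's default `lag_coefficient` is 0. The reason is statistical: a
lagged outcome-derived regressor is correlated with the person intercept,
so the random-effects exogeneity assumption fails (dynamic-panel bias)
and estimator recovery of the generator's coefficients would be
confounded by a bias that has nothing to do with implementation
correctness. With the defaults, generator and estimator describe exactly
the same data-generating process, which is what makes the recovery and
coverage tests sharp. The lagged pathway remains available for
sensitivity analysis.

## The synthetic data generator

The generator exists so that every downstream computation can be tested
against known ground truth without licensed survey microdata. It emulates:

- **Household composition**: adults (treated as OECD-definition adults;
  generated as 18+) and children 0-13, with per-household count
  distributions whose means (1.78 adults, 0.33 children) match the
  published cross-section anchors.
- **Demographics**: age band, sex, region, tenure, ethnicity, marital
  status, employment, education drawn from configurable *marginal*
  proportions patterned on published survey tables. The sex mix is
  deliberately configuration, not assertion - the published balanced
  panel reports an unusual 57.7% male share, and the generator takes no
  position on whether that is representative.
- **Incomes**: log-normal gross earnings among the employed
  (cross-section); for the panel, log net equivalised income follows a
  person mean plus a stationary AR(1) transitory deviation
  (`persistence`, `transitory_sd`), giving separately controllable
  within and between variance shares - exactly what the estimator needs
  distinguishable.
- **Health scores**: generated from the linear model above with known
  coefficients (defaults: $\beta_b^{MCS}=2$, $\beta_w^{MCS}=1$,
  $\beta_b^{PCS}=1.5$, $\beta_w^{PCS}=0.6$ points per log-income unit;
  intercepts set so mean scores sit near the published balanced-panel
  means of 50.5/50.2; person sd 6 and occasion sd 6, in line with
  SF-12-scale variability). Scores are clipped to the instrument range
  [0,100]; the clipping rate is recorded and required below 1%, since
  the model is linear but the instrument is bounded.
- **Attrition**: independent per-wave missingness with configurable
  probability (the reference analysis controls for attrition but does
  not describe its process); `make_balanced()` retains the fully
  observed and keeps the exposure flag as a usable control.

What it does *not* emulate - and hence what passing tests do not show
about real data: joint demographic structure (only marginals are
calibrated), item-level SF-12 measurement, informative attrition,
household dissolution and formation across waves, benefit take-up
correlated with characteristics, and regional cost-of-living differences.
Absolute case counts from synthetic runs are demonstrations of the
machinery, not UK forecasts.

## The tax-benefit calculator

The calculator is a stylised, fully parameterised stand-in for a
statutory-scale microsimulation model: one income-tax schedule, one
National Insurance schedule, Child Benefit, the State Pension, and a
Universal Credit (UC) style benefit

$$UC = \max\!\big(0,\; A - \tau \max(0, E - D) - U\big),$$

with standard allowance plus child elements $A$, taper $\tau = 0.55$ on
net earnings $E$ above the work allowance $D$, and unearned income $U$
offset pound for pound. Defaults follow 2023/24 UK values, but the
contract is oracle-equivalence of these simplified rules (asserted
line-by-line against an independently coded brute-force calculator on a
1,000-cell earnings-by-family-type grid), not legal fidelity. Council
tax, housing benefit geography, indirect taxes, sanctions and behavioural
labour-supply responses are out of scope; costs are static.

Reforms pay BI per person by age band (under 18 / 18-64 / 65+), remove
the replaced benefits one for one, and count BI net of a monthly
disregard as UC unearned income. Choices made where the source material
is silent:

- **Disregard**: "a small disregard" is all that is specified; the
  default is GBP 10/month per household (the household is the benefit
  unit throughout), exposed as configuration. A consequence the test
  suite documents honestly: GBP 10 does *not* guarantee that no
  UC-receiving household loses - a household whose UC is exhausted
  mid-absorption still loses Child Benefit, which UC never compensated.
  Such households are flagged (`low_income_loser`), and the tests show
  the flag empties once the disregard covers the largest lost Child
  Benefit.
- **BI taxability**: BI is non-taxable; the schemes are described as
  replacements for non-means-tested benefits, not as taxable income.
- **Take-up**: UC take-up is an independent seeded Bernoulli per entitled
  household (default probability 1; partial take-up is a configuration),
  with the same draw shared between baseline and reform so income changes
  are not polluted by take-up noise.
- **Funding**: none by default (two of the three schemes are explicitly
  not fiscally balanced); an optional flat percentage-point rise on all
  income-tax rates and a personal-allowance shift apply to the reform
  schedule only.
- **Conversions**: GBP/week x 52/12 = GBP/month everywhere; incomes are
  before housing costs.

Distributional statistics are person-weighted: weighted Gini (computed
from the Lorenz form, tested to 1e-12 against the pairwise
mean-absolute-difference formula), quintile cash and percentage gains,
winners/losers bands, relative poverty (share below 60% of the weighted
median equivalised income, median recomputed under reform), and the
annual exchequer cost.

## From income changes to health and value

The cross-sectional population carries no SF-12 scores, and the source
material never states how its reform population acquires them. The
package makes this bridge explicit and seeded: baseline scores are
imputed as the fitted model's linear predictor (at baseline income,
$x_w = 0$) plus a $N(0, \sigma^2)$ draw (`residual_sd`, default 8 score
points, of the order of the model's residual scale), clipped to [0,100].
Reform scores are baseline plus
$\Delta = \beta_b\,(f(\text{income}_{reform}) - f(\text{income}_{base}))$.
Case counting is inclusive at the published cutoffs: MCS $\le 45.6$ is a
depressive-disorder case (45.7 is not), PCS $\le 50$ a physical-health
case. "Prevented or postponed" is operationalised as the net annual
weighted case difference (cures minus newly created cases), which the
tests verify equals person-level transition accounting.

Confidence intervals for prevented cases, QALYs and YLG propagate
*coefficient* uncertainty only: each bootstrap replicate's $\beta_b$
reprices the deltas while the baseline imputation draws stay fixed, and
percentile bounds are taken. Imputation noise is a sensitivity (rerun
with another seed or `residual_sd`), not folded into the CI - matching
how the reference CIs are constructed from the income-model bootstrap
alone.

Valuation choices:

- **SF-6D crosswalk**: the published conversion is proprietary. The
  package uses a transparent linear crosswalk
  $u = a + 0.0050\,\text{MCS} + 0.0098\,\text{PCS}$, slopes in the range
  of published SF-12-to-SF-6D mappings, intercept calibrated so the
  published balanced-panel means (MCS 50.47, PCS 50.18) map to the
  published mean SF-6D of 0.7857; utilities clamp to [0.345, 1], the
  published SF-6D (SF-12) floor and full health.
- **QALYs**: weighted sum of utility changes, treated as an annual
  impact; GBP 30,000 per QALY (NICE upper threshold), with the Green
  Book value obtained by the 2.33 multiplier (70,000/30,000). No
  discounting: impacts are annual flows.
- **Years of life gained**: sex- and age-band multipliers convert QALY
  gains to life expectancy gains. The shipped table is *synthetic*:
  declining with age, slightly higher for women, calibrated so the
  population-average multiplier under the default adult age mix is about
  1.31 - the ratio implied by published aggregate YLG and QALY figures.
  Substantive work should supply a published table.
- **Costs**: unit costs per treated depressive-disorder case are not
  printed in the source material; the defaults are back-derived from the
  published savings and case counts (about GBP 2,040/year NHS and
  personal social services, GBP 9,105/year total), which the tests show
  are mutually consistent across all three schemes within 1%. The 50%
  treated share applies to costs only, never to case counts or QALYs.
  Physical-health cost savings are refused by design: there is no
  comparable unit-cost base.
- **Grossing**: QALY and YLG aggregation grosses over the reform
  (cross-section) population's weights - the population whose incomes the
  reform actually changes; the panel serves only to estimate
  coefficients.

## Numerical and reproducibility choices

Incomes are floored at GBP 1 before the log transform. Zero within-person
income variance makes $\beta_w$ undefined and it is reported as `NA`,
never as zero; collinear designs error naming the offending columns.
One master seed derives stage-specific sub-seeds (bootstrap resampling,
score imputation, UC take-up) via a fixed hash, all below $2^{31}$ and
recorded in the results manifest together with a configuration hash, so
every number in a bundle is reproducible from the manifest alone.
Reports refuse to write any row whose CI bounds do not bracket the
central estimate. Stage outputs can be cached keyed by configuration
hash; the bootstrap refits dominate runtime.

Problem sizes used by the package's own test and acceptance runs - chosen
as the smallest sizes at which the statistical properties are sharp:
panels of 2,000 persons by 12 waves for recovery and coverage (50 and 100
replicates at 200 bootstrap repetitions), cross-sections of 1,000
households grossed to 53 million people for end-to-end runs, and 10
seeded 200-household populations for the scheme-generosity monotonicity
suite.

## Known limitations

The calculator is stylised, not statutory; absolute exchequer costs and
poverty rates depend on the synthetic income distribution and should not
be read as UK estimates. The between-coefficient projection assumes the
cross-sectional income-health association is causal and symmetric for
income gains. The SF-6D crosswalk is linear where the true scoring is
not. The imputation bridge adds a modelling layer the reference analysis
may not have needed; its seed and sd are exposed precisely so its
influence can be measured. Comorbidity between the two outcomes is not
modelled - cases are counted independently per outcome.
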