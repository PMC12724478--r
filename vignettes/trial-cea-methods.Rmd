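---
title: "Methods: trial-based cost-effectiveness analysis with net-benefit regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis with net-benefit regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## The problem this package addresses

`trialcea` implements a within-trial economic evaluation of a three-arm
randomised trial — the setting is automated feedback after internet-based
depression screening (arms: no feedback, nontailored feedback, tailored
feedback), but every component is parameterised and reusable for similar
short-horizon trials. The evaluation asks: given per-participant costs and
health effects observed over a 180-day follow-up, is each feedback arm
cost-effective relative to its comparators, and how does the answer depend on
the willingness-to-pay (WTP) for a unit of health effect?

The pipeline runs participant-level records through five stages:

1. **Outcome construction** — utility indices, QALYs, VAS-QALYs,
   depression-free days (DFD), PHQ-9 severity bands;
2. **Costing** — resource-use quantities priced with a unit-cost table,
   productivity losses valued by the human capital approach, aggregated under
   a societal or payer perspective;
3. **Multiple imputation** — chained equations over the incomplete table,
   m completed copies;
4. **Estimation** — pairwise incremental costs and effects pooled by Rubin's
   rules, ICERs with dominance classification, net-benefit-regression CEACs;
5. **Scenarios and subgroups** — deterministic sensitivity analyses S1–S5 and
   explorative subgroup curves.

A synthetic-trial generator with known ground-truth arm effects makes the
whole chain testable end to end without access to any real trial data.

## Effect measures

### QALYs under a linear trend

With utility indices $I_{T0}$ and $I_{T3}$ measured $\Delta d$ days apart and
health-related quality of life assumed to change linearly between the two
assessments, the QALYs accrued over the 180-day horizon are

$$\mathrm{QALY} \;=\; \Big[\, I_{T0} + \tfrac{I_{T3}-I_{T0}}{2}\cdot\tfrac{180}{\Delta d} \,\Big]\cdot\tfrac{1}{2}.$$

The slope term rescales the observed change to the 180-day horizon (the
package applies the formula verbatim for any $\Delta d > 0$ and flags
intervals outside 90–365 days); the final factor $1/2$ converts the half-year
horizon into years. When $\Delta d = 180$ the expression reduces to the mean
of the two indices times $0.5$, so its ceiling for indices bounded by 1 is
half a QALY. No discounting is applied — the follow-up is only six months.
VAS-QALYs (scenario S1) apply the identical formula to EQ VAS/100; the
substitution is the only reading consistent with a common QALY scale.

### EQ-5D-5L scoring

`score_eq5d()` evaluates either a full 3125-row lookup table or an additive
decrement scheme (per-dimension, per-level coefficients). The published
German value set is deliberately **not** bundled; the package ships a
clearly-labelled synthetic additive set
(`inst/extdata/value_set_synthetic_de.csv`) that reproduces only the
published range $[-0.661, 1]$, with profile $(1,1,1,1,1)$ at the ceiling and
$(5,5,5,5,5)$ at the floor. Users analysing real data should supply the
licensed value set as a delimited file; the reader auto-detects the dialect
from the header.

### Depression-free days

Scenario S5 replaces QALYs with depression-free days derived from PHQ-9
totals at T0, T2 and T3. The trajectory through the three points is piecewise
linear; DFD is the measure of days in $[0, 180]$ on which the interpolated
score satisfies the depression-free rule, computed *exactly* from segment
threshold crossings (never by day sampling; the test suite checks agreement
with a $10^4$-point discretisation oracle to below half a day).

Two deliberate choices, both configurable:

* **Rule.** The default binary rule counts a day as depression-free iff the
  interpolated score is strictly below 5 — the boundary of the *minimal*
  severity band (0–4), the natural anchor given that the severity bands are
  the only symptom thresholds the instrument defines. Whether the original
  DFD construction was binary or graded is not decidable from the source
  material, so a graded rule (linear credit between a lower and an upper
  score, default 5 and 10) is provided as an alternative; neither is claimed
  to be the trial's certain intent.
* **Extension.** Assessment days are jittered by up to ±14 days, so T3 can
  fall short of day 180. Beyond T3 the last observed score is carried
  forward rather than extrapolated with the last segment's slope:
  slope extrapolation would let an *increase* in the T2 score *increase*
  DFD (a steeper downward extension), violating the monotonicity any
  symptom-day measure should have. The constant extension preserves
  monotonicity, is the conservative last-observation-carried-forward
  convention, and the two choices differ only over the small jitter window.

## Costing

Costs are `quantity × unit cost` per category (inpatient days, outpatient
physician/psychotherapist/non-physician contacts, formal and informal care
hours, medication packs), with prices adjustable to a reference year through
consumer-price-index ratios. Productivity losses are absence days times the
gross daily wage (human capital approach); the wage is a required input
(default €150/day, a round figure near the German average gross wage) because
no wage is printed in the source material. Direct costs accruing in the short
window between randomisation and the post-baseline survey belong to the
post-period, since the intervention occurs immediately after randomisation;
indirect costs assessed at baseline stay pre-period.

Perspectives: *societal* sums all seven direct categories plus indirect
costs; *payer* excludes informal care from the direct sum and — by
construction, though configurable — excludes indirect costs entirely, since a
health-care payer reimburses neither. Payer totals therefore never exceed
societal totals.

## Missing data

`impute_chained()` is the package's own chained-equations engine: every
analysis variable predicts every other (full predictor matrix), cycling 10
iterations by default, m = 10 completed datasets. Numeric variables use
predictive mean matching with Bayesian parameter draws — donors are observed
values, so right-skewed costs can never be imputed negative and integer
scores stay integer; two-level factors use a Bayesian logistic draw. A ridge
of $10^{-6}$ on the cross-product diagonal stabilises near-collinear dummy
blocks. One master seed spawns a per-imputation stream (`seed + i`), so
increasing m never changes the earlier imputations.

Pooling follows Rubin's rules: point estimate = mean; total variance
$T = W + (1 + 1/m)B$; degrees of freedom by the Barnard–Rubin small-sample
formula. One numerical special case: when $B = 0$ exactly (for example, m
copies of a complete dataset), the df is set to the complete-data df so that
pooled inference coincides *exactly* with the single-dataset analysis; the
Barnard–Rubin limit as $B \to 0$ is $\nu_{com}(\nu_{com}+1)/(\nu_{com}+3)$,
which would leave a spurious $\sim 10^{-5}$ discrepancy on the p-value scale.

## Estimation

**Incremental costs and effects** per pairwise comparison are
difference-in-means OLS coefficients on the arm indicator, computed per
completed dataset and pooled; p-values are two-sided from the pooled t
reference. **ICERs** are $\Delta C / \Delta E$ with dominance handled first:
dominant iff $\Delta C < 0 \wedge \Delta E > 0$, dominated iff
$\Delta C > 0 \wedge \Delta E < 0$; a zero effect difference yields no ratio.
South-west-quadrant ratios (cheaper, less effective) are reported with an
explicit label because a bare ratio is ambiguous there: below the WTP it
argues *for* accepting the effect loss.

**CEACs** come from monetary net-benefit regressions. Participant-level net
benefit at WTP $\lambda$ is $NB = \lambda E - C$ (the standard monetary
form); regressing it on the treatment dummy gives a slope equal to the
incremental net benefit, decomposing exactly as
$\lambda\,\Delta E - \Delta C$. The curve value at $\lambda$ is the pooled
one-sided exceedance probability $P(\text{slope} > 0)$ from the pooled t
statistic. The base grid is €0–€160,000 per QALY in €10,000 steps (17
points); S5 uses €0–€200 per DFD in €10 steps (21 points — the source range
with a step chosen to match the base grid's resolution) with the €15/DFD
anchor marked. A nonparametric within-arm bootstrap CEAC (2000 resamples) is
provided as a cross-check; on synthetic data at 300 per arm the two routes
agree within a percentage point.

When both $\Delta C$ and $\Delta E$ are negative the curve slopes downward
in $\lambda$: the effect loss weighs more heavily as WTP rises. The test
suite verifies this, the calibration $P = 0.50$ at the break-even
$\lambda^* = \Delta C / \Delta E$, and the identity of the curve at
$\lambda = 0$ with the probability of cost saving.

**Scenarios.** S1 swaps in VAS-QALYs; S2 and S4 are row selectors (extended
sample re-including previously excluded participants; primary-analysis
sample) carried as flags on the table; S3 switches to the payer cost totals;
S5 switches to DFD. No multiple-testing adjustment is applied across the
three pairwise comparisons or the subgroups — the subgroup analyses are
explorative by design. Age subgroups use rank-based terciles (ties broken by
record order) so the three groups are equal to within one participant even
though ages are recorded to 0.1 year.

**Baseline balance** uses Welch's unequal-variance t for continuous and
chi-square for categorical variables, per variable and arm pair; the tests
are descriptive checks of randomisation, so again no adjustment.

## The synthetic-trial generator

`generate_trial()` emulates the study conditions: arm sizes 343/338/331;
baseline PHQ-9 truncated-normal on [10, 27] with realised mean 14.77 (SD
4.00) — the screening threshold truncates at 10; baseline utility index
truncated-normal on [−0.661, 1] with realised mean 0.69 (SD 0.25); EQ VAS
57.44 (21.93); per-category follow-up costs gamma-distributed with
shape $(\text{mean}/\text{SD})^2$ calibrated to the no-feedback arm's
published category means — shapes far below 1 reproduce the heavy right skew
(SD above the mean in every category); pre-period costs are the same
composition rescaled to the published baseline total (€4,528). Truncated
draws are calibrated by solving for the nominal mean whose *truncated* mean
equals the configured target, so configured moments are realised moments.

Ground-truth arm effects are part of the configuration: cost shifts enter
multiplicatively (every category's gamma scale is inflated by
$1 + \text{shift}/\text{total}$, making the expected total-cost difference
exactly the configured shift), and QALY shifts enter as a $4\times$ index
shift at T3 (the QALY formula quarters it), inflated by ~8% to offset
first-order attenuation from the utility ceiling at 1 — the point mass at
index 1 is itself a deliberate feature, mirroring the ceiling effect of real
utility data. Defaults mirror the reported arm contrasts (+€372/−€597 and
−0.002/−0.006 QALYs versus no feedback). PHQ-9 follow-up drifts (−1.7 at T2,
−4.1 at T3, noise SD 4.5) put roughly 9/33/31/18/9 percent of participants
into the five severity bands at T3. Assessment days are 30 ± 7 and 180 ± 14.

Missing-at-random masking drives each cell's missingness probability through
a logistic model in always-observed covariates only (arm, age, gender), with
the intercept solved per variable so the mean probability hits the target
rate exactly. Sixteen of the table's 33 data columns are eligible (follow-up
outcomes, post-period resource use, absence days, the SCID flag); at the 9%
per-variable default this yields ~4.3% of all cells missing. Arm, id,
baseline PHQ-9 (the stratification variable) and the MAR covariates are
never masked, so the mechanism is verifiably MAR: a logistic fit of the
missingness indicator on the withheld true value plus covariates recovers a
null coefficient on the true value.

What the generator does **not** emulate: the recruitment funnel, item-level
questionnaire responses, dimension-level EQ-5D profiles (indices are drawn
directly; profile synthesis would add nothing the pipeline consumes),
medication heterogeneity (one price per pack), or any nonbinary-stratum
effect structure. Passing end-to-end tests therefore certifies the
*machinery* — unbiased recovery of known contrasts through missingness and
imputation — not distributional fidelity to any real dataset.

## Numerical choices and degenerate inputs

* Costs are kept at full precision; rounding to whole euros happens only in
  reports.
* `icer()` handles all nine sign combinations, including the axes; the test
  suite checks them against a sign-table oracle.
* A CEAC on a single complete dataset skips pooling (m = 1 path) and uses
  complete-data t inference; `pool_rubin()` flags the all-degenerate case
  (total variance 0) instead of dividing by zero.
* Constant variables in balance tests are skipped with a flag; subgroup
  levels with an empty arm are skipped with a warning.
* PMM uses k = 5 donors, found via one sort of the observed predictions and
  a 2k-neighbourhood around each target's insertion point.
* Problem sizes in the validation suite: the null-difference and MAR checks
  run at 2000–3000 per arm; the CEAC calibration uses $10^4$ Monte-Carlo
  replications at 300 per arm; the full-pipeline recovery study runs 100
  replications of the complete chain (n = 1012, m = 10, 5 sweeps — sweeps
  beyond the first few change nothing at 4.3% missingness, and the package
  default remains 10).

## Known limitations

* The chained-equation engine is single-level: no multilevel imputation, no
  congeniality diagnostics beyond the imputation-model record.
* DFD and QALY constructions assume linear change between assessments; with
  only three PHQ-9 points this is an assumption, not an estimate.
* The dominance/CEAC machinery is two-arm at a time; it does not compute a
  three-way efficiency frontier.
* No lifetime extrapolation, no discounting, no value-of-information
  analysis, no covariate-adjusted net-benefit regression (the dummy-only
  model is deliberate, matching the analysis it re-implements).
* The unit-cost and value-set tables bundled for examples are synthetic
  stand-ins; substantive analyses must supply the real catalogues.
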