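---
title: "Modelling the cost-effectiveness of lifestyle counselling for the metabolic syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of lifestyle counselling for the metabolic syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metscea)
```

## The evaluation problem

Primary-care lifestyle counselling programs for patients with the metabolic
syndrome improve risk factors (weight, waist circumference, blood pressure,
lipids, fasting glucose) over a follow-up of about a year. Whether those
improvements are worth the program's cost depends on their long-term
consequences — fewer cases of type 2 diabetes (T2D) and cardiovascular
disease (CVD), fewer early deaths, fewer disease-related costs — which no
12-month trial observes directly. `metscea` closes that gap the standard
health-economics way: a Markov microsimulation extrapolates each patient
group's risk-factor levels into lifetime health outcomes, once using the
levels measured at program start and once using the levels at 12 months, and
the difference between the two simulated futures is attributed to the
program. The comparator is do-nothing, assumed to carry zero costs and zero
health effects, so increments equal the program's own effects.

Because primary-care patients are heterogeneous, the package stratifies them
before modelling. Patients are assigned to low / medium / high risk groups by
counting how many of the five consensus metabolic-syndrome criteria they
meet — central obesity (waist ≥ 94 cm men / 80 cm women), triglycerides
≥ 1.7 mmol/L, HDL < 1.03 / 1.29 mmol/L, blood pressure ≥ 130/85 mmHg,
fasting glucose ≥ 5.6 mmol/L or diagnosed T2D — with fewer than two criteria
low, exactly two medium, three or more high. All five criteria count equally;
central obesity is one of the five, not a prerequisite, which is what the
"three or more criteria" grouping rule implies. The thresholds live in
`mets_thresholds()` configuration, not in code.

## The disease model

Seven health states: `WELL`, `T2D`, `T2D_COMPL` (diabetes with
complications), `CVD` (including stroke), `T2D_CVD` (both disease families),
and two absorbing death states (`DEAD_DISEASE`, `DEAD_OTHER`). Recovery
transitions do not exist; the permitted transitions form a DAG plus
self-loops. Cycles are one year; simulation stops at age 85, after which no
effects or costs accrue.

Annual transition hazards follow a proportional-hazards form

$$ h_k(\text{age}, \text{sex}, x) \;=\; h_{0,k}(\text{age}, \text{sex}) \cdot
   \exp\!\Big(\sum_j \beta_{kj}\,(x_j - \bar x_j)\Big), $$

with age-banded baseline tables $h_{0,k}$ per transition and sex, and
coefficients $\beta$ per unit of each risk factor centred at a reference
profile $\bar x$. Within a cycle, competing risks convert hazards to
probabilities: total exit probability $1 - e^{-H}$ with
$H = \sum_k h_k + h_{\text{other}}$, apportioned by cause-specific hazard;
the self-loop takes the remainder. Other-cause mortality comes from a
Gompertz-shaped life table.

The entire parameter set — baselines, coefficients, reference profile, life
table, quality-of-life weights, state costs — ships as a YAML file
(`inst/extdata/model_params.yaml`) and is loaded by `load_model_params()`.
The defaults are the package's own plausibility-oriented parameterization,
with baseline shapes and coefficient magnitudes inspired by published CVD and
T2D risk scores (e.g. systolic pressure, total and HDL cholesterol and
smoking driving CVD onset; fasting glucose and adiposity driving T2D onset).
They are deliberately not presented as estimates of any particular
population, which is why the package **calibrates** them before use:
`calibrate_baseline_hazards()` scales all disease hazards by a common factor
chosen by bisection so that every risk group's expected years of life lost
(YLL) before 85 falls in a plausible band, 4–9.7 years by default, matching
the magnitude a high-risk primary-care population experiences. The admissible
factor closest to 1 is used, so an already-plausible parameter set is left
untouched. Consequently *absolute* QALY/cost levels produced by the default
engine are illustrative; the package's claims live in differences, orderings
and arithmetic, which is also what the test suite asserts.

Per cycle, a simulated individual accrues
$\text{QALY}_t = q(\text{age}) \cdot m(\text{state}) \cdot (1+r)^{-t}$
(age-indexed population weight times a state utility multiplier, discounted)
and a state cost by perspective (societal ≥ healthcare), also discounted at
annual rate $r$ (default 3%, sensitivity 0% and 5%). Death before 85
contributes $\text{YLL} = 85 - \text{death age}$. No half-cycle correction is
applied — accrual happens at the end of each annual cycle, the simplest
convention consistent with a one-year cycle; at these horizons the choice
shifts levels, not differences.

### Intervention arm and sustainability

Group-level simulations use the group's mean risk-factor profile and mean
baseline age; the same starting age is used in both arms so age effects
cancel. The comparator arm keeps start levels for life. The intervention arm
follows $x(t) = x_{\text{start}} + w(t)\,(x_{12m} - x_{\text{start}})$, where
the sustainability weight $w(t)$ encodes how long the 12-month improvement
persists: the base assumption retains it fully through year 2, then decays
*linearly* to zero by year 5 ("gradual decrease" is not otherwise specified,
and linearity is the parsimonious reading); the `low` scenario keeps it for
year 1 only; `high` keeps it for life. Weights are evaluated at integer
cycles — with one-year cycles there is nothing to interpolate within.
Smoking and diagnosis flags are not modulated by $w(t)$: no 12-month change
is measured for them. After washout the base case returns exactly to start
levels; we do not add secular drift of risk factors with age, so the
comparator and intervention arms stay interpretable as "the program's effect
only".

### Common random numbers and reproducibility

The two arms of a group share per-individual uniform streams and
initial-state draws (common random numbers). With a null effect
($x_{12m} = x_{\text{start}}$) the paired difference is *exactly* zero, and
in general Monte-Carlo noise largely cancels from the deltas. Group-level
runs treat the group smoking rate as a fractional covariate of the "average
individual" rather than drawing smoker status per individual; this keeps the
microsimulation and the deterministic cohort expectation (below) on exactly
the same hazard structure. Diagnosed-diabetes and previous-MI rates enter as
initial-state probabilities (Bernoulli in the microsimulation, an occupancy
mixture in the expectation). All randomness derives from one master seed.

### The deterministic oracle

`cohort_expectation()` propagates a state-occupancy vector through the same
per-cycle transition matrices the microsimulation samples from, producing the
exact expectation the microsimulation converges to. It exists for three
reasons: as an independent check on the stochastic engine (the test suite
requires agreement within 3 Monte-Carlo standard errors on several parameter
sets), as the fast inner loop of calibration, and as the noise-free way to
assert *orderings* (sustainability, discount-rate, risk-group) that finite
simulations can violate by Monte-Carlo noise even under common random
numbers — a trajectory change reorders the inverse-CDF draws, so scenario
pairs are not sample-path monotone.

## Health economics

Program costs per patient are EUR 2,810 (societal) and EUR 2,300
(healthcare) in 2012 euros (SEK converted at 8.71/EUR). The published
healthcare-perspective result rows are arithmetically consistent with
~2,258.5 rather than the rounded 2,300; `program_cost(table5_consistent =
TRUE)` provides that variant. Itemized costing from the resource-valuation
table is also supported: wage lines carry a 20% overhead for office space and
equipment, patient time is valued at a leisure rate (35% of the average wage)
and patient time/fees count only under the societal perspective.

Net cost = program cost − discounted future cost saving. The ICER verdict
partitions the plane: QALY gain with positive net cost gives a ratio
(reported to whole EUR; reproduction of published net-cost cells is exact,
of published ratio cells within the ±1 EUR that independent rounding of
intermediates permits); QALY gain at non-positive net cost is cost-saving
(printed `<0`); QALY loss is dominated (printed `-`); zero QALY change with
non-zero cost leaves the ratio undefined rather than infinite.

## Uncertainty analysis

Deterministic scenarios re-run the pipeline under named overrides: discount
0%/5%, sustainability low/high, an alternative parameter file, and three
alternative stratifications — per-sex average profiles, per-sex simulation of
10,000 patients drawn with their own characteristics, and no grouping at
all. The probabilistic sensitivity analysis bootstraps the paired
per-individual ledgers: 1,000 draws of 1,000 individuals (indices shared by
both arms, matching the common-random-numbers pairing — the paired bootstrap
is the variance-correct choice when arms are correlated), each draw yielding
a (Δcost, ΔQALY) point; the program cost is included in Δcost by default
(flag to exclude), and `ce_plane_summary()` reports quadrant shares, the
cost-saving share and the acceptability value at a willingness-to-pay
threshold (default EUR 50,000/QALY).

One direction deserves a caveat. Replacing group-resolved profiles by a
per-sex average changes ICERs through the *curvature* of the risk engine:
under the shipped proportional-hazards defaults the exponential response is
convex in the risk factors, so averaging understates the pooled benefit
(Jensen's inequality) and the gender-average mode yields *less* favourable
ICERs than the risk-group base case. A differently curved engine can
produce the opposite sign. The package therefore documents and tests the
direction its own default engine implies, and treats the general lesson —
averaging over heterogeneous patients distorts cost-effectiveness — as the
robust conclusion.

## The synthetic cohort generator

No patient-level data are distributed, so `generate_cohort()` fabricates a
cohort whose *group-level* structure matches the published tables: six
(risk level × sex) cells of 4/19/39 men and 37/28/15 women (142 included),
plus 37 additional participants who each fail one of the four inclusion
criteria (179 in total, 79% included). Continuous fields are truncated-normal
marginals tied by a Gaussian copula with a mild positive correlation (0.3)
among the obesity/glycemia fields — metabolic factors co-occur, but the true
covariance is unpublished, so this is a declared assumption, as is the
individual-level change noise (SD = 25% of a field's cross-sectional SD,
recentred to zero mean per cell). Dispersion defaults are the cohort-wide
SD/mean ratios of the published characteristics table. Diagnosed diabetes is
set at fasting glucose ≥ 7.0 mmol/L — the diagnostic threshold — so the flag
never changes a patient's criteria count; this reproduces roughly the
published ~22–26% prevalence.

Two requirements pull against each other: every generated patient must
classify into its intended cell (criteria count consistent), and each cell's
sample means must track the printed targets. They conflict because several
printed cell means themselves cross criteria thresholds (a "low-risk women"
mean systolic pressure of 137 mmHg cannot be reproduced exactly by women who
almost all spend their single permitted criterion on waist circumference).
The sampler therefore rejects inconsistent draws, iteratively recentres the
proposal mean using a large accepted pool, and finally reports the n-subset
of the pool best matching the target; residual bias in the structurally
constrained cells stays within the 3-standard-error band the tests assert.
What passing tests show, accordingly, is that the *group summaries* feeding
the model match the published conditions — not that individual-level joint
distributions match the real cohort, whose correlations, skewness and
longitudinal trajectories are unknown.

## Problem sizes and numerical choices

Default runs use 10,000 microsimulation repetitions per group and arm, the
study's own setting; the bootstrap uses 1,000 × 1,000. The test suite runs
smaller cohorts where only correctness (not convergence) is at stake, and
n = 4,000–10,000 where agreement with the oracle is asserted at 3 Monte-Carlo
SE. Calibration bisects on a log scale to a relative tolerance of 2·10⁻⁴,
taking the bracket endpoint on the feasible side so the calibrated YLL range
sits strictly inside its band. Profile positivity is enforced at generation
(changes clipped at 5% of the start value, with a message) and systolic
pressure is kept above diastolic at both time points. Fixture
self-consistency checks accept one unit in the last printed digit, since
start and 12-month columns were rounded independently; exactly three
difference cells in the published group table exceed that tolerance (two
triglyceride cells and one cholesterol cell with inverted signs) and are
surfaced by `load_fixture_tables()$consistency` rather than patched.

## Known limitations

* Absolute QALY, YLL and cost levels depend on the shipped default engine
  and its single-factor calibration; they are illustrative magnitudes, not
  estimates. Differences, orderings, and the CEA arithmetic are the tested
  claims.
* Risk factors are constant with age apart from the intervention trajectory;
  no secular drift, no treatment changes, no relapse stochasticity.
* The state space folds stroke into CVD and represents diabetes
  complications as a single state.
* Prevention effects on conditions outside the two modelled disease
  families (cancer, musculoskeletal pain) are excluded, as are short-term
  within-program quality-of-life gains.
* The synthetic cohort reproduces first moments and criteria structure, not
  the real joint distribution of risk factors.
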