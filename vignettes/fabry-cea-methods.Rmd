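---
title: "Methods: a lifetime Markov cost-utility model of ERT in Fabry disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lifetime Markov cost-utility model of ERT in Fabry disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Fabry disease is a rare X-linked lysosomal storage disorder. Deficient
alpha-galactosidase A activity leads from acroparesthesia and early organ
signs to end-organ damage: end-stage renal disease (ESRD), cardiac
complications and stroke. Enzyme replacement therapy (ERT, agalsidase
alfa or beta) slows progression at an annual drug cost of roughly
€200,000 per adult patient. The package implements a cost-utility
analysis asking what that slowing is worth: the incremental cost per
year free of end-organ damage (YFEOD) and per quality-adjusted life-year
(QALY) of starting ERT when symptoms develop, against standard medical
care.

## Model structure

The model is a discrete-time Markov state-transition model with eleven
states: asymptomatic, acroparesthesia, symptoms (organ signs without a
complication), the three single complications (ESRD, cardiac,
cerebrovascular accident), their three pairwise combinations, the triple
combination, and death. Cycles last one year; a cohort enters
asymptomatic at birth and is followed to age 70. Progression is
one-directional — a gained complication is never lost — with one
exception: ESRD patients may return to the symptomatic state after a
kidney transplant (transplant follow-up costs are not modelled; only the
first transplant year carries its cost through the ESRD state-cost
entry). Death is reachable from every state and absorbing.

Assumptions inherited from the study design:

* untreated transition probabilities describe the natural course;
  ERT only lowers the probability of progressing to the next state;
* utilities and non-drug costs depend on the disease state (cluster),
  not on treatment status or sex;
* agalsidase alfa and beta are interchangeable (comparable price and no
  evidence of differential effect).

### Transition probabilities

Annual probabilities come from Kaplan-Meier analysis of per-state
sojourn times: the median time to the next state (or the last observed
event time, flagged, when survival never reaches 0.5) is converted under
a constant hazard by

$$p = 1 - 2^{-c/m},$$

with cycle length $c = 1$ year and median $m$; a one-year median maps to
exactly 0.5. Transitions to other destinations are treated as censoring
(latent independent risks), which makes the conversion exact for
exponentially distributed sojourns. The annual probability of dying is
floored by general-population mortality: the model uses
$\max(p_{\text{model}}, q_x)$ with $q_x$ from a national life table by
age and sex.

### Treatment effect

The treatment effect is reported per treatment-year: an odds ratio of
0.82 (95% CI 0.68–0.96) for the step from symptoms to a first
complication and 0.52 (0.31–0.88) from a single to a second
complication. Because the odds ratio multiplies per year of ERT, it is
compounded over the median treatment duration $d$ in the state:

1. cumulative untreated risk $P_0 = 1-(1-p)^d$;
2. treated odds $= \frac{P_0}{1-P_0}\,\mathrm{OR}^d$, giving treated
   cumulative risk $P_1$;
3. cumulative relative risk reduction $1 - P_1/P_0$;
4. de-cumulated to a single cycle via $p_1 = 1-(1-P_1)^{1/d}$, so the
   per-cycle relative risk reduction is $1 - p_1/p$.

The treated probability is the untreated one times one minus the
per-cycle reduction, applied to the three symptoms→complication edges
(first effect) and the six single→double edges (second effect); no
effect is assumed on double→triple or death transitions, because only
those two odds ratios are reported. The three operations compose and
re-cumulate to the treated cumulative risk at machine precision, and for
rare events the per-cycle reduction approaches $1-\mathrm{OR}$.

The source study does not state the median treatment durations it used.
The parameter file therefore requires them explicitly; the synthetic
preset assumes 1 year in the symptomatic state and 2 years in single
complication states, reflecting that ERT had been available for under a
decade in the observation window. These are documented assumptions, not
cohort estimates.

### Utilities and costs

EQ-5D-3L profiles, collected quarterly, are valued with the UK
time-trade-off tariff (the Dutch tariff ships alongside for sensitivity
analysis; its values are higher for the mid and severe profiles, so
slowing progression buys fewer QALYs under it). Utilities are averaged
per patient per disease-state cluster first, then over patients, so
frequent responders do not dominate; confidence intervals bootstrap over
patients. The four living clusters (asymptomatic, acroparesthesia or
symptoms, single complication, multiple complications) carry means
0.874, 0.762, 0.744 and 0.584. With one-year cycles the mean utility in
a cycle is the QALY yield of that cycle; death yields zero.

Costs per state-year combine hospital resource use, out-of-hospital
visits and dialysis/transplant costs at Dutch 2009 unit prices
(inpatient day €457 outside the academic centre, ICU day €2,183,
GP visit €28, dialysis €60,000/year, ...). Quarterly questionnaire
counts are multiplied by four and averaged per patient per cluster, then
over patients. Productivity losses follow the sick-leave rules: days
per fortnight × 26 × mean hours per working day × €30/hour; permanent
sick leave counts as a full-time-equivalent annual loss; people out of
work for unrelated reasons contribute zero. Production losses enter the
analysis only in scenario 6 and only from the 18th year of life.

### Engine

The deterministic cohort engine advances the occupancy vector through 70
age-dependent matrices and accrues life-years, YFEOD (occupancy of the
first three states), QALYs and costs from the post-transition occupancy.
ERT drug cost accrues for alive occupancy in treated states only. The
microsimulation engine samples individual paths from the same matrices,
drawing each patient's sex from the cohort sex mix (0.5), and converges
to the cohort expectation as patients grow.

Numerical choices, all recorded here because the source description is
silent on them:

* **Diagonal fill** — only exit probabilities are specified; residual
  probability stays in the state.
* **No half-cycle correction**; accruals use post-transition occupancy.
* **First cycle undiscounted**: the discount factor is
  $1/(1+r)^t$ with $t = 0$ for the first model year. Differential
  discounting uses 1.5%/year for effects and 4%/year for costs.
* **Treatment as a state-age predicate**: whether occupancy is treated
  is a deterministic function of state and age (Markov memorylessness),
  which also covers "stop after two complications". Transplant
  returnees resume the symptomatic profile and the first-complication
  effect.
* A row failing stochasticity by more than 1e-12 aborts with its cycle
  index rather than being renormalised.

## Strategies and scenarios

Strategies: `no_ert`, `ert_at_symptoms` (base case), `ert_at_40`
(scenario 1), `ert_stop_after_2` (scenario 5). The six scenarios
override exactly one ingredient each and reduce to the base case when
their override is neutral: (1) delayed start; (2) untreated-arm
utilities lowered by 0.1 (floored at 0) in all living clusters; (3) the
classical-phenotype preset with uniformly faster progression; (4)
ACE-inhibitor/ARB co-medication in the comparator arm, implemented as
the first-complication per-cycle relative risk reduction applied to the
untreated symptoms→complication probabilities — i.e. standard care
assumed as effective as ERT against a first complication, with the ERT
arm unchanged; (5) no drug cost and no effect in double/triple states;
(6) production losses added in both arms from age 18. Scenario 4 is an
interpretation of a stated assumption whose full derivation is not
public; it nullifies ERT's added value over co-medication for the first
complication while leaving the second-complication effect.

## Probabilistic sensitivity analysis

Second-order uncertainty: each of 1,000 outer draws samples every annual
transition probability from a beta distribution (shapes by method of
moments from the point estimate and its 95% interval, interval width /
3.92 as standard deviation; draws are independent across transitions
because no correlation structure is reported). First-order uncertainty:
each draw runs 10 microsimulated patients per strategy. By default both
strategies share the random stream within a draw (common random numbers;
switchable), which reduces delta variance; the mode is recorded in the
settings. Net monetary benefit, $\lambda \Delta Q - \Delta C$, is
evaluated on the undiscounted deltas over 25 log-spaced
willingness-to-pay values from €20,000 to €10,000,000 per QALY, and the
cost-effectiveness acceptability curve reports the fraction of draws
with positive benefit. Utilities and costs are held fixed, mirroring the
stated design ("beta-distributed transition probabilities").

The flatness of the acceptability curve below €10 million per QALY is a
property of the two-stage design itself: with only 10 first-order trials
per draw, patient-level noise dominates the draw-level QALY delta and
keeps the curve from rising above 0.5 even where the deterministic ICER
is favourable. Increasing the inner trials sharpens the curve into a
step around the deterministic ICER — worth remembering when scaling the
design up.

## The synthetic generator and calibration

No patient-level data or per-transition source tables are public, so the
package ships synthetic presets (JSON parameter files labelled as such)
plus patient-level generators with known ground truth:

* **histories** — exponential latent sojourn times per exit edge with
  medians implied by the preset probabilities, independent exponential
  censoring at a configured expected rate (15%);
* **EQ-5D records** — two-point mixtures of the profiles bracketing the
  target cluster utility under the shipped tariff, so the expected
  estimated mean equals the target exactly;
* **resource use** — Poisson counts with cluster-specific quarterly
  rates plus employment states for the sick-leave rules.

The `base` preset was calibrated once against the published headline
outcomes, using only printed results as anchors: untreated YFEOD 55.0
years (53.5 male / 56.9 female), untreated QALYs 48.6, an incremental
lifetime cost near €9.6 million, and the effect deltas implied by the
printed cost deltas and ICERs (≈1.47 YFEOD, ≈1.59 QALYs undiscounted).
The calibrated preset lands at untreated YFEOD 55.4 (53.4/57.3), QALYs
46.8, ΔYFEOD 1.64, ΔQALYs 1.45, Δcost €9.76M — inside the published
neighbourhood, with ICERs between €3.3M (discounted) and €6.7M
(undiscounted). The `classical` preset scales progression by 1.06,
landing 5–9% below the base-case ICERs as reported for the
classical-phenotype scenario; `null-effect` sets both odds ratios to 1.
The preset transition probabilities are *plausible*, not *actual*:
exact reproduction of the published tables would require the
unpublished supplementary probability and cost tables.

What the generator deliberately does not emulate: age-dependent
background mortality within the histories (spell hazards are constant,
so Kaplan-Meier recovery is exact in expectation), confounding by
indication (which the study itself could not resolve), and
between-patient heterogeneity in utilities beyond the cluster mean.
Passing the recovery suite therefore shows the estimation chain is
correct for data meeting its assumptions — not that the assumptions hold
in any real cohort.

## Validation suite and problem sizes

The tests close the loop at sizes chosen to keep the default run at a
few minutes: product-limit medians against brute-force tables (n ≤ 10)
and a 5,000-sample exponential consistency check; the two-state
geometric closed form to 1e-9; the treatment-effect round-trip to 1e-12;
row-stochasticity over 1,000 randomly drawn parameter sets;
microsimulation→cohort agreement within two standard errors at 50,000
patients; generate→estimate→simulate recovery within two years/QALYs at
2,500 synthetic patients (pre-registered tolerance, about three times
the observed error); and a 200×10 acceptability-curve check with the
full 1,000×10 design reserved for the acceptance script.

## Known limitations

Sojourn times are effectively exponential per state; there are no tunnel
states, no covariates beyond sex, no transplant follow-up costs, no
agalsidase alfa/beta distinction, and parameter uncertainty in the PSA
covers transition probabilities only. The headline numbers computed on
the synthetic presets approximate, and cannot replace, results on the
study's own parameter tables.
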