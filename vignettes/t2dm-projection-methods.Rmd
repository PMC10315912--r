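---
title: "Methods: a compartmental projection model of type 2 diabetes and its prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a compartmental projection model of type 2 diabetes and its prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(t2dmsim)
```

## The model

`t2dmsim` implements a deterministic population-level compartmental model of
type 2 diabetes mellitus (T2DM) among adults aged 20–79, of the kind used to
project national diabetes burden and to compare prevention policies against
a no-intervention counterfactual. The population is stratified by

* sex (female, male),
* twenty 3-year age bands spanning 20–79,
* the eight-way lattice of three modifiable risk factors — obesity,
  physical inactivity, smoking — and their overlap,
* T2DM status (susceptible, diabetic; the diabetic state is absorbing —
  the interventions modeled here prevent onset, they do not induce
  remission), and
* intervention-coverage class (uncovered, or covered by any subset of the
  active scenarios; with $K$ active scenarios the coverage dimension has
  $2^K$ classes so that co-coverage is represented explicitly).

The dynamics are a system of ordinary differential equations. Per
compartment, the flows are:

* **ageing** as a continuous transfer at rate $1/3$ per year between
  adjacent 3-year bands (consistent with a pure-ODE formulation; people
  leaving band 20 exit the modeled 20–79 range),
* **entry** of 20-year-olds into band 1, susceptible and uncovered, at rate
  $E_0 e^{g_E (t - t_0)}$ persons/year, with a fixed risk-profile mix,
* **background mortality**, Gompertz in age,
  $\mu(a) = \mu_{50} e^{0.085 (a - 50)}$, multiplied by
  $\kappa$ for diabetics ($\kappa = 1.5$ by default; early mortality
  associated with diabetes is documented but not quantified in the source
  setting, so the multiplier is configurable),
* **risk-factor transitions** along lattice edges (one factor changes at a
  time) at acquisition rates $\alpha_f$ and exit rates $\omega_f$,
* **T2DM onset** at hazard
  $$\lambda(s, a, t, \text{profile}) \;=\;
    \underbrace{e^{a_s + b_s z + c_s z^2}}_{\text{age shape},\; z = (a-45)/10}
    \cdot
    \underbrace{e^{g_1 \Delta t + g_2 \Delta t^2 + g_3 \Delta t^3}}_{\text{secular trend}}
    \cdot \prod_{f \in \text{profile}} RR_f
    \cdot m(\text{coverage}, t),$$
  where the relative risks compose multiplicatively
  ($RR_{\text{obese}} = 3.6$, $RR_{\text{inactive}} = 1.3$,
  $RR_{\text{smoker}} = 1.4$ by default, literature-typical pooled values
  taken as inputs rather than fitted) and $m \le 1$ is the product of the
  incidence-rate ratios (IRR/RR) of the scenarios covering the compartment
  whose target filter it matches,
* **coverage recruitment** (below), and
* a **cumulative-incidence accumulator** per sex and band, whose annual
  differences are the "annual number of new cases".

The integrator is `deSolve::ode` with the adaptive Runge–Kutta method
`ode45`, absolute tolerance $10^{-8}$ times the initial population and
relative tolerance $10^{-8}$, with annual dense output. An adaptive
Runge–Kutta is preferred over an implicit multistep method here because the
obesity-forcing controller couples all compartments through an aggregate
(see below): implicit methods then want dense Jacobians of a
$\sim 10^4$-dimensional state, which is far more expensive than taking
smaller explicit steps. Against an independently coded fixed-step Euler
integration of the same equations the engine agrees to better than $10^{-4}$
relative; in a closed system (no entry, no mortality, no exits) the
population is conserved to $10^{-6}$ relative over 30 years.

## The synthetic baseline ("shape from the model, scale from the anchors")

The original model was calibrated to national epidemiological surfaces that
are not available in machine-readable form. The package therefore ships a
synthetic-data module that generates a self-consistent, Qatar-like set of
calibration targets (population counts and T2DM/obesity/inactivity/smoking
prevalence by sex × band × year, 2021–2050) reproducing the published
aggregate anchors:

| anchor | value |
|---|---|
| T2DM prevalence 2021 → 2050 | 17.1% → 29.5% |
| prevalent cases 2021 → 2050 | 33,821 → 84,516 |
| annual new cases 2021 → 2050 | 2,145 → 3,931 |
| cumulative new cases 2021–2050 | ≈ 81,750 (derived from the published averted-case count/proportion pairs 18,619/22.8% and 38,379/46.9%) |
| obesity prevalence | 53.1% (2023), 53.3% baseline in 2030 |
| physical inactivity / smoking (2023) | 46.5% / 20.7% |

The construction (`generate_baseline()`):

1. **Start-year cross-section** (`consistent_structure()`): a young,
   fast-grown exponential age pyramid (decay `age_profile_shape` per year of
   age); a T2DM prevalence age profile obtained from the along-chain balance
   of ageing, onset and excess mortality under the configured onset-hazard
   age shape, with the hazard level solved so the 2021 prevalent-case count
   is exact (prevalence rises from near zero at the entry age,
   monotonically with age); risk-factor marginals at their anchor values,
   combined under independence within each cell, with diabetics allocated
   across profiles proportionally to exposure-weighted risk.
2. **Anchor solve** (`solve_baseline_params()`): seven parameters — hazard
   level $a$, the three secular-trend coefficients, the obesity acquisition
   scale, the entry-rate scale, and the initial pyramid slope (with a weak
   prior holding it in the demographically plausible range) — are adjusted
   by bounded Levenberg–Marquardt least squares until the no-intervention
   model run from the cross-section reproduces the six remaining anchors to
   better than 0.1% each.
3. The emitted surfaces are that run's annual snapshots. The targets are
   therefore *literally a model trajectory*: every surface lies on the
   model's own solution manifold, the start-year anchors hold exactly and
   the end-year anchors to the solve tolerance.

Two consequences are worth stating plainly. First, calibration against
these targets is a parameter-recovery problem with an exact solution, so
the fitted model reproduces the published anchors almost exactly — this is
deliberate and is what makes the downstream machinery testable, but it is a
*machinery* check, not a validation against real data. Second, features of
real calibration data that the generator does not emulate — survey noise,
inconsistent vintages, sex differences, non-exponential pyramids, secular
risk-factor trends — mean that passing tests demonstrate correctness of the
engine, not predictive accuracy for any real population. A `noise_sd`
configuration knob adds seeded log-normal jitter to the surfaces for
robustness experiments.

Two numerical choices deserve a note. The anchored case-count path is
strongly convex: jointly satisfying the first-year, last-year and
cumulative case counts forces annual cases to dip through the late 2020s
before climbing steeply in the 2040s, while a young pyramid ageing into the
peak-onset years produces strong structural growth in incidence. The generating secular trend
therefore starts markedly negative and turns positive — a cubic
log-polynomial in time is the smallest family that can satisfy the three
case-count anchors jointly, and the same family is used in the calibrated
hazard. Second, all Levenberg–Marquardt solves set `epsfcn = 1e-6`: the
default finite-difference step would sit at the ODE error floor and produce
noise Jacobians.

## Calibration

`fit_parameters()` minimizes weighted squared differences between the
simulated no-intervention baseline and the target surfaces: aggregate
population (percent deviation), aggregate T2DM/obesity/inactivity/smoking
prevalence (percentage points) per year, and age-resolved T2DM prevalence
at four years, weighted by the square root of band population shares.
Default family weights are 1 with 0.3 on the age-resolved term and 0.2 on
the (structurally flat) inactivity/smoking families.

The fit is staged for interpretability and robustness: entry rates on
population totals; obesity acquisition scale on the obesity path; then a
profile-matching initialization of the hazard level and trend (the incidence
path implied by the targets — stock change plus mortality/ageing exits — is
compared with the simulated path and the log-ratio regressed onto the trend
polynomial); then the hazard age/trend coefficients on the T2DM surfaces
with multistart (default 5 seeded starts); finally a joint polish of all
free parameters. Bounded trust-region least squares throughout
(`minpack.lm::nls.lm`). On the packaged targets the fit recovers the
generating hazard level, trend and obesity scale to well within 1% and
leaves prevalence residuals below 0.02 pp.

Which parameters the original fit treated as free is not stated in the
source; the default free set here (hazard level/age shape/trend, obesity
acquisition scale, entry rates) is an explicit design choice, with the
relative risks fixed as inputs.

## Interventions

The twelve scenarios and two combination packages ship as a YAML library
(`inst/extdata/table1_scenarios.yaml`) mirroring the published design:
three lifestyle-management scenarios (uptake 50%, adherence 50%, scale-up
2021–2025, IRR 0.70 — the average of the evidence-based effect sizes 0.65
and 0.74 — applied to the obese, those 50+, or the obese 35+), two active
commuting scenarios, four dietary scenarios, three subsidy/legislation
scenarios (all uptake×adherence as published, scale-up 2021–2030), and the
most/least optimistic packages bundling the most/least impactful scenario
of each approach.

**Coverage** is modeled with explicit covered/uncovered compartments.
Eligibility is evaluated continuously (people entering an eligible stratum
become eligible); recruitment moves eligible uncovered persons to the
covered class at a rate combining the ramp's slope (feed-forward) with a
proportional correction (gain 2/yr) so the covered fraction tracks the
linear scale-up and is *maintained* afterwards against dilution by new
entrants — the rate is zero whenever coverage is at target. A simpler
hazard-weighting formulation was rejected because the workplace dietary
scenario changes obesity dynamics only among the covered.

**Obesity endpoints.** Scenarios that state an obesity-prevalence endpoint
(e.g., 53.3% → 50.9% by 2030) are implemented by *forcing*: an additional
obesity-exit rate (and matching acquisition damping) among covered persons,
ramped linearly over the scale-up window, whose scalar multiplier is solved
by a bracketed monotone search so the simulated prevalence in the stated
scope (total population, or the covered subgroup for the workplace
scenario) hits the endpoint within 0.05 pp. The search measures candidate
trajectories with the same integrator settings as the production runs, and
runs are integrated piecewise at every scale-up boundary (the regime of
each forcing group is fixed per segment), so solver stages can never
straddle a ramp/hold kink and the achieved endpoint equals the reported
trajectory's value by construction. After scale-up a smooth
one-sided feedback controller (softplus, gain 150/yr) holds prevalence at
the target; because it only acts from above, the trajectory never
undershoots the target beyond tolerance. The published BMI reductions are
*not* converted to prevalence by the scenario engine: under any single
normal distribution-shift model the printed (ΔBMI, endpoint) pairs are
mutually inconsistent (the `audit_bmi_endpoints()` utility quantifies this
— the fiscal trio implies a common BMI sd of ≈9.3 kg/m², the
active-commuting pairs an sd 2–3× larger), so the printed endpoints are
treated as authoritative. The BMI module remains available as an
exploratory utility.

**Composition.** In packages, incidence multipliers compose
multiplicatively for compartments covered by several scenarios; obesity
forcing is solved with one shared multiplier per scope targeting the most
stringent applicable endpoint, alternating between scopes until all are
within tolerance. Inactivity normalization (public-transport scenario)
moves covered inactive persons to active at a rate completing ~99% of the
shift within the scale-up window. Whether lifestyle adherence decays over
time is not stated in the source; constant adherence is assumed.

## Outcomes

`run_scenario()` simulates the intervention and its counterfactual with
identical parameters and initial state and compares them
(`compare_trajectories()`): annual new cases under both, cumulative averted
cases $\sum_{2021}^{y} (\text{new}_\text{base} - \text{new}_\text{int})$,
and the proportion averted, denominated by cumulative *baseline* new cases
from 2021 (the intervention start) through year $y$ — the definition
consistent with the published count/proportion pairs. Accrual starts in
2021 with the interventions. Prevalence reductions are reported both in
absolute percentage points and as relative reductions, since the source
alternates between the two readings. A one-at-a-time
`sensitivity_sweep()` is provided; the full multivariate uncertainty
analysis of the original model family is out of scope.

Under the packaged synthetic baseline the qualitative orderings hold:
the workplace dietary scenario averts the most among dietary scenarios,
cycling/walking at least as much as public transport, the combined
subsidy+taxation scenario at least as much as either alone, and the most
optimistic package more than the least optimistic. One published ordering
does *not* carry over: lifestyle management restricted to the obese aged
35+ averts slightly fewer cases here than lifestyle management for all
obese, because at equal coverage the larger eligible pool wins under this
calibration's age-hazard profile — in the source, onset was concentrated
enough at 40–55 to reverse this. The absolute averted percentages likewise
differ from the published ones (obesity-mediated effects are weaker here);
reproducing them exactly would require the original calibration surfaces.

## Problem sizes and runtimes

The packaged analyses run at desk scale on one CPU: the baseline lattice
has 640 + 40 states (a single-scenario run 1,320; a package run 10,280),
the generator's anchor solve takes under a minute, the default calibration
a few minutes, a single-scenario run under a second, and a package run
(with its joint forcing solve) about half a minute. The test-suite fixtures
are memoised so the expensive steps run once.

## Known limitations

* The synthetic world is smooth and sex-symmetric; parameter recovery under
  noisy or asymmetric targets is exercised only via the `noise_sd` knob.
* The excess-mortality multiplier (1.5) and the relative risks are inputs;
  sensitivity to them can be explored with `sensitivity_sweep()` but they
  are not calibrated.
* Risk-factor dynamics use age-constant transition rates; the obesity age
  gradient of the targets is carried by the initial state rather than by
  age-specific acquisition.
* Pre-diabetes, complications, costs and the expatriate population are out
  of scope, as are stochastic/individual-level formulations.
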