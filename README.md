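# t2dmsim

A deterministic compartmental (ODE) model of type 2 diabetes mellitus
(T2DM) among adults aged 20–79, built for projecting national diabetes
burden and for comparing public-health prevention policies against a
no-intervention counterfactual. It is aimed at epidemiological modelers and
public-health analysts who want a tested, reusable implementation of the
full pipeline: synthetic baseline data → nonlinear least-squares
calibration → intervention scenarios → counterfactual averted-case
accounting.

## The model

The population is stratified by sex, twenty 3-year age bands, the
eight-way lattice of obesity × physical inactivity × smoking, T2DM status,
and intervention-coverage class. Compartment flows are ageing (continuous,
rate 1/3 per year; people exit the modeled range at 80), entry of
20-year-olds, Gompertz background mortality with an excess-mortality
multiplier κ for diabetics, risk-factor transitions along lattice edges,
and T2DM onset (absorbing) at hazard

λ(s, a, t, profile) = exp(a_s + b_s·z + c_s·z²) ·
exp(g₁Δt + g₂Δt² + g₃Δt³) · Π_f RR_f · m(coverage, t),   z = (a − 45)/10,

with multiplicative relative risks (RR_obese = 3.6, RR_inactive = 1.3,
RR_smoker = 1.4) and m the product of the incidence-rate ratios of the
covering scenarios. Interventions carry explicit coverage compartments with
linear scale-up and maintenance; scenarios that state an obesity-prevalence
endpoint are implemented by a solved forcing of the obesity transition
rates among the covered. Outcomes per scenario are the four standard
series: prevalence, annual new cases, cumulative averted cases, and the
proportion of cases averted (cumulative averted / cumulative counterfactual
new cases since intervention start).

Because the original calibration surfaces are not available
machine-readably, `generate_baseline()` builds a synthetic world whose
surfaces are *literally a model trajectory* solved to reproduce the
published burden anchors (prevalence 17.1% → 29.5%, prevalent cases
33,821 → 84,516, annual new cases 2,145 → 3,931 over 2021–2050, obesity
53.3% in 2030). See the methods vignette
(`vignettes/t2dm-projection-methods.Rmd`) for the full account.

## Worked example

```r
library(t2dmsim)

targets <- generate_baseline()            # synthetic calibration surfaces
fit     <- fit_parameters(targets)        # staged nonlinear least squares
traj    <- simulate_model(initial_state(targets, fit$params), fit$params,
                          t0 = 2021, t1 = 2051)

round(c(prev21 = 100 * prevalence(traj, 2021),
        prev50 = 100 * prevalence(traj, 2050),
        cases50 = prevalent_cases(traj, 2050),
        new21 = annual_new_cases(traj, 2021),
        new50 = annual_new_cases(traj, 2050)), 1)
#>  prev21  prev50 cases50   new21   new50
#>    17.1    29.5 84433.4  2145.6  3929.7

run_scenario("workplace_diet", fit$params, targets)
#> <scenario_result> 2021-2050
#>   2050: prevalence 27.0% vs 29.5% baseline (-2.5 pp)
#>   cumulative averted 8263 cases (10.1% of baseline cases)
```

The first block is the calibrated no-intervention projection: T2DM
prevalence rises from 17.1% to 29.5% of adults 20–79 while annual incident
cases grow from ~2,146 to ~3,930. The second runs one packaged scenario
(a workplace dietary and educational intervention, 50% uptake, RR 0.93 plus
an obesity-prevalence endpoint of 34.8% among the covered by 2030) against
its counterfactual: by 2050 it averts ~8,260 incident cases, about 10.1% of
all baseline incident cases since 2021.

The twelve scenarios and the two combination packages live in a packaged
YAML library (`scenario_library()`, `build_package("most_optimistic")`).
The numbered scripts under `analysis/` run the whole study end to end
(generate → calibrate → project → all scenarios → BMI-endpoint audit →
sensitivity sweeps), writing tables under `results/`:

```sh
Rscript analysis/01_generate_targets.R
Rscript analysis/02_calibrate.R
Rscript analysis/03_baseline_projection.R
Rscript analysis/04_run_scenarios.R
Rscript analysis/05_audit_bmi_endpoints.R
Rscript analysis/06_sensitivity.R
```

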