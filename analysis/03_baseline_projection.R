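#!/usr/bin/env Rscript
# Step 3 — the calibrated no-intervention projection, 2021-2050.
#
# Simulates the counterfactual baseline and writes the year-indexed burden
# table (population, prevalence, prevalent cases, annual new cases) to
# results/baseline_projection.csv. The printed lines are the quantities the
# published projection reports for 2021 and 2050.

library(t2dmsim)

targets <- read_targets("results/targets.csv")
params <- read_params("results/params.json")

traj <- simulate_model(initial_state(targets, params), params,
                       t0 = 2021, t1 = 2051)
export_trajectory(traj, path_aggregate = "results/baseline_projection.csv")

for (y in c(2021, 2030, 2040, 2050))
  cat(sprintf("%d: prevalence %5.1f%%  prevalent %6.0f  new cases %5.0f\n",
              y, 100 * prevalence(traj, y), prevalent_cases(traj, y),
              annual_new_cases(traj, y)))
cum <- sum(vapply(2021:2050, function(y) annual_new_cases(traj, y), 0))
cat(sprintf("cumulative new cases 2021-2050: %.0f\n", cum))
cat("projection -> results/baseline_projection.csv\n")
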