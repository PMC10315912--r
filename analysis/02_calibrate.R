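#!/usr/bin/env Rscript
# Step 2 — calibrate the natural-history parameters.
#
# Fits the model to results/targets.csv (generating the targets first if
# step 1 has not been run) by staged nonlinear least squares, writes the
# fitted parameters to results/params.json and the per-cell residual table
# to results/residuals.csv, and prints the fit summary.

library(t2dmsim)

dir.create("results", showWarnings = FALSE)
targets <- if (file.exists("results/targets.csv"))
  read_targets("results/targets.csv") else generate_baseline()
if (is.null(attr(targets, "config"))) attr(targets, "config") <- baseline_config()

fit <- fit_parameters(targets, fit_spec())
print(fit)

write_params(fit$params, "results/params.json")
rr <- residual_report(fit, targets)
write.csv(rr, "results/residuals.csv", row.names = FALSE)
cat(sprintf("max |T2DM prevalence residual|: %.4f pp\n",
            100 * max(abs(rr$residual[rr$family == "t2dm"]))))
cat("fitted parameters -> results/params.json; residuals -> results/residuals.csv\n")
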