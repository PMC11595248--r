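#!/usr/bin/env Rscript
# Stage 2: fit the two-phase logistic model to the simulated cohort.
#
# Growth is fitted to the per-day mean volumes of detected lesions on days
# 7-21, regression to days 21+; both use the reference initialisation
# (c = -10, kappa = +/-0.1 1/day, theta = 1.46997e9 cells) with a 10,000
# iteration budget. Writes JSON fit reports under results/.

suppressPackageStartupMessages(library(lesionkinetics))

obs <- read_lesion_table("results/cohort_observations.csv")

fit_growth <- fit_phase(obs, fit_config("growth"))
cat("Growth phase:\n"); print(fit_growth)
write_fit_report(fit_growth, "results/fit_growth.json")

fit_regression <- tryCatch(
  fit_phase(obs, fit_config("regression")),
  warning = function(w) {
    cat("note:", conditionMessage(w), "\n")
    suppressWarnings(fit_phase(obs, fit_config("regression")))
  })
cat("Regression phase:\n"); print(fit_regression)
write_fit_report(fit_regression, "results/fit_regression.json")

cat("Wrote results/fit_growth.json and results/fit_regression.json\n")
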