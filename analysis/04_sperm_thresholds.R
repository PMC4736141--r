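#!/usr/bin/env Rscript
# Sperm presence in excised organs: single-predictor logistic fits on age
# and on mean testicular length, AIC comparison, and inversion of the
# length curve into management thresholds (plug-in MLE curve plus a
# parametric-bootstrap median curve). Run 01_simulate_cohorts.R first.

suppressPackageStartupMessages(library(alpacatestis))
dir.create("results", showWarnings = FALSE)
seed <- 20160204

cohort <- read_cohort_csv("results/cohort_experiment2_fixture.csv")
cmp <- compare_predictors(cohort)
print(cmp)

fits <- data.frame(
  predictor = c("age_months", "mean_length_cm"),
  slope = c(cmp$fit_age$slope, cmp$fit_length$slope),
  p_wald = c(cmp$fit_age$p_wald_slope, cmp$fit_length$p_wald_slope),
  aic = c(cmp$fit_age$aic, cmp$fit_length$aic),
  r2_mcfadden = c(cmp$fit_age$pseudo_r2$mcfadden,
                  cmp$fit_length$pseudo_r2$mcfadden),
  r2_nagelkerke = c(cmp$fit_age$pseudo_r2$nagelkerke,
                    cmp$fit_length$pseudo_r2$nagelkerke),
  r2_tjur = c(cmp$fit_age$pseudo_r2$tjur, cmp$fit_length$pseudo_r2$tjur))
write.csv(fits, "results/sperm_logistic_fits.csv", row.names = FALSE)

bt <- bootstrap_thresholds(cmp$fit_length, cohort$mean_length_cm,
                           n_boot = 2000, seed = seed)
cat(sprintf(
  "bootstrap median thresholds (%d usable resamples):\n", bt$n_used))
cat(sprintf("  upper %.1f cm (95%% CI %.1f-%.1f)\n",
            bt$upper_cm[["median"]], bt$upper_cm[["ci_lower"]],
            bt$upper_cm[["ci_upper"]]))
cat(sprintf("  lower %.1f cm (95%% CI %.1f-%.1f)\n",
            bt$lower_cm[["median"]], bt$lower_cm[["ci_lower"]],
            bt$lower_cm[["ci_upper"]]))

th <- cmp$thresholds
write.csv(data.frame(
  method = c("mle_curve", "bootstrap_median"),
  upper_cm = c(th$upper_cm, round_half_up(bt$upper_cm[["median"]], 1)),
  lower_cm = c(th$lower_cm, round_half_up(bt$lower_cm[["median"]], 1))),
  "results/sperm_thresholds.csv", row.names = FALSE)
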