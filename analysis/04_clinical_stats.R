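#!/usr/bin/env Rscript
# Step 4 — outcome statistics.
#
# 2x2 association of each EEG exposure with the ASD outcome (odds ratio,
# Wald 95% CI, sensitivity/specificity/PPV/NPV), univariable and
# multivariable (mutation + treatment) logistic models, Mann-Whitney
# comparisons of the developmental quotients by dysmaturity, and linear
# models of transformed DQs.
#
# Inputs:  results/cohort.csv
# Outputs: results/stats_report.csv

library(tscqeeg)

cohort <- read_cohort("results/cohort.csv")
stats <- cohort_stats(cohort)
write.csv(stats$association, "results/stats_report.csv", row.names = FALSE)

cat("\n2x2 associations with 24-month ASD outcome:\n")
print(within(stats$association, {
  or <- round_half_up(or, 1)
  ci_lower <- round_half_up(ci_lower, 1)
  ci_upper <- round_half_up(ci_upper, 1)
  sensitivity <- round_half_up(100 * sensitivity)
  specificity <- round_half_up(100 * specificity)
  ppv <- round_half_up(100 * ppv)
  npv <- round_half_up(100 * npv)
}), row.names = FALSE)

cat("\nunivariable logistic model (dysmature EEG):\n")
print(stats$logistic_univariable)
cat("\nmultivariable logistic model (+ TSC2, preventive treatment):\n")
print(stats$logistic_multivariable)

cat("\nDQ by dysmaturity (Mann-Whitney):\n")
print(stats$dq_mann_whitney, row.names = FALSE, digits = 3)
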