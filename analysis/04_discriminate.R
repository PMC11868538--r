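#!/usr/bin/env Rscript

# Step 4: group-level discrimination.
#
# For all participants and the cognitively impaired subgroup, evaluates how
# well plasma p217+tau separates the three headline stage contrasts (A-T- vs
# all A+; lower stages vs Intermediate/Advanced; Advanced vs all others):
# AUC with DeLong CI, the Youden operating point with stratified-bootstrap
# CIs, fixed 90/95% sensitivity and specificity points, the biomarker-vs-
# covariate risk models compared by DeLong test, the two-threshold triage
# zoning, and the two-step Youden screen for the Advanced stage.

suppressPackageStartupMessages(library(ptaustage))

SEED <- 1
cohort <- read_cohort("results/cohort_staged.csv")
stages <- factor(cohort$stage, levels = STAGE_LEVELS)
cfg <- run_config(seed = SEED, bootstrap_B = 2000)

report <- run_full_pipeline(cohort, cfg)
write_report(report, "results/analysis_report.json")

cat("Headline contrasts (plasma p217+tau alone):\n")
for (nm in names(report$discrimination)) {
  d <- report$discrimination[[nm]]
  y <- d$operating_points$youden
  cat(sprintf("  %-12s AUC %.2f [%.2f-%.2f]  Youden %6.1f fg/ml  sens %.2f  spec %.2f  PPV %.2f  NPV %.2f\n",
              nm, d$auc, d$auc_ci[1], d$auc_ci[2], y$threshold,
              y$sensitivity, y$specificity, y$ppv, y$npv))
}

# biomarker vs demographic covariates, all participants, A-T- vs A+
keep <- stages %in% STAGEABLE_LEVELS
d <- cohort[keep, ]; g <- stages[keep]
y <- g != "A_NEG_T_NEG"
base <- fit_risk_model(d[, c("age_years", "sex", "apoe_e4")], y)
full <- fit_risk_model(d[, c("p217_fg_ml", "age_years", "sex", "apoe_e4")], y)
dl_base <- delong_compare_paired(d$p217_fg_ml, base$scores, y)
dl_full <- delong_compare_paired(full$scores, d$p217_fg_ml, y)
cat(sprintf("\nA-T- vs A+ (all): p217 AUC %.2f vs base model %.2f (DeLong p = %.2g)\n",
            dl_base$auc_a, dl_base$auc_b, dl_base$p_two_sided))
cat(sprintf("  full model AUC %.2f vs p217 alone %.2f (DeLong p = %.2g)\n",
            dl_full$auc_a, dl_full$auc_b, dl_full$p_two_sided))

# two-threshold triage for amyloid positivity, all participants
roc <- empirical_roc(d$p217_fg_ml, y)
lo <- threshold_at_target(roc, 0.95, "sensitivity")$threshold
hi <- threshold_at_target(roc, 0.90, "specificity")$threshold
z <- two_threshold_zoning(d$p217_fg_ml, y, lo, hi)
cat(sprintf("\nTwo-threshold triage (95%% sens %.1f, 90%% spec %.1f fg/ml):\n",
            lo, hi))
cat(sprintf("  indeterminate %.0f%%, accuracy in Low/High %.0f%%, PPV High %.0f%%, NPV Low %.0f%%\n",
            100 * z$fraction_indeterminate, 100 * z$accuracy_determinate,
            100 * z$ppv_high, 100 * z$npv_low))

# two-step Youden screen for the Advanced stage among CI participants
ci <- cohort$clinical_group %in% c("MCI", "DEM") & keep
ts <- two_step_youden(cohort$p217_fg_ml[ci], stages[ci],
                      step1_pos = c("INTERMEDIATE", "ADVANCED"),
                      step2_pos = "ADVANCED")
cat(sprintf("\nTwo-step Youden (CI): step-1 threshold %.1f fg/ml keeps %d participants;\n",
            ts$step1$report$threshold, ts$step1$n_survivors))
cat(sprintf("  step-2 AUC %.2f (vs step-1 AUC %.2f), step-2 threshold %.1f fg/ml\n",
            ts$step2$roc$auc, ts$step1$roc$auc, ts$step2$report$threshold))
cat("Wrote results/analysis_report.json\n")
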