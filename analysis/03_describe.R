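#!/usr/bin/env Rscript

# Step 3: per-stage descriptives and between-stage biomarker comparisons.
#
# Rebuilds the demographic-characteristics table from the staged cohort and
# tests plasma p217+tau differences across stages with Kruskal-Wallis
# followed by Dunn's pairwise test (Holm-adjusted), with Cohen's d and the
# median fold change per pair. The key expectation, mirrored from the study:
# every adjacent-stage contrast separates except Initial vs Early, which is
# why those stages are consolidated downstream.

suppressPackageStartupMessages(library(ptaustage))

cohort <- read_cohort("results/cohort_staged.csv")
stages <- factor(cohort$stage, levels = STAGE_LEVELS)

desc <- describe_by_stage(cohort, stages)
write.csv(desc, "results/descriptives_by_stage.csv", row.names = FALSE)
cat("Per-stage p217+tau medians (fg/ml):\n")
print(setNames(round(desc$p217_median, 1), desc$stage))

keep <- stages %in% STAGEABLE_LEVELS
kd <- kruskal_dunn(cohort$p217_fg_ml[keep],
                   factor(as.character(stages[keep]), levels = STAGEABLE_LEVELS))
cat(sprintf("\nKruskal-Wallis: H = %.1f (df %d), p = %.3g\n",
            kd$H, kd$df, kd$p_value))

pw <- kd$pairwise
write.csv(pw, "results/pairwise_p217.csv", row.names = FALSE)
adj <- pw[paste(pw$group1, pw$group2) %in%
            c("A_NEG_T_NEG INITIAL", "INITIAL EARLY",
              "EARLY INTERMEDIATE", "INTERMEDIATE ADVANCED"), ]
cat("\nAdjacent-stage contrasts (Dunn, Holm-adjusted):\n")
for (i in seq_len(nrow(adj)))
  cat(sprintf("  %-12s vs %-12s  p = %8.2e  d = %5.2f  fold change = %.2f%s\n",
              adj$group1[i], adj$group2[i], adj$p_adjusted[i],
              adj$cohens_d[i], adj$median_fold_change[i],
              if (adj$p_adjusted[i] >= 0.05) "   (ns)" else ""))
cat(sprintf("\nA-T- to Advanced median fold change: %.2f\n",
            median_fold_change(cohort$p217_fg_ml[stages == "A_NEG_T_NEG"],
                               cohort$p217_fg_ml[stages == "ADVANCED"])))

# categorical stage comparisons
tab_apoe <- table(droplevels(stages[keep]), cohort$apoe_e4[keep] == 1)
chi <- chi_square_categorical(tab_apoe)
cat(sprintf("APOE e4 carriership by stage: chi-square %.1f (df %d), p = %.3g\n",
            chi$statistic, chi$df, chi$p_value))
cat("Wrote results/descriptives_by_stage.csv and results/pairwise_p217.csv\n")
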