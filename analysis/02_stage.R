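#!/usr/bin/env Rscript

# Step 2: assign biological PET stages.
#
# Applies the staging rule table (amyloid positivity at 25 Centiloid; tau
# positivity at 1.18/1.24/1.08 SUVR for the Me/Te/R regions; high tau at
# 2.68 Te SUVR) and reports the stage distribution and the headline
# prevalences over stageable participants.

suppressPackageStartupMessages(library(ptaustage))

cohort <- read_cohort("results/cohort.csv")
stages <- classify_stage(cohort, staging_thresholds())
cohort$stage <- as.character(stages)
write_cohort(cohort, "results/cohort_staged.csv")

sc <- stage_counts(stages)
cat("Stage counts:\n")
print(sc$counts[sc$counts > 0])
cat(sprintf("Stageable participants: %d (excluded A-T+: %d, unstaged: %d)\n",
            sc$n_stageable, sc$n_excluded, sc$n_unstaged))
cat(sprintf("Prevalence: A+ %.0f%%, Intermediate/Advanced %.0f%%, Advanced %.0f%%\n",
            sc$prevalence_pct[["a_pos"]],
            sc$prevalence_pct[["intermediate_advanced"]],
            sc$prevalence_pct[["advanced"]]))

counts_df <- data.frame(stage = names(sc$counts), n = sc$counts,
                        row.names = NULL)
write.csv(counts_df, "results/stage_counts.csv", row.names = FALSE)
cat("Wrote results/cohort_staged.csv and results/stage_counts.csv\n")
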