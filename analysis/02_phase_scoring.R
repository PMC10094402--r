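#!/usr/bin/env Rscript
# Phase-wise behavioral scoring: collapse the 15 3-minute bins into the
# phase-1 (0-9 min) and phase-2 (9-45 min) totals, summarise groups,
# compute per-rat AA% against the vehicle group, and run the
# repeated-measures ANOVA (phase as the within factor) with Tukey HSD.

suppressPackageStartupMessages(library(nocistat))

behavior <- read_behavior_csv("results/behavior.csv")
ph <- phase_summaries(behavior)
aa <- aa_table(ph)
grp <- group_phase_summary(ph)
write.csv(aa, "results/aa_per_rat.csv", row.names = FALSE)
write.csv(grp, "results/group_summary.csv", row.names = FALSE)

cat("Group means (seconds of face rubbing):\n")
print(grp, row.names = FALSE, digits = 4)

long <- behavior_long(behavior, unit = "phase")
anova <- two_way_rm_anova(long, value = "value", treatment = "group",
                          time = "phase", rat = "rat_id")
write.csv(anova, "results/anova_phases.csv", row.names = FALSE)
cat("\nTwo-way RM-ANOVA (group x phase):\n")
print(anova, row.names = FALSE, digits = 4)

tk <- tukey_hsd(ph$phase2_s, ph$group)
write.csv(tk, "results/tukey_phase2.csv", row.names = FALSE)
cat("\nTukey HSD, phase 2 --", sum(tk$significant), "of", nrow(tk),
    "pairs significant at 0.05\n")
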