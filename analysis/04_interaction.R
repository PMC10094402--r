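#!/usr/bin/env Rscript
# Fixed-dose interaction analysis: cromoglycate alone vs cromoglycate +
# magnesium 15 mg/kg, per phase. Parallelism pretest, relative potency
# with Fieller limits, interaction verdict, per-dose %I, and the
# parallel-model ED50 identity.

suppressPackageStartupMessages(library(nocistat))

behavior <- read_behavior_csv("results/behavior.csv")
# the combination arm pairs doses 1/5/10/30 with MS 15; drop MS-alone rows
sub <- behavior[!(behavior$cg_dose_mgkg == 0 & behavior$ms_dose_mgkg > 0), ]

for (phase in 1:2) {
  cat("\n================ phase", phase, "================\n")
  rep <- fixed_dose_analysis(sub, phase = phase)
  print(rep)
  write.csv(rep$inhibition,
            sprintf("results/inhibition_phase%d.csv", phase),
            row.names = FALSE)
}

cat("\nNote: under the default scenario the combination adds magnesium's\n")
cat("dose-independent ~40% phase-2 effect on top of the cromoglycate\n")
cat("curve; near the 100% ceiling this flattens the combination line, so\n")
cat("a nonparallel/indeterminate phase-2 call mirrors the study's own\n")
cat("finding that the phase-2 combination lines were not parallel (see\n")
cat("the methods vignette).\n")
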