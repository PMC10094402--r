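#!/usr/bin/env Rscript
# Histomorphometry: average the three high representative fields per rat,
# summarise totals and degranulated counts per group x time point, compute
# the degranulation inhibition I% of magnesium pretreatment, and correlate
# degranulation with phase pain times.

suppressPackageStartupMessages(library(nocistat))

histology <- read_histology_csv("results/histology.csv")
behavior <- read_behavior_csv("results/behavior.csv")

ms <- mastcell_summaries(histology)
write.csv(ms, "results/mastcell_per_rat.csv", row.names = FALSE)

agg <- aggregate(cbind(mean_total, mean_degranulated) ~ group + time_point,
                 ms, mean)
cat("Mean mast cells per HRF (group x time):\n")
print(agg[order(agg$time_point, agg$group), ], row.names = FALSE,
      digits = 4)

cat("\nDegranulation inhibition by magnesium pretreatment (I%):\n")
inh <- do.call(rbind, lapply(c("5min", "25min", "24h"), function(tp) {
  f <- mean(ms$mean_degranulated[ms$group == "formalin" &
                                   ms$time_point == tp])
  m <- mean(ms$mean_degranulated[ms$group == "formalin_ms" &
                                   ms$time_point == tp])
  data.frame(time_point = tp, formalin = f, formalin_ms = m,
             inhibition_pct = degranulation_inhibition(f, m))
}))
print(inh, row.names = FALSE, digits = 3)
write.csv(inh, "results/mastcell_inhibition.csv", row.names = FALSE)

cat("\nDegranulation-pain correlations (magnesium arm, by position):\n")
ph <- phase_summaries(behavior)
pain <- ph[ph$group == "MS15", ]
for (cb in list(c("5min", 1), c("5min", 2), c("25min", 2))) {
  mc <- ms[ms$group == "formalin_ms" & ms$time_point == cb[1], ]
  paired <- pair_degranulation_pain(mc, pain, phase = as.integer(cb[2]),
                                    mode = "position")
  ct <- correlate_degranulation_pain(paired$mean_degranulated,
                                     paired$pain_s)
  cat(sprintf("  degranulation %-5s vs phase-%s pain: r = %6.3f, p = %.3f\n",
              cb[1], cb[2], ct$r, ct$p))
}
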