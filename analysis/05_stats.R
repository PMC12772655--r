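#!/usr/bin/env Rscript
# Stage 5: statistical comparisons at the 5% level — normality-gated
# paired tests of noise and CNR between scanners per dose, and one-way
# ANOVA of HU values across doses per scanner and material.

suppressPackageStartupMessages(library(lungphantom))

roi <- read.csv("results/roi_measurements.csv")
cnr <- cnr_table(roi)
st <- study_stats(roi, cnr, alpha = 0.05)

dir.create("results", showWarnings = FALSE)
write.csv(st, "results/stats.csv", row.names = FALSE)

cat("Noise comparisons (PCCT vs EIDCT), gated paired tests:\n")
print(st[st$metric == "noise",
         c("comparison", "test", "statistic", "p_value", "significant")],
      row.names = FALSE, digits = 3)
cat("\nHU-across-dose ANOVAs (expect non-significant):\n")
print(st[st$metric == "hu_vs_dose",
         c("comparison", "statistic", "p_value", "significant")],
      row.names = FALSE, digits = 3)
cat("\nCNR comparisons:\n")
print(st[st$metric == "cnr",
         c("comparison", "test", "p_value", "significant")],
      row.names = FALSE, digits = 3)
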