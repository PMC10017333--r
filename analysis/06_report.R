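#!/usr/bin/env Rscript
# 06 — Collect the run's headline numbers into one summary table.

suppressPackageStartupMessages(library(pinephenomics))

mr <- read.csv("results/run/model_results.csv", stringsAsFactors = FALSE)
h2 <- read.csv("results/run/h2_series.csv", stringsAsFactors = FALSE)
sel <- read.csv("results/run/selection.csv", stringsAsFactors = FALSE)

lines <- c(
  "Synthetic slash-pine UAV phenotyping run - summary",
  "==================================================",
  "",
  "Model comparison (pooled 11-month table, 80/20 split):")
for (tr in c("N", "NSC")) {
  sub <- mr[mr$trait == tr, ]
  lines <- c(lines, sprintf("  %s:", tr),
             sprintf("    %-4s cal R2 %.2f RMSE %.2f%% | val R2 %.2f RMSE %.2f%%%s",
                     sub$method, sub$cal_r2, sub$cal_rmse, sub$val_r2,
                     sub$val_rmse, ifelse(sub$best, "  <- best", "")))
}
lines <- c(lines, "",
           "Narrow-sense heritability of UAV-predicted traits by month:")
for (tr in c("N", "NSC")) {
  sub <- h2[h2$trait == tr, ]
  lines <- c(lines, sprintf("  %-3s %s", tr,
                            paste(sprintf("%s %.2f", sub$month, sub$h2),
                                  collapse = "  ")))
}
lines <- c(lines, "",
           sprintf("Families selected (both breeding values above the mean): %s",
                   paste(sel$family, collapse = ", ")))
writeLines(lines, "results/run/summary.txt")
writeLines(lines)
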