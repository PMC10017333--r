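#!/usr/bin/env Rscript
# 05 — Monthly genetic evaluation and bivariate family selection.
#
# Per trait and month, fits the REML mixed model (fixed intercept + site;
# random block, family, residual) to the UAV-predicted trait values of all
# matched trees, converts variance components to narrow-sense heritability
# (h2 = 2.5 s2_f / total) and family breeding values a_i = h2 (y_i - mu),
# and applies the first-quadrant selection rule over the late-season months.

suppressPackageStartupMessages(library(pinephenomics))

cfg <- read_config("results/run/config.yaml")
pred <- read.csv("results/run/predicted_traits.csv", stringsAsFactors = FALSE)

gen <- monthly_genetic_series(pred)
write.csv(gen$h2, "results/run/h2_series.csv", row.names = FALSE)
write.csv(gen$breeding_values, "results/run/breeding_values.csv",
          row.names = FALSE)
cat("monthly heritability of UAV-predicted traits:\n")
print(stats::reshape(gen$h2[c("trait", "month", "h2")], idvar = "trait",
                     timevar = "month", direction = "wide"), digits = 2)

sel_months <- intersect(cfg$selection$months, unique(gen$breeding_values$month))
sel <- select_families(gen$breeding_values, sel_months, k = cfg$selection$k)
write.csv(sel, "results/run/selection.csv", row.names = FALSE)
cat(sprintf("families above the breeding-value mean for both traits in %s:\n",
            paste(sel_months, collapse = "/")))
print(sel, digits = 3)
if (nrow(sel) == 0) {
  cat("  (none - the default generator draws every family from one distribution,\n",
      "  so an empty strict-quadrant selection is the truthful outcome; planted\n",
      "  superior families are recovered in the seeded recovery experiments)\n")
}

# genetic trend sanity: compare against heritability of the true simulated
# trait values (prediction error attenuates family signal)
truth <- read.csv("results/run/inputs/traits_true.csv", stringsAsFactors = FALSE)
gen_true <- monthly_genetic_series(truth)
cmp <- merge(gen$h2[c("trait", "month", "h2")],
             gen_true$h2[c("trait", "month", "h2")],
             by = c("trait", "month"), suffixes = c("_pred", "_true"))
cat(sprintf("mean h2 on predicted vs true traits: N %.2f vs %.2f, NSC %.2f vs %.2f\n",
            mean(cmp$h2_pred[cmp$trait == "N"]), mean(cmp$h2_true[cmp$trait == "N"]),
            mean(cmp$h2_pred[cmp$trait == "NSC"]), mean(cmp$h2_true[cmp$trait == "NSC"])))
write.csv(cmp, "results/run/h2_pred_vs_true.csv", row.names = FALSE)
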