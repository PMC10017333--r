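#!/usr/bin/env Rscript
# 04 — Fit and compare the four trait-prediction models.
#
# One seeded 80/20 calibration/validation split of the pooled table, then
# PLSR (<= 10 components, leave-one-out), SVM (radial, cost/width grid),
# GBM (learning-rate/tree grid) and RF (300 trees), each with internal CV
# only on the calibration rows. Reports R2/RMSE on both partitions, flags
# the best validation model per trait, ranks permutation importance, and
# predicts N and NSC for every matched tree-month with the winning models.

suppressPackageStartupMessages(library(pinephenomics))

cfg <- read_config("results/run/config.yaml")
ms <- cfg$master_seed
train <- read.csv("results/run/training_table.csv", stringsAsFactors = FALSE)

res <- compare_methods(train, traits = c("N", "NSC"),
                       specs = default_model_specs(seed = derive_seed(ms, "models")),
                       split_fraction = cfg$split$fraction,
                       split_seed = derive_seed(ms, "split"))
write.csv(res, "results/run/model_results.csv", row.names = FALSE)
print(res[c("method", "trait", "cal_r2", "cal_rmse", "val_r2", "val_rmse",
            "gap", "best")], digits = 3)

imp <- attr(res, "importance")
imp_df <- data.frame(model = rep(names(imp), each = length(predictor_names())),
                     predictor = rep(predictor_names(), length(imp)),
                     importance = unlist(imp, use.names = FALSE))
write.csv(imp_df, "results/run/importance.csv", row.names = FALSE)
for (tr in c("N", "NSC")) {
  best <- res$method[res$trait == tr & res$best]
  top <- sort(imp[[paste(tr, best, sep = ".")]], decreasing = TRUE)[1:5]
  cat(sprintf("%s (%s) top predictors: %s\n", tr, best,
              paste(sprintf("%s=%.0f", names(top), top), collapse = ", ")))
}

# predict both traits for every matched tree-month with the winning models
feats <- do.call(rbind, lapply(cfg$months, function(m)
  read.csv(file.path("results/run/months", m, "features.csv"),
           stringsAsFactors = FALSE)))
ok <- feats[!is.na(feats$tree_id) & !feats$flag_undefined, ]
models <- attr(res, "models")
pred <- do.call(rbind, lapply(c("N", "NSC"), function(tr) {
  best <- res$method[res$trait == tr & res$best][1]
  data.frame(tree_id = ok$tree_id, month = ok$month, trait = tr,
             value = predict(models[[paste(tr, best, sep = ".")]], ok),
             family = ok$family, block = ok$block, site = ok$site,
             stringsAsFactors = FALSE)
}))
write.csv(pred, "results/run/predicted_traits.csv", row.names = FALSE)
cat(sprintf("predicted %d tree-month trait values for genetic evaluation\n",
            nrow(pred)))
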