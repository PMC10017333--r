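#!/usr/bin/env Rscript
# 03 — Assemble the pooled modelling table.
#
# Joins every month's matched feature rows to the ground-truth needle
# chemistry of the sampled trees, pooling all 11 flights into one table (the
# workflow aggregates months before the calibration/validation split).
# Writes results/run/training_table.csv and a feature summary.

suppressPackageStartupMessages(library(pinephenomics))

cfg <- read_config("results/run/config.yaml")
ground <- read.csv("results/run/inputs/ground_truth.csv", stringsAsFactors = FALSE)

feats <- do.call(rbind, lapply(cfg$months, function(m)
  read.csv(file.path("results/run/months", m, "features.csv"),
           stringsAsFactors = FALSE)))
cat(sprintf("pooled %d detections over %d months; %d rows flagged undefined\n",
            nrow(feats), length(cfg$months), sum(feats$flag_undefined)))

gw <- stats::reshape(ground[c("tree_id", "month", "trait", "value")],
                     idvar = c("tree_id", "month"), timevar = "trait",
                     direction = "wide")
names(gw) <- sub("^value\\.", "", names(gw))
train <- merge(feats[!is.na(feats$tree_id) & !feats$flag_undefined, ], gw,
               by = c("tree_id", "month"))
write.csv(train, "results/run/training_table.csv", row.names = FALSE)
cat(sprintf("training table: %d ground-sampled tree-months, %d predictors\n",
            nrow(train), length(predictor_names())))

# quick look at the strongest single predictors
cors <- sapply(predictor_names(), function(p) cor(train[[p]], train$N))
cat("top |cor| with N:",
    paste(names(sort(abs(cors), decreasing = TRUE))[1:5], collapse = ", "), "\n")
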