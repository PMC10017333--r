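#!/usr/bin/env Rscript
# 01 — Simulate the breeding trial and render the monthly imagery.
#
# Generates the progeny-trial layout (2 sites x 20 blocks x 20 open-
# pollinated families, single-tree plots at 2 x 3 m), monthly needle N and
# NSC values under the family/block mixed model, trait-linked canopy
# reflectance, the monthly ground-sampling subsets (35 trees/month over 11
# flights = 385 samples, the field protocol's order of magnitude), and the
# per-month DSM/DTM/band rasters at 10 cm pixels. Everything lands under
# results/run/inputs/ for the later stages.

suppressPackageStartupMessages(library(pinephenomics))

cfg <- pipeline_config(rendering = list(resolution = 0.1, margin = 3),
                       ground = list(n_per_month = 35),
                       master_seed = 42L)
dir.create("results/run", recursive = TRUE, showWarnings = FALSE)
write_config(cfg, "results/run/config.yaml")
ms <- cfg$master_seed

dir.create("results/run/inputs", recursive = TRUE, showWarnings = FALSE)
layout <- do.call(make_layout, c(cfg$layout, seed = derive_seed(ms, "layout")))
print(layout)
write.csv(layout$trees[c("tree_id", "site", "block", "family", "x", "y")],
          "results/run/inputs/field.csv", row.names = FALSE)

gn <- genetic_config(var_family = cfg$genetics$N$var_family,
                     var_block = cfg$genetics$N$var_block,
                     var_residual = cfg$genetics$N$var_residual,
                     site_effects = unlist(cfg$genetics$N$site_effects),
                     monthly_means = unlist(cfg$genetics$N$monthly_means),
                     bounds = unlist(cfg$genetics$N$bounds),
                     seed = derive_seed(ms, "traits_N"))
gc <- genetic_config(var_family = cfg$genetics$NSC$var_family,
                     var_block = cfg$genetics$NSC$var_block,
                     var_residual = cfg$genetics$NSC$var_residual,
                     site_effects = unlist(cfg$genetics$NSC$site_effects),
                     monthly_means = unlist(cfg$genetics$NSC$monthly_means),
                     bounds = unlist(cfg$genetics$NSC$bounds),
                     seed = derive_seed(ms, "traits_NSC"))
traits <- rbind(simulate_traits(layout, gn, cfg$months, "N"),
                simulate_traits(layout, gc, cfg$months, "NSC"))
write.csv(traits, "results/run/inputs/traits_true.csv", row.names = FALSE)
cat(sprintf("simulated %d tree-month trait values (true h2: N %.2f, NSC %.2f)\n",
            nrow(traits),
            2.5 * gn$var_family / (gn$var_family + gn$var_block + gn$var_residual),
            2.5 * gc$var_family / (gc$var_family + gc$var_block + gc$var_residual)))

ground <- do.call(rbind, lapply(cfg$months, function(m)
  sample_ground_truth(traits, m, cfg$ground$n_per_month,
                      seed = derive_seed(ms, paste0("ground_", m)))))
write.csv(ground, "results/run/inputs/ground_truth.csv", row.names = FALSE)
cat(sprintf("ground sampling: %d trees x %d months = %d chemistry samples\n",
            cfg$ground$n_per_month, length(cfg$months),
            length(unique(paste(ground$tree_id, ground$month)))))

refl <- simulate_reflectance(traits, optics_config(noise_sd = cfg$optics$noise_sd,
                                                   seed = derive_seed(ms, "optics")))
for (m in cfg$months) {
  st <- render_rasters(layout, refl, m, resolution = cfg$rendering$resolution,
                       margin = cfg$rendering$margin)
  write_raster_stack(st, file.path("results/run/inputs/rasters", m))
  cat(sprintf("rendered %s: %d x %d px\n", m, nrow(st$grids$dsm),
              ncol(st$grids$dsm)))
}
cat("inputs complete under results/run/inputs/\n")
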