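# End-to-end orchestration: simulate -> render -> detect -> features ->
# fit -> genetics, from one config with one master seed. Every stage seed
# is derived deterministically from the master seed and the stage name, and
# each stage consumes only artifacts written by earlier stages, so a run is
# re-startable from any checkpoint and byte-identical under one seed.

#' Assemble a pipeline configuration
#'
#' Returns the default configuration (the study-scale trial: 2 sites x 20
#' blocks x 20 families, 11 monthly flights, 35 ground samples per month,
#' 5 cm pixels) with any overrides merged in. The config round-trips
#' through YAML unchanged.
#'
#' @param ... Named overrides, nested lists merged with
#'   \code{modifyList} (e.g. \code{layout = list(blocks_per_site = 4)}).
#' @param master_seed Master seed; all stage seeds derive from it.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(..., master_seed = 42L) {
  cfg <- list(
    master_seed = as.integer(master_seed),
    months = flight_months(),
    layout = list(sites = 2, blocks_per_site = 20, families = 20,
                  spacing_x = 2, spacing_y = 3,
                  height_mean = 5, height_sd = 0.5,
                  crown_radius_range = c(0.9, 1.25)),
    genetics = list(
      N = list(var_family = 0.010, var_block = 0.010, var_residual = 0.080,
               site_effects = list(S1 = 0, S2 = 0.10),
               monthly_means = as.list(default_n_genetics()$monthly_means),
               bounds = c(0.5, 4)),
      NSC = list(var_family = 0.15, var_block = 0.10, var_residual = 1.20,
                 site_effects = list(S1 = 0, S2 = -0.30),
                 monthly_means = as.list(default_nsc_genetics()$monthly_means),
                 bounds = c(5, 15))),
    optics = list(noise_sd = 0.01),
    rendering = list(resolution = 0.05, margin = 3),
    detection = list(min_height = 2.6, max_crown_diameter = 2.5,
                     a = 0, b = 0.3, r_min = 0.5),
    crowns = list(seed_fraction = 0.45, crown_fraction = 0.55),
    matching = list(tolerance = 1.0),
    ground = list(n_per_month = 35),
    split = list(fraction = 0.8),
    selection = list(months = c("Jul", "Aug", "Sep", "Oct"), k = 5)
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline config as YAML
#' @param config A \code{pipeline_config}.
#' @param path YAML file path.
#' @return \code{read_config} returns the \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, c(cfg[setdiff(names(cfg), "master_seed")],
                             master_seed = cfg$master_seed))
}

cfg_genetic <- function(g, seed) {
  genetic_config(var_family = g$var_family, var_block = g$var_block,
                 var_residual = g$var_residual,
                 site_effects = unlist(g$site_effects),
                 monthly_means = unlist(g$monthly_means),
                 bounds = unlist(g$bounds), seed = seed)
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

run_stage <- function(name, manifest_path, manifest, expr) {
  tryCatch(expr, error = function(e) {
    manifest$failed_stage <- name
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
    stop_cfg("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full synthetic pipeline
#'
#' Generates the trial (layout, monthly traits, reflectance), renders and
#' writes the monthly raster stacks plus the field and ground-truth CSVs
#' under \code{out_dir/inputs/}, then hands those files to
#' \code{\link{run_from_rasters}} for the imagery-side analysis. Outputs are
#' byte-identical across runs with the same config.
#'
#' @param config A \code{pipeline_config}.
#' @param out_dir Output directory.
#' @return Invisibly, the report list from \code{\link{run_from_rasters}}.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- file.path(out_dir, "inputs")
  dir.create(inputs, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con))
  ms <- config$master_seed
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(master_seed = ms,
                   package_version = as.character(utils::packageVersion("pinephenomics")),
                   config = unclass(config))

  layout <- run_stage("layout", manifest_path, manifest, {
    log_line(log_con, "stage layout: seed %d", derive_seed(ms, "layout"))
    do.call(make_layout, c(config$layout, seed = derive_seed(ms, "layout")))
  })
  field <- layout$trees[c("tree_id", "site", "block", "family", "x", "y")]
  write.csv(field, file.path(inputs, "field.csv"), row.names = FALSE)

  traits <- run_stage("traits", manifest_path, manifest, {
    gn <- cfg_genetic(config$genetics$N, derive_seed(ms, "traits_N"))
    gc <- cfg_genetic(config$genetics$NSC, derive_seed(ms, "traits_NSC"))
    rbind(simulate_traits(layout, gn, config$months, "N"),
          simulate_traits(layout, gc, config$months, "NSC"))
  })
  write.csv(traits, file.path(inputs, "traits_true.csv"), row.names = FALSE)

  ground <- run_stage("ground_sampling", manifest_path, manifest, {
    do.call(rbind, lapply(config$months, function(m)
      sample_ground_truth(traits, m, config$ground$n_per_month,
                          seed = derive_seed(ms, paste0("ground_", m)))))
  })
  write.csv(ground, file.path(inputs, "ground_truth.csv"), row.names = FALSE)

  run_stage("render", manifest_path, manifest, {
    optics <- optics_config(noise_sd = config$optics$noise_sd,
                            seed = derive_seed(ms, "optics"))
    refl <- simulate_reflectance(traits, optics)
    terr <- terrain_config()
    for (m in config$months) {
      log_line(log_con, "stage render: month %s", m)
      stack <- render_rasters(layout, refl, m,
                              resolution = config$rendering$resolution,
                              terrain = terr, margin = config$rendering$margin)
      write_raster_stack(stack, file.path(inputs, "rasters", m))
    }
  })

  run_from_rasters(config, file.path(inputs, "rasters"),
                   file.path(inputs, "field.csv"),
                   file.path(inputs, "ground_truth.csv"),
                   out_dir, .log_con = log_con, .manifest = manifest)
}

#' Run the analysis from raster and field files
#'
#' The imagery-side entry point, consuming what a photogrammetric pipeline
#' (or \code{\link{run_pipeline}}) wrote to disk: per-month raster
#' directories (dsm/dtm + five bands), a field CSV of planted positions and
#' labels, and a ground-truth CSV of measured traits. Per month it computes
#' the CHM, detects and delineates crowns, extracts crown spectra, builds
#' the 21-feature table and matches detections to field records; then fits
#' the four model families on the pooled ground-sampled rows, predicts both
#' traits for every matched tree-month, and runs the monthly genetic
#' evaluation and bivariate family selection on the predictions.
#'
#' @param config A \code{pipeline_config}.
#' @param raster_dir Directory with one subdirectory per month.
#' @param field_csv CSV with tree_id, site, block, family, x, y.
#' @param ground_csv CSV with tree_id, month, trait, value.
#' @param out_dir Output directory.
#' @param .log_con,.manifest Internal (shared with \code{run_pipeline}).
#' @return Invisibly, a list: features, model_results, predicted,
#'   genetics (h2 + breeding values), selection, match_report.
#' @export
run_from_rasters <- function(config, raster_dir, field_csv, ground_csv,
                             out_dir, .log_con = NULL, .manifest = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ms <- config$master_seed
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- .manifest %||% list(master_seed = ms, config = unclass(config))
  months <- intersect(config$months, list.dirs(raster_dir, recursive = FALSE,
                                               full.names = FALSE))
  if (!length(months)) stop_cfg("no month subdirectories found in %s", raster_dir)
  field <- read.csv(field_csv, stringsAsFactors = FALSE)
  ground <- read.csv(ground_csv, stringsAsFactors = FALSE)

  feats <- list(); match_report <- list()
  for (m in months) {
    res <- run_stage(paste0("detect_", m), manifest_path, manifest, {
      stack <- read_raster_stack(file.path(raster_dir, m))
      need <- c("dsm", "dtm", "blue", "green", "red", "rededge", "nir")
      miss <- setdiff(need, names(stack$grids))
      if (length(miss))
        stop_cfg("month %s: missing raster layer(s): %s", m,
                 paste(miss, collapse = ", "))
      chm <- compute_chm(stack$grids$dsm, stack$grids$dtm, stack$nodata)
      det <- detect_trees(chm, stack$transform,
                          min_height = config$detection$min_height,
                          max_crown_diameter = config$detection$max_crown_diameter,
                          a = config$detection$a, b = config$detection$b,
                          r_min = config$detection$r_min)
      crowns <- delineate_crowns(chm, det, stack$transform,
                                 seed_fraction = config$crowns$seed_fraction,
                                 crown_fraction = config$crowns$crown_fraction,
                                 max_crown_diameter = config$detection$max_crown_diameter)
      spectra <- extract_spectra(stack, crowns)
      spectra <- spectra[!spectra$flag_empty, , drop = FALSE]
      fx <- compute_features(spectra)
      fx <- match_trees(fx, field, tolerance = config$matching$tolerance)
      fx$month <- m
      log_line(.log_con, "month %s: %d detections, %d matched", m,
               nrow(fx), sum(!is.na(fx$tree_id)))
      mdir <- file.path(out_dir, "months", m)
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      write.csv(fx, file.path(mdir, "features.csv"), row.names = FALSE)
      write_crowns_geojson(crowns, file.path(mdir, "crowns.geojson"))
      list(fx = fx, unmatched = attr(fx, "unmatched_field"))
    })
    feats[[m]] <- res$fx
    match_report[[m]] <- res$unmatched
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL

  # training table: ground-sampled trees joined to their extracted features
  train <- run_stage("training_table", manifest_path, manifest, {
    gw <- stats::reshape(ground[c("tree_id", "month", "trait", "value")],
                         idvar = c("tree_id", "month"), timevar = "trait",
                         direction = "wide")
    names(gw) <- sub("^value\\.", "", names(gw))
    tt <- merge(features[!is.na(features$tree_id), ], gw,
                by = c("tree_id", "month"))
    tt[!tt$flag_undefined, , drop = FALSE]
  })
  log_line(.log_con, "training table: %d ground-sampled tree-months", nrow(train))

  results <- run_stage("models", manifest_path, manifest, {
    compare_methods(train, traits = c("N", "NSC"),
                    specs = default_model_specs(seed = derive_seed(ms, "models")),
                    split_fraction = config$split$fraction,
                    split_seed = derive_seed(ms, "split"))
  })
  write.csv(results, file.path(out_dir, "model_results.csv"), row.names = FALSE)
  imp <- attr(results, "importance")
  if (length(imp)) {
    imp_df <- data.frame(model = rep(names(imp), each = length(predictor_names())),
                         predictor = rep(predictor_names(), length(imp)),
                         importance = unlist(imp, use.names = FALSE))
    write.csv(imp_df, file.path(out_dir, "importance.csv"), row.names = FALSE)
  }

  predicted <- run_stage("predict", manifest_path, manifest, {
    models <- attr(results, "models")
    ok <- features[!is.na(features$tree_id) & !features$flag_undefined, ]
    out <- list()
    for (tr in c("N", "NSC")) {
      best <- results$method[results$trait == tr & results$best][1]
      fit <- models[[paste(tr, best, sep = ".")]]
      out[[tr]] <- data.frame(tree_id = ok$tree_id, month = ok$month,
                              trait = tr, value = predict(fit, ok),
                              family = ok$family, block = ok$block,
                              site = ok$site, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  rownames(predicted) <- NULL
  write.csv(predicted, file.path(out_dir, "predicted_traits.csv"),
            row.names = FALSE)

  gen <- run_stage("genetics", manifest_path, manifest,
                   monthly_genetic_series(predicted))
  write.csv(gen$h2, file.path(out_dir, "h2_series.csv"), row.names = FALSE)
  write.csv(gen$breeding_values, file.path(out_dir, "breeding_values.csv"),
            row.names = FALSE)

  selection <- run_stage("selection", manifest_path, manifest, {
    sel_months <- intersect(config$selection$months, unique(gen$breeding_values$month))
    if (length(sel_months)) {
      select_families(gen$breeding_values, sel_months, k = config$selection$k)
    } else data.frame(family = character(0), score = numeric(0))
  })
  write.csv(selection, file.path(out_dir, "selection.csv"), row.names = FALSE)

  manifest$months <- months
  manifest$n_detections <- nrow(features)
  manifest$n_training <- nrow(train)
  manifest$unmatched_field <- lapply(match_report, as.character)
  manifest$stage_seeds <- stats::setNames(
    lapply(c("layout", "traits_N", "traits_NSC", "optics", "models", "split"),
           function(s) derive_seed(ms, s)),
    c("layout", "traits_N", "traits_NSC", "optics", "models", "split"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  log_line(.log_con, "pipeline complete: %d months, %d detections",
           length(months), nrow(features))

  invisible(list(features = features, model_results = results,
                 predicted = predicted, genetics = gen,
                 selection = selection, match_report = match_report))
}
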