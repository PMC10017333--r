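# Split arithmetic, metrics, the four model engines, permutation
# importance, leakage audit and cross-method comparison.

test_that("split arithmetic matches the floor rule and is seeded", {
  d <- data.frame(x = seq_len(383))
  p <- split_data(d, 0.8, seed = 4)
  expect_equal(nrow(p$calibration), 306)
  expect_equal(nrow(p$validation), 77)
  expect_length(intersect(p$calibration$x, p$validation$x), 0)
  p2 <- split_data(d, 0.8, seed = 4)
  expect_identical(p, p2)
  expect_error(split_data(d[1:5, , drop = FALSE], 0.8), "at least 10")
  pfull <- split_data(d, 1.0, seed = 1)
  expect_equal(nrow(pfull$validation), 0)
})

test_that("evaluation metrics follow their definitions exactly", {
  fx <- linear_feature_table(60, noise_sd = 0.2, seed = 2)
  fit <- fit_model(fx, "N", model_spec("RF", seed = 1))
  ev <- evaluate(fit, fx)
  expect_gte(ev$rmse, 0)
  # metric definitions on hand-built prediction vectors
  obs <- fx$N
  pred_perfect <- obs
  expect_equal(1 - sum((obs - pred_perfect)^2) / sum((obs - mean(obs))^2), 1)
  pred_mean <- rep(mean(obs), length(obs))
  expect_equal(1 - sum((obs - pred_mean)^2) / sum((obs - mean(obs))^2), 0)
  pred_off <- obs + 1
  expect_equal(sqrt(mean((obs - pred_off)^2)), 1.0, tolerance = 1e-12)
  expect_error(evaluate(fit, fx[0, ]), "empty")
  cst <- fx
  cst$N <- 1
  expect_error(evaluate(fit, cst), "variance")
  expect_error(fit_model(cst, "N", model_spec("RF")), "constant")
})

test_that("a noiseless linear trait is fit essentially perfectly by PLSR", {
  # linear-model limit: allow the component cap up to the predictor rank
  # (the 10-component protocol default is a field-data setting, not a bound
  # of the method)
  fx <- linear_feature_table(150, noise_sd = 0, seed = 3)
  p <- split_data(fx, 0.8, seed = 5)
  fit <- fit_model(p$calibration, "N", model_spec("PLSR", seed = 1, ncomp = 18))
  expect_gte(evaluate(fit, p$validation)$r2, 0.999)
})

test_that("every engine is reproducible under its seed", {
  fx <- linear_feature_table(80, noise_sd = 0.3, seed = 6)
  p <- split_data(fx, 0.8, seed = 1)
  for (m in c("PLSR", "SVM", "GBM", "RF")) {
    f1 <- fit_model(p$calibration, "N", model_spec(m, seed = 9))
    f2 <- fit_model(p$calibration, "N", model_spec(m, seed = 9))
    expect_identical(predict(f1, p$validation), predict(f2, p$validation),
                     label = paste(m, "prediction reproducibility"))
  }
})

test_that("permutation importance isolates the informative predictor", {
  fx <- linear_feature_table(120, noise_sd = 0.02, seed = 7)
  fit <- fit_model(fx, "N", model_spec("RF", seed = 2))
  imp <- variable_importance(fit, fx, seed = 3)
  expect_equal(max(imp), 100)
  expect_equal(names(which.max(imp)), "NDVI")
  expect_true(all(imp >= 0))
  # scores unaffected by the column order of the supplied data
  fx_shuf <- fx[, rev(names(fx))]
  imp2 <- variable_importance(fit, fx_shuf, seed = 3)
  expect_identical(imp, imp2)
  # the duplicated pair (NRI = GRVI) shares signal without vanishing jointly
  fx2 <- linear_feature_table(120, noise_sd = 0, seed = 8)
  fx2$N <- 2 * fx2$GRVI + rnorm(120, 0, 0.01)
  fit2 <- fit_model(fx2, "N", model_spec("RF", seed = 2))
  imp_pair <- variable_importance(fit2, fx2, seed = 3)[c("NRI", "GRVI")]
  expect_gt(sum(imp_pair), 0)
})

test_that("no calibration-set leakage: validation rows never shape the model", {
  fx <- linear_feature_table(100, noise_sd = 0.3, seed = 10)
  p <- split_data(fx, 0.8, seed = 11)
  fit <- fit_model(p$calibration, "N", model_spec("SVM", seed = 1))
  # corrupt the validation rows wholesale; the fitted model and its
  # calibration predictions must be unchanged
  probe <- predict(fit, p$calibration)
  fx2 <- fx
  val_rows <- as.integer(rownames(p$validation))
  fx2$N[match(val_rows, as.integer(rownames(fx2)))] <- 999
  for (b in c("blue", "nir")) fx2[[b]][match(val_rows, as.integer(rownames(fx2)))] <- 0.999
  p2 <- split_data(fx2, 0.8, seed = 11)
  expect_identical(p2$calibration, p$calibration) # same seeded partition
  fit2 <- fit_model(p2$calibration, "N", model_spec("SVM", seed = 1))
  expect_identical(predict(fit2, p$calibration), probe)
})

test_that("compare_methods reports 4 methods x 2 traits with sane gaps", {
  fx <- linear_feature_table(120, noise_sd = 0.2, seed = 12)
  fx$NSC <- 5 * fx$GNDVI + rnorm(120, 0, 0.3)
  res <- compare_methods(fx, traits = c("N", "NSC"),
                         specs = default_model_specs(seed = 2),
                         split_seed = 3, importance = FALSE)
  expect_equal(nrow(res), 8)
  expect_setequal(res$method, c("PLSR", "SVM", "GBM", "RF"))
  expect_equal(sum(res$best), 2)
  expect_equal(res$gap, res$cal_r2 - res$val_r2)
  # strong signal: calibration at least matches validation up to noise
  expect_true(all(res$cal_r2 >= res$val_r2 - 0.05))
  res2 <- compare_methods(fx, traits = c("N", "NSC"),
                          specs = default_model_specs(seed = 2),
                          split_seed = 3, importance = FALSE)
  # bit-identical result table under the same master seed (fitted engine
  # objects carry environments/pointers, so compare the reported values)
  expect_identical(res[, names(res)], res2[, names(res2)])
})

test_that("RF overfits more than PLSR on small noisy samples", {
  wins <- 0
  for (s in 1:11) {
    fx <- linear_feature_table(60, noise_sd = 1.0, seed = 100 + s)
    p <- split_data(fx, 0.8, seed = s)
    rf <- fit_model(p$calibration, "N", model_spec("RF", seed = s))
    pl <- fit_model(p$calibration, "N", model_spec("PLSR", seed = s))
    gap_rf <- evaluate(rf, p$calibration)$r2 - evaluate(rf, p$validation)$r2
    gap_pl <- evaluate(pl, p$calibration)$r2 - evaluate(pl, p$validation)$r2
    wins <- wins + (gap_rf > gap_pl)
  }
  expect_gt(wins, 11 / 2)
})

test_that("more optics noise never helps held-out accuracy (trend)", {
  mean_r2 <- sapply(c(0.005, 0.02, 0.08), function(ns) {
    r2 <- sapply(1:12, function(s) {
      lay <- small_layout(seed = 200 + s, sites = 1, blocks = 5, families = 8)
      trN <- simulate_traits(lay, default_n_genetics(seed = 300 + s), "Jul", "N")
      trC <- simulate_traits(lay, default_nsc_genetics(seed = 400 + s), "Jul", "NSC")
      refl <- simulate_reflectance(rbind(trN, trC),
                                   optics_config(noise_sd = ns, seed = 500 + s))
      fx <- compute_features(stats::setNames(
        refl[c("blue", "green", "red", "rededge", "nir")],
        c("blue", "green", "red", "rededge", "nir")))
      fx$N <- trN$value[match(refl$tree_id, trN$tree_id)]
      fx <- fx[!fx$flag_undefined, , drop = FALSE]
      p <- split_data(fx, 0.8, seed = s)
      fit <- fit_model(p$calibration, "N", model_spec("RF", seed = s))
      evaluate(fit, p$validation)$r2
    })
    mean(r2)
  })
  expect_true(mean_r2[1] >= mean_r2[2] && mean_r2[2] >= mean_r2[3])
})
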