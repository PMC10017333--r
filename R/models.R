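# Machine-learning predictors of needle chemistry from the 21 spectral
# features, with the study's split, metrics and importance ranking.
#
# Engines: PLSR via mixOmics (NIPALS regression mode), SVM via e1071
# (radial kernel, grid over cost/width), GBM via xgboost (grid over
# learning rate and tree count, depth 3), RF via randomForest (300 trees).
# Predictors are standardised with calibration-set statistics only; grid
# search is scored by cross-validated RMSE inside the calibration set, so
# validation rows are touched exactly once, at evaluation.

#' Split a feature table into calibration and validation sets
#'
#' Seeded uniform partition: calibration gets floor(n * fraction) rows
#' (383 rows at 0.8 give 306 / 77), validation the remainder.
#'
#' @param data data.frame with at least 10 rows.
#' @param fraction Calibration fraction (default 0.8).
#' @param seed Integer seed.
#' @return list(calibration, validation) of disjoint row subsets.
#' @export
split_data <- function(data, fraction = 0.8, seed = 1L) {
  n <- nrow(data)
  if (n < 10) stop_cfg("need at least 10 rows to split, got %d", n)
  if (fraction <= 0 || fraction > 1) stop_cfg("fraction must be in (0, 1]")
  n_cal <- floor(n * fraction)
  with_seed(seed, {
    idx <- sample.int(n, n_cal)
    list(calibration = data[sort(idx), , drop = FALSE],
         validation = data[setdiff(seq_len(n), idx), , drop = FALSE])
  })
}

#' Hyperparameter specification for one model family
#'
#' Defaults follow the study protocol where stated (PLSR: up to 10
#' components chosen by leave-one-out CV; RF: 300 trees) and conventional
#' grids where it is silent (SVM cost/width; GBM learning rate and tree
#' count, searched by 5-fold CV).
#'
#' @param method One of "PLSR", "SVM", "GBM", "RF".
#' @param seed Integer seed for fold assignment and stochastic fitters.
#' @param ... Overrides: \code{ncomp} (PLSR), \code{cost}, \code{gamma}
#'   (SVM), \code{eta}, \code{nrounds}, \code{max_depth} (GBM),
#'   \code{ntree} (RF), \code{cv_folds}.
#' @return A \code{model_spec} list.
#' @export
model_spec <- function(method = c("PLSR", "SVM", "GBM", "RF"), seed = 1L, ...) {
  method <- match.arg(method)
  defaults <- switch(method,
    PLSR = list(ncomp = 10L),
    SVM = list(cost = c(0.25, 0.5, 1, 2, 4), gamma = c(0.01, 0.1, 1),
               cv_folds = 5L),
    GBM = list(eta = c(0.01, 0.05, 0.1), nrounds = c(100L, 300L, 500L, 1000L),
               max_depth = 3L, cv_folds = 5L),
    RF = list(ntree = 300L))
  spec <- utils::modifyList(defaults, list(...))
  spec$method <- method
  spec$seed <- seed
  structure(spec, class = "model_spec")
}

#' The study's four model specifications
#' @param seed Integer seed shared by all four.
#' @return Named list of \code{model_spec}s (PLSR, SVM, GBM, RF).
#' @export
default_model_specs <- function(seed = 1L) {
  stats::setNames(lapply(c("PLSR", "SVM", "GBM", "RF"), model_spec, seed = seed),
                  c("PLSR", "SVM", "GBM", "RF"))
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

cv_fold_ids <- function(n, k, seed) {
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' Fit one trait-prediction model on a calibration set
#'
#' Standardises the 21 predictors with calibration means/SDs, runs the
#' spec's hyperparameter search (CV entirely inside the calibration set),
#' and fits the final model at the chosen setting. All randomness is
#' seeded through the spec.
#'
#' @param calibration Calibration data.frame holding the predictor columns
#'   and the trait; rows flagged \code{flag_undefined} must be removed
#'   beforehand.
#' @param trait Name of the response column.
#' @param spec A \code{model_spec}.
#' @param predictors Predictor column names (default
#'   \code{\link{predictor_names}()}).
#' @return A \code{trait_model} object with a \code{predict} method.
#' @export
fit_model <- function(calibration, trait, spec,
                      predictors = predictor_names()) {
  stopifnot(inherits(spec, "model_spec"))
  miss <- setdiff(c(predictors, trait), names(calibration))
  if (length(miss)) stop_cfg("missing column(s): %s", paste(miss, collapse = ", "))
  if (isTRUE(any(calibration$flag_undefined)))
    stop_cfg("calibration contains rows flagged undefined; drop them first")
  y <- calibration[[trait]]
  if (stats::sd(y) == 0) stop_cfg("trait '%s' is constant in calibration", trait)
  X <- as.matrix(calibration[predictors])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1 # constant predictors carry no signal; leave centred
  Xs <- scale(X, ctr, scl)
  n <- nrow(Xs)

  fitted <- with_seed(spec$seed, switch(spec$method,
    PLSR = {
      # stay strictly below the predictor rank: the feature set contains an
      # exact duplicate pair, and NIPALS prediction degenerates at full rank
      kmax <- min(spec$ncomp, qr(Xs)$rank - 1L, n - 2L)
      # leave-one-out CV over the number of components
      press <- matrix(NA_real_, n, kmax)
      for (i in seq_len(n)) {
        f <- mixOmics::pls(Xs[-i, , drop = FALSE], y[-i], ncomp = kmax,
                           mode = "regression", scale = FALSE)
        p <- predict(f, Xs[i, , drop = FALSE])$predict[1, 1, ]
        press[i, ] <- (p - y[i])^2
      }
      loo_rmse <- sqrt(colMeans(press))
      k <- which.min(loo_rmse)
      fit <- mixOmics::pls(Xs, y, ncomp = kmax, mode = "regression", scale = FALSE)
      list(fit = fit, params = list(ncomp = k), loo_rmse = loo_rmse)
    },
    SVM = {
      grid <- expand.grid(cost = spec$cost, gamma = spec$gamma)
      folds <- cv_fold_ids(n, spec$cv_folds, spec$seed)
      cv <- vapply(seq_len(nrow(grid)), function(g) {
        errs <- vapply(seq_len(spec$cv_folds), function(f) {
          tr <- folds != f
          m <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = grid$cost[g], gamma = grid$gamma[g])
          rmse(y[!tr], predict(m, Xs[!tr, , drop = FALSE]))
        }, 0)
        mean(errs)
      }, 0)
      best <- grid[which.min(cv), ]
      fit <- e1071::svm(Xs, y, kernel = "radial", cost = best$cost,
                        gamma = best$gamma)
      list(fit = fit, params = as.list(best), cv_rmse = cv)
    },
    GBM = {
      grid <- expand.grid(eta = spec$eta, nrounds = spec$nrounds)
      folds <- cv_fold_ids(n, spec$cv_folds, spec$seed)
      nmax <- max(spec$nrounds)
      cv <- matrix(0, length(spec$eta), length(spec$nrounds),
                   dimnames = list(spec$eta, spec$nrounds))
      for (ei in seq_along(spec$eta)) {
        for (f in seq_len(spec$cv_folds)) {
          tr <- folds != f
          m <- xgboost::xgboost(x = Xs[tr, , drop = FALSE], y = y[tr],
                                nrounds = nmax, learning_rate = spec$eta[ei],
                                max_depth = spec$max_depth,
                                objective = "reg:squarederror",
                                nthreads = 1, verbosity = 0)
          for (ni in seq_along(spec$nrounds)) {
            p <- predict(m, Xs[!tr, , drop = FALSE],
                         iterationrange = c(1, spec$nrounds[ni] + 1))
            cv[ei, ni] <- cv[ei, ni] + rmse(y[!tr], p) / spec$cv_folds
          }
        }
      }
      best <- which(cv == min(cv), arr.ind = TRUE)[1, ]
      eta <- spec$eta[best[1]]; nrounds <- spec$nrounds[best[2]]
      fit <- xgboost::xgboost(x = Xs, y = y, nrounds = nrounds,
                              learning_rate = eta, max_depth = spec$max_depth,
                              objective = "reg:squarederror",
                              nthreads = 1, verbosity = 0)
      list(fit = fit, params = list(eta = eta, nrounds = nrounds), cv_rmse = cv)
    },
    RF = {
      fit <- randomForest::randomForest(Xs, y, ntree = spec$ntree)
      list(fit = fit, params = list(ntree = spec$ntree))
    }))

  structure(list(method = spec$method, trait = trait, predictors = predictors,
                 center = ctr, scale = scl, fit = fitted$fit,
                 params = fitted$params, spec = spec,
                 cv_profile = fitted$cv_rmse %||% fitted$loo_rmse),
            class = "trait_model")
}

#' @export
predict.trait_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$predictors])
  Xs <- scale(X, object$center, object$scale)
  switch(object$method,
    PLSR = {
      k <- object$params$ncomp
      predict(object$fit, Xs)$predict[, 1, k]
    },
    SVM = as.numeric(predict(object$fit, Xs)),
    GBM = predict(object$fit, Xs),
    RF = as.numeric(predict(object$fit, Xs)))
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("trait_model: %s for %s (%s)\n", x$method, x$trait,
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Evaluate a fitted model on a dataset
#'
#' R^2 = 1 - SS_res / SS_tot about the dataset's own mean (not a squared
#' correlation; negative values are possible on held-out data), RMSE in
#' trait percent units.
#'
#' @param model A \code{trait_model}.
#' @param data Nonempty data.frame with predictors and the trait.
#' @return list(r2, rmse, n).
#' @export
evaluate <- function(model, data) {
  if (nrow(data) == 0) stop_cfg("cannot evaluate on an empty dataset")
  obs <- data[[model$trait]]
  if (is.null(obs)) stop_cfg("trait '%s' missing from dataset", model$trait)
  if (stats::var(obs) == 0) stop_cfg("trait variance is zero; R^2 undefined")
  pred <- predict(model, data)
  list(r2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
       rmse = rmse(obs, pred), n = length(obs))
}

#' Permutation variable importance, scaled 0-100
#'
#' Mean RMSE increase over seeded permutations of each predictor column
#' (method-agnostic, so scores are comparable across model families),
#' negatives clamped to zero, then linearly rescaled so the maximum is 100.
#'
#' @param model A \code{trait_model}.
#' @param data Data to permute over (normally the calibration set).
#' @param n_perm Permutations per predictor (default 10).
#' @param seed Integer seed.
#' @return Named numeric vector over the model's predictors, decreasing
#'   order preserved on names; max 100 when any predictor is informative.
#' @export
variable_importance <- function(model, data, n_perm = 10L, seed = 1L) {
  obs <- data[[model$trait]]
  base <- rmse(obs, predict(model, data))
  with_seed(seed, {
    raw <- vapply(model$predictors, function(p) {
      incr <- vapply(seq_len(n_perm), function(j) {
        d <- data
        d[[p]] <- d[[p]][sample.int(nrow(d))]
        rmse(obs, predict(model, d)) - base
      }, 0)
      mean(incr)
    }, 0)
    raw[raw < 0] <- 0
    if (max(raw) > 0) raw <- 100 * raw / max(raw)
    raw
  })
}

#' Fit and compare the four model families on one feature table
#'
#' Runs the full protocol: one seeded 80/20 split, per trait and method a
#' calibration fit with internal hyperparameter search, evaluation on both
#' partitions, permutation importance, and the overfitting gap
#' (calibration R^2 minus validation R^2). The best validation-R^2 method
#' is flagged per trait.
#'
#' @param features Feature table (undefined-flagged rows are dropped with a
#'   message).
#' @param traits Response column names (default c("N", "NSC")).
#' @param specs Named list of \code{model_spec}s (default
#'   \code{default_model_specs()}).
#' @param split_fraction,split_seed Split parameters.
#' @param importance Compute permutation importances (default TRUE).
#' @return data.frame with one row per method x trait: method, trait,
#'   cal_r2, cal_rmse, val_r2, val_rmse, gap, best, params; importance
#'   matrices attached as attribute \code{importance} (named
#'   "<trait>.<method>"), fitted models as attribute \code{models}.
#' @export
compare_methods <- function(features, traits = c("N", "NSC"),
                            specs = default_model_specs(),
                            split_fraction = 0.8, split_seed = 1L,
                            importance = TRUE) {
  if ("flag_undefined" %in% names(features) && any(features$flag_undefined)) {
    message(sprintf("dropping %d row(s) with undefined indices",
                    sum(features$flag_undefined)))
    features <- features[!features$flag_undefined, , drop = FALSE]
  }
  parts <- split_data(features, split_fraction, split_seed)
  if (nrow(parts$validation) == 0)
    stop_cfg("validation set is empty at fraction %.2f", split_fraction)
  rows <- list(); imps <- list(); models <- list()
  for (tr in traits) {
    for (m in names(specs)) {
      fit <- fit_model(parts$calibration, tr, specs[[m]])
      cal <- evaluate(fit, parts$calibration)
      val <- evaluate(fit, parts$validation)
      rows[[paste(tr, m)]] <- data.frame(
        method = m, trait = tr,
        cal_r2 = cal$r2, cal_rmse = cal$rmse,
        val_r2 = val$r2, val_rmse = val$rmse,
        gap = cal$r2 - val$r2,
        params = paste(names(fit$params), unlist(fit$params), sep = "=",
                       collapse = ";"),
        stringsAsFactors = FALSE)
      if (importance) {
        imps[[paste(tr, m, sep = ".")]] <-
          variable_importance(fit, parts$calibration,
                              seed = specs[[m]]$seed)
      }
      models[[paste(tr, m, sep = ".")]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$best <- FALSE
  for (tr in traits) {
    i <- which(out$trait == tr)
    out$best[i[which.max(out$val_r2[i])]] <- TRUE
  }
  attr(out, "importance") <- imps
  attr(out, "models") <- models
  attr(out, "split") <- parts
  out
}
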