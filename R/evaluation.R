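# Error metrics (with the Theil inequality decomposition) and the repeated
# random-split validation protocol.

#' Seven forecast error metrics
#'
#' Computes MSE, MAE, MAPE (as a proportion), the Theil inequality
#' coefficient `RMSE / (sqrt(mean(y^2)) + sqrt(mean(yhat^2)))`, and the
#' bias / variance / covariance proportions decomposing MSE:
#' `BP = (mean(yhat) - mean(y))^2 / MSE`,
#' `VP = (sd(yhat) - sd(y))^2 / MSE` with population (divide-by-n) SDs, and
#' `CP = 1 - BP - VP`.  Population SDs make the decomposition exact:
#' `BP + VP + CP = 1` whenever MSE > 0, and CP equals the direct covariance
#' form `2 (1 - r) sd(y) sd(yhat) / MSE` (cross-checked internally).  With a
#' perfect prediction the first four metrics are 0 and the three proportions
#' are reported as `NA`.
#'
#' @param observed numeric vector of observed values, all > 0 (MAPE and the
#'   Theil denominator require it; zero-outcome records are removed upstream
#'   by [filter_zero_outcomes()]).
#' @param predicted numeric vector of predictions, same length.
#' @return named numeric vector with elements `MSE`, `MAE`, `MAPE`,
#'   `TheilIC`, `BP`, `VP`, `CP`.
#' @export
error_metrics <- function(observed, predicted) {
  assert_that(length(observed) == length(predicted) && length(observed) >= 2,
              "observed and predicted must have equal length >= 2")
  if (any(observed <= 0)) {
    stop_lagcast(paste("observed values must be > 0;",
                       "apply filter_zero_outcomes() upstream"),
                 "lagcast_nonpositive_observed")
  }
  e <- observed - predicted
  n <- length(e)
  mse <- mean(e^2)
  mae <- mean(abs(e))
  mape <- mean(abs(e / observed))
  theil <- sqrt(mse) / (sqrt(mean(observed^2)) + sqrt(mean(predicted^2)))
  if (mse == 0) {
    return(c(MSE = 0, MAE = 0, MAPE = 0, TheilIC = 0,
             BP = NA_real_, VP = NA_real_, CP = NA_real_))
  }
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  so <- sd_pop(observed); sp <- sd_pop(predicted)
  bp <- (mean(predicted) - mean(observed))^2 / mse
  vp <- (sp - so)^2 / mse
  cp <- 1 - bp - vp
  if (so > 0 && sp > 0) {
    r <- mean((observed - mean(observed)) * (predicted - mean(predicted))) /
      (so * sp)
    cp_direct <- 2 * (1 - r) * so * sp / mse
    stopifnot(abs(cp - cp_direct) < 1e-8)
  }
  c(MSE = mse, MAE = mae, MAPE = mape, TheilIC = theil,
    BP = bp, VP = vp, CP = cp)
}

metric_names <- function() c("MSE", "MAE", "MAPE", "TheilIC", "BP", "VP", "CP")

# Fit the roster + combination on a training set and predict a test set.
# Combination weights come from an internal fold split of the training set
# only -- no test leakage.
fit_and_predict_all <- function(X_tr, y_tr, X_te, specs, combo_folds, seed) {
  # resolve CV-selected hyperparameters once per training set
  concrete <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    if (sp$kind == "ridge" && identical(sp$hyper$penalty %||% "cv", "cv")) {
      sp$hyper$penalty <- select_ridge_penalty(X_tr, y_tr,
                                               seed = derive_seed(seed, "cv_ridge"))
    }
    if (sp$kind == "pls" && identical(sp$hyper$n_components %||% "cv", "cv")) {
      sp$hyper$n_components <- select_pls_ncomp(X_tr, y_tr,
                                                seed = derive_seed(seed, "cv_pls"))
    }
    sp
  })
  names(concrete) <- names(specs)

  fits <- lapply(concrete, function(sp) fit_model_spec(sp, X_tr, y_tr, seed))
  preds <- lapply(fits, predict, newdata = X_te)

  folds <- with_seed(derive_seed(seed, "combo_folds"),
                     sample(rep_len(seq_len(combo_folds), nrow(X_tr))))
  fold_err <- matrix(NA_real_, combo_folds, length(specs),
                     dimnames = list(NULL, names(specs)))
  for (f in seq_len(combo_folds)) {
    tr <- folds != f
    for (nm in names(concrete)) {
      m <- fit_model_spec(concrete[[nm]], X_tr[tr, , drop = FALSE], y_tr[tr],
                          seed = seed)
      fold_err[f, nm] <- mean(abs(y_tr[!tr] -
                                    predict(m, X_tr[!tr, , drop = FALSE])))
    }
  }
  cw <- combination_weights(fold_err)
  preds$combination <- drop(vapply(preds, identity,
                                   numeric(nrow(X_te)))[, names(specs), drop = FALSE] %*%
                              cw$weights[names(specs)])
  list(predictions = preds, weights = cw)
}

#' Repeated random-split model evaluation
#'
#' For each loop: draw a uniform random split of the design rows into a
#' training and a testing set, fit every model in `specs` plus the
#' coefficient-of-variation combination (its weights derived from folds
#' within the training set), score the seven error metrics on the test set,
#' and finally report the per-model mean and SD of each metric over loops.
#' Combination weights are re-derived every loop.
#'
#' @param design a [build_lag_design()] result (or any data frame with the
#'   predictor columns and the response).
#' @param specs named list of [model_spec()]s (default
#'   [default_model_specs()]).
#' @param response response column (default `"mortality_rate"`).
#' @param train_fraction fraction of rows used for training (default 0.9).
#' @param loops number of random splits (default 1000; scale down for
#'   exploratory runs).
#' @param seed RNG seed governing every split and fold.
#' @param combo_folds folds used to derive combination weights (default 5).
#' @return object of class `eval_report`: list with `table` (model x metric
#'   mean and SD), `weights` (loops x models combination weights), and the
#'   protocol settings.
#' @export
run_validation <- function(design, specs = default_model_specs(),
                           response = "mortality_rate",
                           train_fraction = 0.9, loops = 1000, seed = 1L,
                           combo_folds = 5) {
  preds_cols <- design_predictors(design)
  X <- as_feature_matrix(as.data.frame(design)[, preds_cols, drop = FALSE])
  y <- design[[response]]
  n <- nrow(X)
  n_train <- floor(n * train_fraction)
  assert_that(n_train >= 2 && n - n_train >= 2,
              "degenerate split: need >= 2 rows in both training and test sets")

  model_names <- c(names(specs), "combination")
  acc <- array(NA_real_, c(loops, length(model_names), 7),
               dimnames = list(NULL, model_names, metric_names()))
  wts <- matrix(NA_real_, loops, length(specs),
                dimnames = list(NULL, names(specs)))

  for (b in seq_len(loops)) {
    loop_seed <- derive_seed(seed, sprintf("loop_%d", b))
    tr_idx <- with_seed(loop_seed, sample(n, n_train))
    te_idx <- setdiff(seq_len(n), tr_idx)
    res <- fit_and_predict_all(X[tr_idx, , drop = FALSE], y[tr_idx],
                               X[te_idx, , drop = FALSE], specs,
                               combo_folds, loop_seed)
    for (nm in model_names) {
      acc[b, nm, ] <- error_metrics(y[te_idx], res$predictions[[nm]])
    }
    wts[b, ] <- res$weights$weights[colnames(wts)]
  }

  tab <- do.call(rbind, lapply(model_names, function(nm) {
    data.frame(model = nm, metric = metric_names(),
               mean = apply(acc[, nm, , drop = FALSE], 3, mean, na.rm = TRUE),
               sd = if (loops == 1) 0 else
                 apply(acc[, nm, , drop = FALSE], 3, stats::sd, na.rm = TRUE),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(table = tab, weights = wts, loops = loops,
                 train_fraction = train_fraction, seed = seed,
                 response = response, metrics = acc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d loops, train fraction %.2f, response %s\n",
              x$loops, x$train_fraction, x$response))
  wide <- format_eval_report(x)
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Reshape an evaluation report to the metric-by-model layout
#'
#' Cells are "mean (SD)" strings, rows metrics, columns models.
#'
#' @param report an [run_validation()] report.
#' @return data frame.
#' @export
format_eval_report <- function(report) {
  tab <- report$table
  models <- unique(tab$model)
  out <- data.frame(metric = metric_names(), stringsAsFactors = FALSE)
  for (m in models) {
    sub <- tab[tab$model == m, ]
    out[[m]] <- sprintf("%.2f (%.2f)",
                        sub$mean[match(out$metric, sub$metric)],
                        sub$sd[match(out$metric, sub$metric)])
  }
  out
}

#' Split-proportion sensitivity analysis
#'
#' Re-runs [run_validation()] for several training fractions and records the
#' model ranking by mean MSE under each.
#'
#' @param design a `lag_design`.
#' @param specs model roster.
#' @param response response column.
#' @param fractions training fractions (default 0.9, 0.85, 0.8, 0.75, 0.7).
#' @param loops loops per fraction.
#' @param seed RNG seed.
#' @param combo_folds combination-weight folds.
#' @return list with `reports` (one `eval_report` per fraction) and
#'   `ranking` (data frame: fraction, model, mean MSE, rank).
#' @export
split_sensitivity <- function(design, specs = default_model_specs(),
                              response = "mortality_rate",
                              fractions = c(0.9, 0.85, 0.8, 0.75, 0.7),
                              loops = 100, seed = 1L, combo_folds = 5) {
  reports <- lapply(fractions, function(fr) {
    run_validation(design, specs, response, train_fraction = fr,
                   loops = loops, seed = seed, combo_folds = combo_folds)
  })
  names(reports) <- sprintf("train_%g", fractions)
  ranking <- do.call(rbind, lapply(seq_along(fractions), function(i) {
    tab <- reports[[i]]$table
    mse <- tab[tab$metric == "MSE", ]
    data.frame(fraction = fractions[i], model = mse$model, mean_mse = mse$mean,
               rank = rank(mse$mean, ties.method = "first"),
               stringsAsFactors = FALSE)
  }))
  list(reports = reports, ranking = ranking)
}
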