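# The five forecasting models, written from scratch: ridge regression,
# PLS1 (NIPALS), CART-style regression tree, model tree with ridge-stabilized
# linear leaves, and the inverse coefficient-of-variation combination.
#
# Naming note: the regional-lag coefficient of the exposure-response design
# is `lambda_reg`; the ridge penalty is always `penalty` / `ridge_penalty`.
# The two are unrelated despite sharing a Greek letter in textbooks.

new_lagcast_model <- function(kind, fit, feature_names, hyper, n_train) {
  structure(list(kind = kind, fit = fit, feature_names = feature_names,
                 hyper = hyper, n_train = n_train),
            class = "lagcast_model")
}

#' @export
print.lagcast_model <- function(x, ...) {
  cat(sprintf("lagcast_model '%s': %d features, n_train = %d\n",
              x$kind, length(x$feature_names), x$n_train))
  invisible(x)
}

as_feature_matrix <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

check_features <- function(object, newdata) {
  X <- as_feature_matrix(newdata)
  assert_that(setequal(colnames(X), object$feature_names),
              sprintf("feature names at predict time must equal the training set (%s)",
                      paste(object$feature_names, collapse = ", ")))
  X[, object$feature_names, drop = FALSE]
}

# --- ridge ------------------------------------------------------------------

#' Ridge regression (closed form)
#'
#' Predictors are standardized internally (mean 0, SD 1) and the response
#' centered; the coefficients solve the penalized normal equations
#' `(X'X + penalty * I) b = X'y` with the intercept unpenalized, and are
#' reported back on the original scale.  `penalty = 0` reproduces ordinary
#' least squares on full-rank designs.
#'
#' @param X design matrix (or data frame) of predictors.
#' @param y numeric response.
#' @param penalty ridge penalty, >= 0 (applied on the standardized scale).
#' @param standardize standardize predictors internally (default `TRUE`).
#' @param intercept fit an unpenalized intercept (default `TRUE`).
#' @param warn_constant warn when constant columns are dropped.
#' @return a `lagcast_model` of kind `"ridge"` with `coefficients` (original
#'   scale) and `intercept` in its fit slot.
#' @export
fit_ridge <- function(X, y, penalty = 1, standardize = TRUE,
                      intercept = TRUE, warn_constant = TRUE) {
  assert_that(penalty >= 0, "ridge penalty must be >= 0")
  X <- as_feature_matrix(X)
  assert_that(nrow(X) >= 2 && nrow(X) == length(y),
              "need n >= 2 rows and matching y")
  assert_that(!anyNA(X) && !anyNA(y), "missing values are not allowed")
  features <- colnames(X)

  keep <- col_sds(X) > 0
  if (!all(keep) && standardize) {
    if (warn_constant) {
      warning(sprintf("dropping constant predictor column(s): %s",
                      paste(features[!keep], collapse = ", ")))
    }
    Xw <- X[, keep, drop = FALSE]
  } else {
    Xw <- X
    keep <- rep(TRUE, ncol(X))
  }

  if (standardize) {
    xm <- colMeans(Xw); xs <- col_sds(Xw)
    Xs <- sweep(sweep(Xw, 2, xm), 2, xs, `/`)
  } else {
    xm <- rep(0, ncol(Xw)); xs <- rep(1, ncol(Xw))
    Xs <- Xw
  }
  ym <- if (intercept) mean(y) else 0
  yc <- y - ym

  p <- ncol(Xs)
  b_std <- if (p > 0) {
    A <- crossprod(Xs) + diag(penalty, p)
    drop(solve(A, crossprod(Xs, yc)))
  } else numeric(0)

  beta <- stats::setNames(rep(0, length(features)), features)
  beta[colnames(Xw)] <- b_std / xs
  alpha <- ym - sum(beta[colnames(Xw)] * xm)

  new_lagcast_model("ridge",
                    list(coefficients = beta, intercept = alpha),
                    features,
                    list(penalty = penalty, standardize = standardize,
                         intercept = intercept),
                    nrow(X))
}

#' Choose a ridge penalty by k-fold cross-validation
#'
#' Grid search over a log-spaced penalty grid, scoring mean squared error.
#'
#' @param X,y training data.
#' @param grid candidate penalties (default `10^(-3:3)`).
#' @param k folds (default 5).
#' @param seed fold-assignment seed.
#' @return the penalty with the lowest CV mean squared error.
#' @export
select_ridge_penalty <- function(X, y, grid = 10^(-3:3), k = 5, seed = 1L) {
  X <- as_feature_matrix(X)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), nrow(X))))
  mse <- vapply(grid, function(lam) {
    err <- 0
    for (f in seq_len(k)) {
      tr <- folds != f
      m <- fit_ridge(X[tr, , drop = FALSE], y[tr], penalty = lam,
                     warn_constant = FALSE)
      err <- err + sum((y[!tr] - predict(m, X[!tr, , drop = FALSE]))^2)
    }
    err / length(y)
  }, numeric(1))
  grid[which.min(mse)]
}

# --- partial least squares --------------------------------------------------

#' Partial least squares regression (PLS1, NIPALS)
#'
#' Sequentially extracts components maximizing covariance with the response
#' on standardized predictors, deflating after each component; the final
#' regression coefficients are reported on the original scale.  Requesting
#' more components than the effective rank truncates with a warning.  With
#' as many components as the rank, predictions match ordinary least squares.
#'
#' @param X design matrix of predictors.
#' @param y numeric response.
#' @param n_components number of latent components, >= 1.
#' @return a `lagcast_model` of kind `"pls"`; its fit slot holds the
#'   coefficient path for 1..k components (used for CV selection).
#' @export
fit_pls <- function(X, y, n_components = 2) {
  assert_that(n_components >= 1, "n_components must be >= 1")
  X <- as_feature_matrix(X)
  assert_that(nrow(X) == length(y) && nrow(X) >= 2, "X and y must align, n >= 2")
  features <- colnames(X)

  keep <- col_sds(X) > 0
  Xw <- X[, keep, drop = FALSE]
  xm <- colMeans(Xw); xs <- col_sds(Xw)
  E <- sweep(sweep(Xw, 2, xm), 2, xs, `/`)
  ym <- mean(y)
  f <- y - ym

  p <- ncol(E)
  kmax <- min(n_components, p, nrow(X) - 1)
  Wm <- matrix(0, p, 0); Pm <- matrix(0, p, 0); qv <- numeric(0)
  tol <- 1e-12 * max(1, sum(f^2))
  k <- 0
  while (k < kmax) {
    cv <- drop(crossprod(E, f))
    nw <- sqrt(sum(cv^2))
    if (nw^2 <= tol) break
    w <- cv / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    if (tt <= 1e-12) break
    pvec <- drop(crossprod(E, t_)) / tt
    q <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, pvec)
    f <- f - q * t_
    Wm <- cbind(Wm, w); Pm <- cbind(Pm, pvec); qv <- c(qv, q)
    k <- k + 1
  }
  if (k < n_components) {
    warning(sprintf("PLS truncated at %d component(s) (requested %d)",
                    k, n_components))
  }

  coef_path <- matrix(0, length(features), max(k, 1),
                      dimnames = list(features, NULL))
  if (k > 0) {
    for (kk in seq_len(k)) {
      Wk <- Wm[, seq_len(kk), drop = FALSE]
      Pk <- Pm[, seq_len(kk), drop = FALSE]
      b_std <- drop(Wk %*% solve(crossprod(Pk, Wk), qv[seq_len(kk)]))
      coef_path[keep, kk] <- b_std / xs
    }
  }
  beta <- coef_path[, max(k, 1)]
  alpha <- ym - sum(beta[keep] * xm)
  intercept_path <- ym - drop(crossprod(coef_path[keep, , drop = FALSE], xm))

  new_lagcast_model("pls",
                    list(coefficients = beta, intercept = alpha,
                         coef_path = coef_path,
                         intercept_path = intercept_path,
                         n_components = k),
                    features,
                    list(n_components_requested = n_components),
                    nrow(X))
}

#' Choose the number of PLS components by k-fold cross-validation
#'
#' @param X,y training data.
#' @param max_ncomp largest candidate (default 10, capped at the rank).
#' @param k folds (default 5).
#' @param seed fold-assignment seed.
#' @return the component count with the lowest CV mean squared error.
#' @export
select_pls_ncomp <- function(X, y, max_ncomp = 10, k = 5, seed = 1L) {
  X <- as_feature_matrix(X)
  max_ncomp <- min(max_ncomp, ncol(X))
  folds <- with_seed(seed, sample(rep_len(seq_len(k), nrow(X))))
  sse <- numeric(max_ncomp)
  for (f in seq_len(k)) {
    tr <- folds != f
    m <- suppressWarnings(fit_pls(X[tr, , drop = FALSE], y[tr], max_ncomp))
    path <- m$fit$coef_path
    kf <- ncol(path)
    pred <- X[!tr, , drop = FALSE] %*% path +
      matrix(m$fit$intercept_path, sum(!tr), kf, byrow = TRUE)
    for (kk in seq_len(max_ncomp)) {
      sse[kk] <- sse[kk] + sum((y[!tr] - pred[, min(kk, kf)])^2)
    }
  }
  which.min(sse)
}

# --- trees ------------------------------------------------------------------

grow_tree <- function(X, y, idx, depth, min_leaf, max_depth, leaf_fit) {
  n <- length(idx)
  make_leaf <- function() {
    if (is.null(leaf_fit)) {
      list(leaf = TRUE, value = mean(y[idx]), n = n)
    } else {
      list(leaf = TRUE, model = leaf_fit(X[idx, , drop = FALSE], y[idx]), n = n)
    }
  }
  if (depth >= max_depth || n < 2 * min_leaf || stats::var(y[idx]) == 0) {
    return(make_leaf())
  }
  sp <- .best_split_idx_cpp(X, y, idx, min_leaf)
  if (sp$feature == 0) return(make_leaf())
  left <- idx[X[idx, sp$feature] <= sp$threshold]
  right <- idx[X[idx, sp$feature] > sp$threshold]
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold, n = n,
       left = grow_tree(X, y, left, depth + 1, min_leaf, max_depth, leaf_fit),
       right = grow_tree(X, y, right, depth + 1, min_leaf, max_depth, leaf_fit))
}

predict_tree <- function(node, X, idx, out) {
  if (node$leaf) {
    out[idx] <- if (!is.null(node$model)) {
      predict(node$model, X[idx, , drop = FALSE])
    } else {
      node$value
    }
    return(out)
  }
  go_left <- X[idx, node$feature] <= node$threshold
  if (any(go_left)) out <- predict_tree(node$left, X, idx[go_left], out)
  if (any(!go_left)) out <- predict_tree(node$right, X, idx[!go_left], out)
  out
}

#' CART-style regression tree
#'
#' Binary recursive partitioning minimizing the total within-node sum of
#' squared errors.  Split candidates are midpoints between consecutive
#' distinct sorted feature values; leaves predict the training mean; growth
#' stops on depth, leaf size, or zero SSE improvement.  Split ties are broken
#' toward the lowest feature index, then the lowest threshold.
#'
#' @param X design matrix of predictors.
#' @param y numeric response.
#' @param min_samples_leaf minimum rows per leaf (default 5).
#' @param max_depth maximum depth, root = 0 (default 10).
#' @return a `lagcast_model` of kind `"regression_tree"`.
#' @export
fit_regression_tree <- function(X, y, min_samples_leaf = 5, max_depth = 10) {
  X <- as_feature_matrix(X)
  assert_that(nrow(X) >= 2 * min_samples_leaf,
              "need n >= 2 * min_samples_leaf rows")
  root <- grow_tree(X, y, seq_len(nrow(X)), 0L, min_samples_leaf,
                    max_depth, leaf_fit = NULL)
  new_lagcast_model("regression_tree", list(root = root), colnames(X),
                    list(min_samples_leaf = min_samples_leaf,
                         max_depth = max_depth),
                    nrow(X))
}

#' Model tree: CART splits with linear-model leaves
#'
#' Uses the same SSE-minimizing split search as [fit_regression_tree()], but
#' each leaf fits a ridge-stabilized linear model (penalty 1e-6) on all
#' features; prediction evaluates the leaf model at the query point.  The
#' minimum leaf size must exceed the feature count so every leaf regression
#' is determined.
#'
#' @param X design matrix of predictors.
#' @param y numeric response.
#' @param min_samples_leaf minimum rows per leaf (default 20); must be
#'   greater than `ncol(X)`.
#' @param max_depth maximum depth (default 5).
#' @return a `lagcast_model` of kind `"model_tree"`.
#' @export
fit_model_tree <- function(X, y, min_samples_leaf = 20, max_depth = 5) {
  X <- as_feature_matrix(X)
  assert_that(min_samples_leaf > ncol(X),
              "min_samples_leaf must exceed the number of features")
  assert_that(nrow(X) >= 2 * min_samples_leaf,
              "need n >= 2 * min_samples_leaf rows")
  leaf_fit <- function(Xl, yl) {
    fit_ridge(Xl, yl, penalty = 1e-6, warn_constant = FALSE)
  }
  root <- grow_tree(X, y, seq_len(nrow(X)), 0L, min_samples_leaf,
                    max_depth, leaf_fit)
  new_lagcast_model("model_tree", list(root = root), colnames(X),
                    list(min_samples_leaf = min_samples_leaf,
                         max_depth = max_depth),
                    nrow(X))
}

# --- prediction -------------------------------------------------------------

#' Predict from a fitted lagcast model
#'
#' @param object a `lagcast_model`.
#' @param newdata matrix or data frame whose feature-name set equals the
#'   training features.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.lagcast_model <- function(object, newdata, ...) {
  X <- check_features(object, newdata)
  switch(object$kind,
    ridge = ,
    pls = drop(X %*% object$fit$coefficients) + object$fit$intercept,
    regression_tree = ,
    model_tree = predict_tree(object$fit$root, X, seq_len(nrow(X)),
                              numeric(nrow(X))),
    stop_lagcast(sprintf("cannot predict for kind '%s'", object$kind))
  )
}

# --- combination ------------------------------------------------------------

#' Inverse coefficient-of-variation combination weights
#'
#' For each component model, the coefficient of variation of its per-fold
#' mean absolute errors is `CV_m = SD(fold errors) / mean(fold errors)`; the
#' combination weight is the normalized inverse,
#' `w_m = (1/CV_m) / sum_k (1/CV_k)`.  A model whose fold errors are
#' perfectly stable (`CV = 0`) takes the whole weight, split equally among
#' all zero-CV models.
#'
#' @param fold_errors numeric matrix of per-fold mean absolute errors, rows
#'   = folds, columns = models (named).
#' @return object of class `combination_weights`: list with `weights`
#'   (sums to 1), `cv`, and `mean_errors`.
#' @export
combination_weights <- function(fold_errors) {
  fold_errors <- as.matrix(fold_errors)
  assert_that(ncol(fold_errors) >= 2, "need at least 2 component models")
  assert_that(nrow(fold_errors) >= 2, "need at least 2 folds")
  if (is.null(colnames(fold_errors))) {
    colnames(fold_errors) <- sprintf("m%d", seq_len(ncol(fold_errors)))
  }
  mean_err <- colMeans(fold_errors)
  assert_that(all(mean_err > 0), "all mean fold errors must be > 0")
  cv <- apply(fold_errors, 2, stats::sd) / mean_err
  if (any(cv == 0)) {
    w <- ifelse(cv == 0, 1 / sum(cv == 0), 0)
  } else {
    inv <- 1 / cv
    w <- inv / sum(inv)
  }
  structure(list(weights = w, cv = cv, mean_errors = mean_err),
            class = "combination_weights")
}

#' Convex combination of component predictions
#'
#' @param components named list of fitted `lagcast_model`s, aligned with the
#'   weights.
#' @param weights a [combination_weights()] object (or a named numeric
#'   vector summing to 1).
#' @param X prediction matrix.
#' @return numeric vector `sum_m w_m * yhat_m`.
#' @export
predict_combination <- function(components, weights, X) {
  w <- if (inherits(weights, "combination_weights")) weights$weights else weights
  assert_that(length(components) == length(w),
              "weights do not align with components")
  if (!is.null(names(components)) && !is.null(names(w))) {
    assert_that(setequal(names(components), names(w)),
                "weights do not align with components (name mismatch)")
    w <- w[names(components)]
  }
  preds <- vapply(components, function(m) predict(m, X),
                  numeric(nrow(as.matrix(X))))
  drop(as.matrix(preds) %*% w)
}

# --- model specs (used by the evaluation protocol) --------------------------

#' Specification of a model family and its hyperparameters
#'
#' Hyperparameters left as `"cv"` are selected by internal k-fold
#' cross-validation on each training set.
#'
#' @param kind one of `"ridge"`, `"pls"`, `"regression_tree"`,
#'   `"model_tree"`.
#' @param ... kind-specific hyperparameters.
#' @return a `model_spec` object.
#' @export
model_spec <- function(kind, ...) {
  kind <- match.arg(kind, c("ridge", "pls", "regression_tree", "model_tree"))
  structure(list(kind = kind, hyper = list(...)), class = "model_spec")
}

#' Default model roster
#'
#' Ridge (CV-selected penalty), PLS (CV-selected components), regression
#' tree and model tree at their documented defaults.  The combination model
#' over these four is added by the evaluation protocol itself.
#'
#' @return named list of [model_spec()]s.
#' @export
default_model_specs <- function() {
  list(
    ridge = model_spec("ridge", penalty = "cv"),
    pls = model_spec("pls", n_components = "cv"),
    regression_tree = model_spec("regression_tree",
                                 min_samples_leaf = 5, max_depth = 10),
    model_tree = model_spec("model_tree",
                            min_samples_leaf = 20, max_depth = 5)
  )
}

# Resolve "cv" hyperparameters on a concrete training set, then fit.
fit_model_spec <- function(spec, X, y, seed = 1L) {
  h <- spec$hyper
  switch(spec$kind,
    ridge = {
      pen <- h$penalty %||% "cv"
      if (identical(pen, "cv")) pen <- select_ridge_penalty(X, y, seed = seed)
      fit_ridge(X, y, penalty = pen, warn_constant = FALSE)
    },
    pls = {
      nc <- h$n_components %||% "cv"
      if (identical(nc, "cv")) nc <- select_pls_ncomp(X, y, seed = seed)
      suppressWarnings(fit_pls(X, y, n_components = nc))
    },
    regression_tree = fit_regression_tree(
      X, y,
      min_samples_leaf = h$min_samples_leaf %||% 5,
      max_depth = h$max_depth %||% 10
    ),
    model_tree = fit_model_tree(
      X, y,
      min_samples_leaf = h$min_samples_leaf %||% 20,
      max_depth = h$max_depth %||% 5
    )
  )
}
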