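# The five forecasting models.

test_that("ridge matches its closed form and limits", {
  # hand-solved: X = (1, 2)', y = (1, 2), no intercept/standardization,
  # penalty 1 -> (X'X + 1)^-1 X'y = 5/6
  m <- fit_ridge(matrix(c(1, 2), 2, 1), c(1, 2), penalty = 1,
                 standardize = FALSE, intercept = FALSE)
  expect_equal(unname(m$fit$coefficients), 5 / 6, tolerance = 1e-12)

  set.seed(2)
  X <- matrix(rnorm(80), 20, 4)
  y <- drop(X %*% c(1, -2, 0.5, 3)) + rnorm(20, 0, 0.3)
  ols <- lm(y ~ X)
  m0 <- fit_ridge(X, y, penalty = 0)
  expect_equal(unname(m0$fit$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-8)
  expect_equal(m0$fit$intercept, unname(coef(ols)[1]), tolerance = 1e-8)

  mbig <- fit_ridge(X, y, penalty = 1e9)
  expect_lt(max(abs(mbig$fit$coefficients)), 1e-4)
  expect_equal(mbig$fit$intercept, mean(y), tolerance = 1e-3)

  expect_error(fit_ridge(X, y, penalty = -1), ">= 0")
  Xc <- cbind(X, const = 7)
  expect_warning(mc <- fit_ridge(Xc, y, penalty = 1), "constant predictor")
  expect_equal(unname(mc$fit$coefficients["const"]), 0)
})

test_that("ridge coefficient norms shrink monotonically in the penalty", {
  set.seed(3)
  X <- matrix(rnorm(200), 40, 5)
  y <- rnorm(40)
  norms <- vapply(10^seq(-3, 3, by = 0.5), function(lam) {
    sqrt(sum(fit_ridge(X, y, penalty = lam)$fit$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("PLS reduces to OLS at full rank and to simple regression at k=1", {
  set.seed(4)
  X <- matrix(rnorm(90), 30, 3)
  y <- drop(X %*% c(2, -1, 0.5)) + rnorm(30, 0, 0.2)
  mp <- fit_pls(X, y, n_components = 3)
  expect_lt(max(abs(predict(mp, X) - fitted(lm(y ~ X)))), 1e-6)

  x1 <- matrix(rnorm(30), 30, 1)
  m1 <- fit_pls(x1, y, 1)
  expect_equal(unname(m1$fit$coefficients), unname(coef(lm(y ~ x1))[2]),
               tolerance = 1e-8)

  # y orthogonal to X by construction: prediction collapses to mean(y)
  Xo <- matrix(c(1, -1, 1, -1, 1, -1), 6, 1)
  yo <- c(1, 1, -1, -1, 0, 0)                  # crossprod = 0
  expect_equal(sum(Xo * yo), 0)
  mo <- suppressWarnings(fit_pls(Xo, yo, 1))
  expect_equal(unname(predict(mo, Xo)), rep(mean(yo), 6), tolerance = 1e-10)

  expect_warning(fit_pls(X, y, n_components = 10), "truncated")
})

test_that("PLS training SSE is non-increasing in components", {
  set.seed(5)
  X <- matrix(rnorm(300), 50, 6)
  y <- rnorm(50)
  sse <- vapply(1:6, function(k) {
    sum((y - predict(fit_pls(X, y, k), X))^2)
  }, numeric(1))
  expect_true(all(diff(sse) <= 1e-8))
})

test_that("regression tree finds the optimal first split", {
  m <- fit_regression_tree(matrix(c(1, 2, 10, 11), 4, 1), c(0, 0, 10, 10),
                           min_samples_leaf = 2)
  expect_false(m$fit$root$leaf)
  expect_equal(m$fit$root$threshold, 6)
  expect_equal(m$fit$root$left$value, 0)
  expect_equal(m$fit$root$right$value, 10)
  expect_equal(predict(m, matrix(c(0, 7), 2, 1)), c(0, 10))

  # constant response: a single leaf
  mc <- fit_regression_tree(matrix(1:10, 10, 1), rep(4, 10),
                            min_samples_leaf = 2)
  expect_true(mc$fit$root$leaf)
  expect_equal(mc$fit$root$value, 4)

  # fully grown tree memorizes distinct-feature training data
  set.seed(6)
  Xm <- matrix(runif(20), 20, 1)
  ym <- rnorm(20)
  mm <- fit_regression_tree(Xm, ym, min_samples_leaf = 1, max_depth = 50)
  expect_equal(predict(mm, Xm), ym, tolerance = 1e-12)
})

test_that("first splits match the exhaustive brute-force oracle", {
  set.seed(7)
  for (i in 1:12) {
    n <- sample(10:30, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- rnorm(n)
    oracle <- brute_force_split(X, y, 3)
    got <- lagcast:::.best_split_cpp(X, y, 3L)
    expect_equal(got$feature, oracle$feature)
    expect_equal(got$threshold, oracle$threshold, tolerance = 1e-12)
    expect_equal(got$sse, oracle$sse, tolerance = 1e-9)
  }
})

test_that("tree training SSE is non-increasing in depth", {
  set.seed(8)
  X <- matrix(rnorm(400), 100, 4)
  y <- drop(X %*% c(1, 2, 0, -1)) + rnorm(100)
  sse <- vapply(0:6, function(d) {
    sum((y - predict(fit_regression_tree(X, y, 5, max_depth = d), X))^2)
  }, numeric(1))
  expect_true(all(diff(sse) <= 1e-9))
})

test_that("model trees recover piecewise-linear structure", {
  # regime change with a level shift: the SSE-on-means split search locates
  # the boundary, and the ridge leaves recover the per-regime slopes.
  # (A continuous V-shape is NOT recovered by a single mean-based split --
  # the split search is shared with the regression tree by contract.)
  x <- seq(-1, 1, length.out = 200)
  x <- x[x != 0]
  y <- ifelse(x < 0, 2 * x, -3 * x + 10)
  m <- fit_model_tree(matrix(x, ncol = 1), y, min_samples_leaf = 20,
                      max_depth = 5)
  expect_lt(max(abs(predict(m, matrix(x, ncol = 1)) - y)), 1e-3)
  slopes <- sort(unique(round(vapply(tree_leaves(m$fit$root), function(l)
    unname(l$model$fit$coefficients), numeric(1)), 3)))
  expect_equal(slopes, c(-3, 2), tolerance = 1e-3)

  # globally linear noiseless data: no split improves, error ~ 0
  yl <- 3 * x + 1
  ml <- fit_model_tree(matrix(x, ncol = 1), yl, 20, 5)
  expect_lt(max(abs(predict(ml, matrix(x, ncol = 1)) - yl)), 1e-6)

  # constant response: one leaf, zero slope, intercept = constant
  mc <- fit_model_tree(matrix(x, ncol = 1), rep(2.5, length(x)), 20, 5)
  expect_true(mc$fit$root$leaf)
  expect_equal(unname(mc$fit$root$model$fit$coefficients), 0)
  expect_equal(mc$fit$root$model$fit$intercept, 2.5)

  expect_error(fit_model_tree(matrix(rnorm(40), 20, 2), rnorm(20),
                              min_samples_leaf = 2), "exceed")
})

test_that("combination weights follow the inverse-CV rule", {
  eq <- matrix(5, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  eq <- eq + rep(c(-1, 1, -1, 1), 3)             # same fold pattern per model
  w <- combination_weights(eq)
  expect_equal(unname(w$weights), rep(1 / 3, 3), tolerance = 1e-12)

  # CVs 0.1 and 0.3 -> weights 0.75 / 0.25
  fe <- cbind(m1 = c(9, 11), m2 = c(7, 13))      # means 10; sds sqrt(2), 3*sqrt(2)
  w2 <- combination_weights(fe)
  expect_equal(unname(w2$cv[1] / w2$cv[2]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(w2$weights), c(0.75, 0.25), tolerance = 1e-12)

  # zero-CV models take the whole weight, split equally
  fz <- cbind(a = c(5, 5), b = c(4, 6), c = c(3, 3))
  wz <- combination_weights(fz)
  expect_equal(unname(wz$weights), c(0.5, 0, 0.5))

  set.seed(9)
  for (i in 1:10) {
    fr <- matrix(runif(12, 1, 10), 4, 3)
    expect_equal(sum(combination_weights(fr)$weights), 1, tolerance = 1e-12)
  }
  expect_error(combination_weights(matrix(1, 4, 1)), "2 component")
  expect_error(combination_weights(matrix(1, 1, 3)), "2 folds")
  expect_error(combination_weights(cbind(c(0, 0), c(1, 1))), "> 0")
})

test_that("combination predictions are the stated convex mix", {
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3)
  y <- drop(X %*% c(1, 1, 1)) + rnorm(20)
  m1 <- fit_ridge(X, y, 1)
  m2 <- fit_regression_tree(X, y, 5)
  single <- predict_combination(list(a = m1), c(a = 1), X)
  expect_equal(single, predict(m1, X))

  w <- structure(list(weights = c(a = 0.5, b = 0.5)),
                 class = "combination_weights")
  mix <- predict_combination(list(a = m1, b = m2), w, X)
  expect_equal(mix, (predict(m1, X) + predict(m2, X)) / 2)
  expect_error(predict_combination(list(a = m1), c(a = .5, b = .5), X),
               "align")

  # convexity: combined MSE never exceeds the worst component MSE
  for (i in 1:100) {
    yt <- rnorm(15)
    p1 <- yt + rnorm(15); p2 <- yt + rnorm(15, 0, 2)
    lam <- runif(1)
    mse_mix <- mean((yt - (lam * p1 + (1 - lam) * p2))^2)
    expect_lte(mse_mix,
               max(mean((yt - p1)^2), mean((yt - p2)^2)) + 1e-12)
  }
})

test_that("models serialize to JSON and back with identical predictions", {
  set.seed(11)
  X <- matrix(rnorm(200), 50, 4)
  colnames(X) <- sprintf("v%d", 1:4)
  y <- drop(X %*% c(1, 0, -1, 2)) + rnorm(50, 0, 0.5)
  for (fit in list(fit_ridge(X, y, 0.5),
                   fit_pls(X, y, 2),
                   fit_regression_tree(X, y, 5),
                   fit_model_tree(X, y, 10, 3))) {
    tmp <- withr::local_tempfile(fileext = ".json")
    model_to_json(fit, tmp)
    back <- model_from_json(tmp)
    expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-10)
    expect_equal(back$kind, fit$kind)
  }
})

test_that("predict enforces the training feature set", {
  X <- matrix(rnorm(40), 20, 2)
  colnames(X) <- c("p", "q")
  m <- fit_ridge(X, rnorm(20), 1)
  Xbad <- X
  colnames(Xbad) <- c("p", "zz")
  expect_error(predict(m, Xbad), "feature names")
  # column order may differ as long as the set matches
  expect_equal(predict(m, X[, c("q", "p")]), predict(m, X))
})
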