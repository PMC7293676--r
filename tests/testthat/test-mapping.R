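# Variogram estimation/fitting and ordinary Kriging.

test_that("the Matheron estimator matches hand evaluation", {
  # two points, values 0 and 2, one bin: gamma = (0-2)^2 / (2*1) = 2
  emp <- suppressMessages(
    empirical_variogram(rbind(c(0, 0), c(1, 0)), c(0, 2), n_lags = 1,
                        max_dist = 1.5))
  expect_equal(emp$gamma, 2)
  expect_equal(emp$n_pairs, 1L)

  set.seed(15)
  pts <- cbind(runif(15), runif(15))
  empc <- empirical_variogram(pts, rep(3.3, 15))
  expect_true(all(empc$gamma == 0))

  # pair accounting when max_dist covers all pairs
  empall <- empirical_variogram(pts, rnorm(15), n_lags = 6, max_dist = 10)
  expect_equal(sum(empall$n_pairs), 15 * 14 / 2)

  expect_error(empirical_variogram(matrix(1, 12, 2), rnorm(12)),
               "coincident")
})

test_that("variogram fitting recovers exact spherical parameters", {
  truth <- list(model = "spherical", nugget = 1, sill = 8, range = 3)
  h <- seq(0.3, 6, by = 0.3)
  emp <- data.frame(dist = h, gamma = variogram_value(h, truth),
                    n_pairs = 50)
  fit <- fit_variogram(emp)
  expect_equal(fit$nugget, 1, tolerance = 0.05)
  expect_equal(fit$sill, 8, tolerance = 0.05 * 8)
  expect_equal(fit$range, 3, tolerance = 0.05 * 3)

  # pure nugget: structured variance ~ 0 relative to the nugget
  flat <- data.frame(dist = h, gamma = 5, n_pairs = 50)
  ffit <- fit_variogram(flat)
  expect_lt(ffit$sill / 5, 0.05)

  # scale equivariance: doubling semivariances doubles nugget+sill,
  # leaves range unchanged
  emp2 <- emp; emp2$gamma <- 2 * emp2$gamma
  fit2 <- fit_variogram(emp2)
  expect_equal(fit2$nugget, 2 * fit$nugget, tolerance = 0.02 * 2)
  expect_equal(fit2$sill, 2 * fit$sill, tolerance = 0.02 * 16)
  expect_equal(fit2$range, fit$range, tolerance = 0.02 * 3)
})

test_that("a generated field round-trips through the variogram fit", {
  # generator-estimator round trip: median fitted range over 5 seeded
  # 100x100 fields within 25% of the generating range (single-realization
  # fits scatter by ~+-30% at this domain/range ratio)
  cc <- expand.grid(y = seq(0.05, 9.95, 0.1), x = seq(0.05, 9.95, 0.1))
  idx <- seq(1, nrow(cc), by = 3)
  ranges <- vapply(1:5, function(s) {
    f <- lagcast:::grf_fields(100, 100, 0.1, sill = 80, range = 0.5,
                              n_fields = 1, seed = s)[[1]]
    emp <- empirical_variogram(cbind(cc$x[idx], cc$y[idx]),
                               as.vector(f)[idx], n_lags = 20, max_dist = 2)
    fit_variogram(emp, "exponential")$range
  }, numeric(1))
  expect_lt(abs(median(ranges) - 0.5) / 0.5, 0.25)
})

test_that("ordinary kriging honors its defining properties", {
  set.seed(16)
  pts <- cbind(runif(25, 0, 10), runif(25, 0, 10))
  vals <- rnorm(25, 20, 4)
  vg <- structure(list(model = "spherical", nugget = 0, sill = 10,
                       range = 4), class = "variogram_model")

  # constant field kriges to the constant everywhere
  kc <- ordinary_kriging(pts, rep(8, 25), vg,
                         list(origin = c(lon = 0, lat = 0), cell_size = 1,
                              n_rows = 6, n_cols = 6))
  expect_equal(range(kc$prediction), c(8, 8), tolerance = 1e-8)

  # zero nugget: exact interpolation at data locations
  for (i in c(1, 7, 19)) {
    kw <- kriging_weights(pts, vg, pts[i, ])
    expect_equal(sum(kw$weights * vals[kw$idx]), vals[i], tolerance = 1e-6)
  }

  # unbiasedness constraint: weights sum to 1 anywhere
  for (i in 1:10) {
    target <- runif(2, 0, 10)
    kw <- kriging_weights(pts, vg, target, k_neighbors = 12)
    expect_equal(sum(kw$weights), 1, tolerance = 1e-10)
  }

  # surface predictions and nonnegative variance
  ks <- ordinary_kriging(pts, vals, vg,
                         list(origin = c(lon = 0, lat = 0), cell_size = 0.5,
                              n_rows = 20, n_cols = 20), k_neighbors = 12)
  expect_true(all(is.finite(ks$prediction)))
  expect_true(all(ks$variance >= 0))
  expect_gte(min(ks$prediction), min(vals) - 1e-6)  # no wild extrapolation
  expect_lte(max(ks$prediction), max(vals) + 1e-6)
})

test_that("kriging beats nearest-neighbor interpolation on smooth fields", {
  wins <- vapply(1:6, function(s) {
    f <- lagcast:::grf_fields(40, 40, 0.25, sill = 25, range = 2,
                              n_fields = 1, seed = 300 + s)[[1]]
    cc <- expand.grid(r = 1:40, c = 1:40)
    xy <- cbind((cc$c - 0.5) * 0.25, (cc$r - 0.5) * 0.25)
    z <- f[cbind(cc$r, cc$c)]
    set.seed(s)
    tr <- sample(nrow(xy), 80)
    te <- sample(setdiff(seq_len(nrow(xy)), tr), 100)
    emp <- empirical_variogram(xy[tr, ], z[tr], n_lags = 12)
    vg <- fit_variogram(emp, "exponential")
    pred <- vapply(te, function(i) {
      kw <- kriging_weights(xy[tr, ], vg, xy[i, ], k_neighbors = 15)
      sum(kw$weights * z[tr][kw$idx])
    }, numeric(1))
    nn <- vapply(te, function(i) {
      d <- (xy[tr, 1] - xy[i, 1])^2 + (xy[tr, 2] - xy[i, 2])^2
      z[tr][which.min(d)]
    }, numeric(1))
    sqrt(mean((pred - z[te])^2)) < sqrt(mean((nn - z[te])^2))
  }, logical(1))
  expect_gte(sum(wins), 5)
})

test_that("kriged surfaces serialize to ASCII + CSV", {
  set.seed(17)
  pts <- cbind(runif(12, 0, 4), runif(12, 0, 4))
  vg <- structure(list(model = "exponential", nugget = 0.5, sill = 4,
                       range = 1.5), class = "variogram_model")
  ks <- ordinary_kriging(pts, rnorm(12, 30, 2), vg,
                         list(origin = c(lon = 0, lat = 0), cell_size = 1,
                              n_rows = 4, n_cols = 4))
  asc <- withr::local_tempfile(fileext = ".asc")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_kriged_surface(ks, asc, csv)
  back <- read_esri_ascii(asc)
  expect_equal(back$values, ks$prediction, tolerance = 1e-6)
  df <- read.csv(csv)
  expect_named(df, c("lon", "lat", "predicted", "variance"))
  expect_equal(nrow(df), 16)
})
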