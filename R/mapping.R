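# Variogram estimation/fitting and ordinary Kriging of area-level forecasts
# onto a regular grid.

#' Empirical semivariogram (Matheron estimator)
#'
#' `gamma(h) = (1 / 2|N(h)|) * sum_{(i,j) in N(h)} (z_i - z_j)^2` over
#' equal-width distance bins up to `max_dist`; empty bins are omitted.
#'
#' @param coords two-column matrix of point coordinates (lon, lat, planar
#'   degrees).
#' @param values numeric vector of point values.
#' @param n_lags number of distance bins (default 12).
#' @param max_dist largest pair distance considered; default half the
#'   bounding-box diagonal.
#' @return data frame with `dist` (mean pair distance in the bin), `gamma`,
#'   `n_pairs`.
#' @export
empirical_variogram <- function(coords, values, n_lags = 12, max_dist = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  assert_that(n >= 2, "need at least 2 points for a variogram")
  if (n < 10) {
    message("empirical_variogram: fewer than 10 points; estimates are crude")
  }
  assert_that(length(values) == n, "values must align with coords")
  d <- stats::dist(coords)
  assert_that(max(d) > 0, "all points are coincident")
  if (is.null(max_dist)) {
    bb <- apply(coords, 2, range)
    max_dist <- sqrt(sum((bb[2, ] - bb[1, ])^2)) / 2
  }
  dv <- as.vector(d)
  gv <- as.vector(stats::dist(values))^2 / 2
  keep <- dv <= max_dist & dv > 0
  dv <- dv[keep]; gv <- gv[keep]
  assert_that(length(dv) > 0, "no pairs within max_dist")
  bin <- pmin(ceiling(dv / (max_dist / n_lags)), n_lags)
  agg_g <- tapply(gv, bin, mean)
  agg_d <- tapply(dv, bin, mean)
  agg_n <- tapply(gv, bin, length)
  out <- data.frame(dist = as.vector(agg_d), gamma = as.vector(agg_g),
                    n_pairs = as.vector(agg_n))
  out[order(out$dist), , drop = FALSE]
}

#' Theoretical semivariance
#'
#' Spherical: `nugget + sill * (1.5 h/r - 0.5 (h/r)^3)` for `h < r`, flat at
#' `nugget + sill` beyond; exponential: `nugget + sill * (1 - exp(-h/r))`.
#' `sill` is the partial sill (structured variance above the nugget).
#'
#' @param h distances (>= 0).
#' @param model a `variogram_model` (or list with `model`, `nugget`, `sill`,
#'   `range`).
#' @return semivariances; `gamma(0) = 0` by convention.
#' @export
variogram_value <- function(h, model) {
  g <- if (model$model == "spherical") {
    hr <- pmin(h / model$range, 1)
    model$nugget + model$sill * (1.5 * hr - 0.5 * hr^3)
  } else {
    model$nugget + model$sill * (1 - exp(-h / model$range))
  }
  g[h == 0] <- 0
  g
}

#' Fit a variogram model by weighted least squares
#'
#' Minimizes `sum n_pairs * (gamma_emp - gamma_model)^2` over (nugget, sill,
#' range) with nonnegativity bounds, using a deterministic multi-start over a
#' fixed grid of initial values.  If the spherical fit fails, an exponential
#' fit is attempted with a warning.
#'
#' @param empirical an [empirical_variogram()] data frame.
#' @param model `"spherical"` (default) or `"exponential"`.
#' @return object of class `variogram_model`: list with `model`, `nugget`,
#'   `sill` (partial sill), `range`, `empirical`.
#' @export
fit_variogram <- function(empirical, model = c("spherical", "exponential")) {
  model <- match.arg(model)
  assert_that(nrow(empirical) >= 3, "need at least 3 empirical points")
  h <- empirical$dist; g <- empirical$gamma; w <- empirical$n_pairs

  obj <- function(par, mod) {
    m <- list(model = mod, nugget = par[1], sill = par[2], range = par[3])
    # the vanishing-range limit of any model is pure nugget; the tiny sill
    # penalty breaks that tie toward the nugget interpretation
    sum(w * (g - variogram_value(h, m))^2) + 1e-8 * sum(w) * par[2]^2
  }
  fit_one <- function(mod) {
    g_max <- max(g); h_max <- max(h)
    starts <- expand.grid(
      nugget = c(0, 0.25 * g_max),
      sill = c(0.5, 1) * max(g_max, 1e-12),
      range = c(0.25, 0.5, 1) * h_max
    )
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::optim(as.numeric(starts[i, ]), obj, mod = mod,
                     method = "L-BFGS-B",
                     lower = c(0, 1e-12, 1e-6 * h_max),
                     # ranges beyond the sampled distances are unidentifiable
                     upper = c(Inf, Inf, 3 * h_max)),
        error = function(e) NULL
      )
      if (!is.null(res) && (is.null(best) || res$value < best$value)) {
        best <- res
      }
    }
    best
  }
  best <- fit_one(model)
  if (is.null(best) && model == "spherical") {
    warning("spherical variogram fit failed; falling back to exponential")
    model <- "exponential"
    best <- fit_one(model)
  }
  assert_that(!is.null(best), "variogram fit failed for all starts")
  structure(list(model = model, nugget = best$par[1], sill = best$par[2],
                 range = best$par[3], empirical = empirical),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model (%s): nugget %.4g, partial sill %.4g, range %.4g\n",
              x$model, x$nugget, x$sill, x$range))
  invisible(x)
}

# Solve the ordinary-Kriging system for one target location given its
# neighborhood.  Returns list(weights, mu) or NULL if singular twice.
ok_solve <- function(G, g0) {
  k <- nrow(G)
  A <- rbind(cbind(G, 1), c(rep(1, k), 0))
  b <- c(g0, 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) {
    A2 <- A
    diag(A2)[seq_len(k)] <- diag(A2)[seq_len(k)] + 1e-10
    sol <- tryCatch(solve(A2, b), error = function(e) NULL)
  }
  if (is.null(sol)) return(NULL)
  list(weights = sol[seq_len(k)], mu = sol[k + 1])
}

#' Ordinary-Kriging weights at one target point
#'
#' Exposes the Lagrange-constrained solution for inspection: the weights sum
#' to 1 (the unbiasedness constraint) and, with a zero nugget, kriging at a
#' data location reproduces its value.
#'
#' @param coords data point coordinates (two-column matrix).
#' @param variogram a fitted [fit_variogram()] model.
#' @param target numeric `c(lon, lat)` target location.
#' @param k_neighbors number of nearest data points used (default 25).
#' @return list with `weights`, `mu` (Lagrange multiplier), `idx` (indices
#'   of the data points used).
#' @export
kriging_weights <- function(coords, variogram, target, k_neighbors = 25) {
  coords <- as.matrix(coords)
  d2 <- (coords[, 1] - target[1])^2 + (coords[, 2] - target[2])^2
  idx <- order(d2)[seq_len(min(k_neighbors, nrow(coords)))]
  sub <- coords[idx, , drop = FALSE]
  G <- variogram_value(as.matrix(stats::dist(sub)), variogram)
  g0 <- variogram_value(sqrt(d2[idx]), variogram)
  sol <- ok_solve(G, g0)
  assert_that(!is.null(sol), "singular Kriging system")
  list(weights = sol$weights, mu = sol$mu, idx = idx)
}

#' Ordinary Kriging onto a regular grid
#'
#' Per target cell, solves the ordinary-Kriging system (semivariance matrix
#' with a Lagrange multiplier enforcing weights summing to 1) over the
#' `k_neighbors` nearest data points, returning the prediction and Kriging
#' variance surfaces.  Singular systems are retried once with a 1e-10
#' diagonal jitter, then marked NODATA (a count is reported).
#'
#' @param coords data point coordinates (two-column matrix, lon/lat).
#' @param values data point values.
#' @param variogram a fitted [fit_variogram()] model.
#' @param target_grid an [exposure_grid()] used as the target geometry (its
#'   values are ignored), or a list with `origin`, `cell_size`, `n_rows`,
#'   `n_cols`.
#' @param k_neighbors neighborhood size (default 25).
#' @return object of class `kriged_surface`: list with `prediction` and
#'   `variance` (`exposure_grid`-oriented matrices), `origin`, `cell_size`,
#'   `n_failed`.
#' @export
ordinary_kriging <- function(coords, values, variogram, target_grid,
                             k_neighbors = 25) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  assert_that(n >= 3, "need at least 3 data points")
  assert_that(length(values) == n, "values must align with coords")
  if (inherits(target_grid, "exposure_grid")) {
    tg <- list(origin = target_grid$origin, cell_size = target_grid$cell_size,
               n_rows = nrow(target_grid$values),
               n_cols = ncol(target_grid$values))
  } else {
    tg <- target_grid
  }
  cs <- tg$cell_size
  lon <- tg$origin[["lon"]] + (seq_len(tg$n_cols) - 0.5) * cs
  lat <- tg$origin[["lat"]] + (tg$n_rows - seq_len(tg$n_rows) + 0.5) * cs

  pred <- matrix(NA_real_, tg$n_rows, tg$n_cols)
  krvar <- matrix(NA_real_, tg$n_rows, tg$n_cols)
  n_failed <- 0L
  k_use <- min(k_neighbors, n)

  # neighborhoods repeat across nearby cells; cache factorization per set
  cache <- new.env(parent = emptyenv())
  for (r in seq_len(tg$n_rows)) {
    for (cc in seq_len(tg$n_cols)) {
      d2 <- (coords[, 1] - lon[cc])^2 + (coords[, 2] - lat[r])^2
      idx <- sort(order(d2)[seq_len(k_use)])
      key <- paste(idx, collapse = ",")
      Ainv <- cache[[key]]
      if (is.null(Ainv)) {
        sub <- coords[idx, , drop = FALSE]
        G <- variogram_value(as.matrix(stats::dist(sub)), variogram)
        A <- rbind(cbind(G, 1), c(rep(1, k_use), 0))
        Ainv <- tryCatch(solve(A), error = function(e) {
          diag(A)[seq_len(k_use)] <- diag(A)[seq_len(k_use)] + 1e-10
          tryCatch(solve(A), error = function(e2) NULL)
        })
        cache[[key]] <- if (is.null(Ainv)) FALSE else Ainv
      }
      if (isFALSE(Ainv)) {
        n_failed <- n_failed + 1L
        next
      }
      g0 <- variogram_value(sqrt(d2[idx]), variogram)
      sol <- drop(Ainv %*% c(g0, 1))
      w <- sol[seq_len(k_use)]
      pred[r, cc] <- sum(w * values[idx])
      krvar[r, cc] <- max(sum(w * g0) + sol[k_use + 1], 0)
    }
  }
  if (n_failed > 0) {
    message(sprintf("ordinary_kriging: %d cell(s) NODATA (singular system)",
                    n_failed))
  }
  structure(list(prediction = pred, variance = krvar,
                 origin = c(lon = unname(tg$origin[["lon"]]),
                            lat = unname(tg$origin[["lat"]])),
                 cell_size = cs, n_failed = n_failed,
                 variogram = variogram),
            class = "kriged_surface")
}

#' @export
print.kriged_surface <- function(x, ...) {
  cat(sprintf("kriged_surface: %dx%d cells @ %g deg, %d NODATA\n",
              nrow(x$prediction), ncol(x$prediction), x$cell_size, x$n_failed))
  invisible(x)
}
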