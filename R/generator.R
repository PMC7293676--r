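# Synthetic registry-panel generator: lattice geography, Gaussian random
# field exposure surfaces with AR(1) persistence, and outcome panels with the
# distributed-lag linear structure the downstream analysis assumes.

#' Registry entry counts per year, 2006--2014
#'
#' Number of areal units reporting outcomes in each year of the default
#' outcome window.  The counts grow from 34 to 339 and sum to 1294
#' area-year records, matching the size and unbalanced structure of the
#' national cancer-registry panel the generator emulates.
#'
#' @return named integer vector, names are years.
#' @export
default_registry_schedule <- function() {
  stats::setNames(
    c(34L, 38L, 41L, 72L, 145L, 177L, 193L, 255L, 339L),
    as.character(2006:2014)
  )
}

#' Configuration for the synthetic data generator
#'
#' Bundles every tunable of the stated synthetic world: lattice size, year
#' ranges, distributed-lag coefficients, exposure-field covariance, and the
#' unbalanced registry entry schedule.
#'
#' @param n_rows,n_cols lattice dimensions (areas are 1 degree square cells).
#' @param years_exposure inclusive year range of exposure surfaces.
#' @param years_outcome inclusive year range of outcome records.
#' @param beta_loc numeric length-9 vector of local-lag coefficients
#'   (rate per 100,000 per microgram/m3), lags 0..8.
#' @param lambda_reg numeric length-9 vector of regional-lag coefficients.
#' @param alpha intercept of the mortality-rate model, per 100,000.
#' @param alpha_morbidity intercept of the morbidity-rate model.
#' @param sigma_eps SD of the Gaussian noise on the rate scale.
#' @param field_mean spatial mean of the exposure surface, micrograms/m3.
#' @param field_range range parameter of the exponential covariance
#'   C(h) = sill * exp(-h/range), in degrees.
#' @param field_sill sill (marginal variance) of the random field component.
#' @param field_gradient west-to-east linear trend, micrograms/m3 per degree
#'   of longitude (positive = dirtier east).
#' @param ar1 year-to-year AR(1) persistence of the field component.
#' @param cells_per_area exposure grid cells per area side (grid resolution
#'   = 1/cells_per_area degrees).
#' @param registry_schedule named vector year -> number of reporting areas;
#'   `NULL` uses [default_registry_schedule()], proportionally rescaled when
#'   the lattice has fewer areas than the schedule maximum.
#' @param poisson_counts logical; if `TRUE`, rates are realized through
#'   Poisson death/case counts given the population instead of Gaussian
#'   noise on the rate scale (off by default).
#' @param origin_lon,origin_lat lower-left corner of the lattice, decimal
#'   degrees.
#' @param seed integer master seed; every random substream derives from it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_rows = 19L, n_cols = 19L,
                             years_exposure = c(1998L, 2016L),
                             years_outcome = c(2006L, 2014L),
                             beta_loc = default_beta_loc(),
                             lambda_reg = default_lambda_reg(),
                             alpha = 8, alpha_morbidity = 12,
                             sigma_eps = 12,
                             field_mean = 40, field_range = 0.5,
                             field_sill = 80, field_gradient = 0.5,
                             ar1 = 0.8, cells_per_area = 10L,
                             registry_schedule = NULL,
                             poisson_counts = FALSE,
                             origin_lon = 100, origin_lat = 25,
                             seed = 1L) {
  assert_that(n_rows >= 1 && n_cols >= 1 && n_rows * n_cols >= 4,
              "lattice must have at least 4 areas (2x2)")
  assert_that(length(beta_loc) == 9, "beta_loc must have length 9")
  assert_that(length(lambda_reg) == 9, "lambda_reg must have length 9")
  assert_that(sigma_eps >= 0, "sigma_eps must be >= 0")
  assert_that(field_range > 0, "field_range must be > 0")
  assert_that(field_sill >= 0, "field_sill must be >= 0")
  assert_that(ar1 >= 0 && ar1 < 1, "ar1 must be in [0, 1)")
  years_exposure <- as.integer(years_exposure)
  years_outcome <- as.integer(years_outcome)
  assert_that(years_exposure[1] <= years_outcome[1] - 8,
              "exposure years must start at least 8 years before outcomes")
  assert_that(years_exposure[2] >= years_outcome[2],
              "exposure years must cover the outcome years")

  n_areas <- n_rows * n_cols
  out_years <- seq(years_outcome[1], years_outcome[2])
  if (is.null(registry_schedule)) {
    sched <- default_registry_schedule()
    if (length(out_years) != length(sched)) {
      # non-default outcome window: interpolate the default growth curve
      sched <- stats::setNames(
        as.integer(round(stats::approx(seq_along(sched), unname(sched),
                                       xout = seq(1, length(sched),
                                                  length.out = length(out_years)))$y)),
        as.character(out_years)
      )
    } else {
      names(sched) <- as.character(out_years)
    }
    if (max(sched) > n_areas) {
      sched <- pmax(1L, as.integer(round(sched * n_areas / max(sched))))
      sched <- stats::setNames(cummax(sched), as.character(out_years))
    }
    registry_schedule <- sched
  }
  registry_schedule <- stats::setNames(as.integer(registry_schedule),
                                       names(registry_schedule))
  assert_that(!is.unsorted(registry_schedule),
              "registry_schedule must be nondecreasing over years")
  assert_that(max(registry_schedule) <= n_areas,
              "registry_schedule counts cannot exceed the number of areas")
  assert_that(identical(names(registry_schedule), as.character(out_years)),
              "registry_schedule names must be the outcome years")

  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    years_exposure = years_exposure, years_outcome = years_outcome,
    beta_loc = as.numeric(beta_loc), lambda_reg = as.numeric(lambda_reg),
    alpha = alpha, alpha_morbidity = alpha_morbidity,
    sigma_eps = sigma_eps,
    field_mean = field_mean, field_range = field_range,
    field_sill = field_sill, field_gradient = field_gradient,
    ar1 = ar1, cells_per_area = as.integer(cells_per_area),
    registry_schedule = registry_schedule,
    poisson_counts = isTRUE(poisson_counts),
    origin_lon = origin_lon, origin_lat = origin_lat,
    cell_deg = 1,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default local-lag coefficients
#'
#' Calibrated (once) so that pooled outcome/lag Pearson correlations land in
#' the 0.15-0.35 band typical of county-level PM2.5 / lung-cancer panels,
#' with slightly stronger distal lags.  Units: rate per 100,000 per
#' microgram/m3.
#' @return numeric length-9 vector (lags 0..8).
#' @export
default_beta_loc <- function() {
  c(0.060, 0.060, 0.063, 0.068, 0.072, 0.075, 0.078, 0.075, 0.075)
}

#' Default regional-lag coefficients
#'
#' Element-wise smaller than [default_beta_loc()]: neighboring-area exposure
#' matters, but less than the area's own.
#' @return numeric length-9 vector (lags 0..8).
#' @export
default_lambda_reg <- function() {
  c(0.027, 0.027, 0.029, 0.030, 0.033, 0.035, 0.036, 0.035, 0.035)
}

area_id_for <- function(row, col) sprintf("r%03dc%03d", row, col)

#' Generate a lattice study region
#'
#' Builds a rectangular lattice of square 1-degree areas with queen
#' adjacency (areas sharing an edge or a corner are neighbors), per-area
#' polygons, centroids and populations.  A lattice exercises contiguity,
#' aggregation and Kriging identically to real county polygons while keeping
#' fixtures tiny.
#'
#' @param config a [generator_config()].
#' @return an object of class `study_region`: list with `areas` (list of
#'   area units), `adjacency` (named list of neighbor id character vectors),
#'   and `lattice` metadata.
#' @export
generate_region <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  nr <- config$n_rows; nc <- config$n_cols
  assert_that(nr >= 2 && nc >= 2,
              "lattice must be at least 2x2: queen adjacency is degenerate otherwise")
  cd <- config$cell_deg
  yrs <- seq(config$years_outcome[1], config$years_outcome[2])

  pops <- with_seed(derive_seed(config$seed, "population"), {
    base <- stats::rlnorm(nr * nc, meanlog = log(5e5), sdlog = 0.5)
    round(outer(base, 1.01^(seq_along(yrs) - 1)))
  })

  areas <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      k <- k + 1L
      x0 <- config$origin_lon + (cc - 1) * cd
      y0 <- config$origin_lat + (r - 1) * cd
      poly <- cbind(
        lon = c(x0, x0 + cd, x0 + cd, x0, x0),
        lat = c(y0, y0, y0 + cd, y0 + cd, y0)
      )
      areas[[k]] <- list(
        area_id = area_id_for(r, cc),
        polygon = poly,
        centroid = c(lon = x0 + cd / 2, lat = y0 + cd / 2),
        population_by_year = stats::setNames(pops[k, ], as.character(yrs)),
        row = r, col = cc
      )
    }
  }
  ids <- vapply(areas, `[[`, "", "area_id")
  adjacency <- stats::setNames(vector("list", length(ids)), ids)
  k <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      k <- k + 1L
      nb <- character(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc2 <- cc + dc
        if (rr >= 1 && rr <= nr && cc2 >= 1 && cc2 <= nc) {
          nb <- c(nb, area_id_for(rr, cc2))
        }
      }
      adjacency[[k]] <- sort(nb)
    }
  }
  structure(list(
    areas = stats::setNames(areas, ids),
    adjacency = adjacency,
    lattice = list(n_rows = nr, n_cols = nc, cell_deg = cd,
                   origin_lon = config$origin_lon,
                   origin_lat = config$origin_lat)
  ), class = "study_region")
}

#' @export
print.study_region <- function(x, ...) {
  cat(sprintf("study_region: %d areas (%dx%d lattice), queen adjacency\n",
              length(x$areas), x$lattice$n_rows, x$lattice$n_cols))
  invisible(x)
}

#' Area ids of a study region, in region order
#' @param region a `study_region`.
#' @return character vector.
#' @export
region_ids <- function(region) names(region$areas)

#' Area centroids of a study region
#' @param region a `study_region`.
#' @return matrix with columns `lon`, `lat`; rownames are area ids.
#' @export
region_centroids <- function(region) {
  t(vapply(region$areas, `[[`, c(lon = 0, lat = 0), "centroid"))
}

# --- Gaussian random field via 2-D circulant embedding ----------------------
# Simulates stationary zero-mean fields on a regular grid with exponential
# covariance C(h) = sill * exp(-h/range), exactly (up to clamping of the
# few slightly negative embedding eigenvalues) and in O(N log N).
grf_fields <- function(n_row, n_col, cellsize, sill, range, n_fields, seed) {
  if (sill <= 0 || n_fields == 0) {
    return(replicate(n_fields, matrix(0, n_row, n_col), simplify = FALSE))
  }
  m1 <- 2L * n_row; m2 <- 2L * n_col
  d1 <- pmin(0:(m1 - 1), m1 - (0:(m1 - 1))) * cellsize
  d2 <- pmin(0:(m2 - 1), m2 - (0:(m2 - 1))) * cellsize
  dd <- sqrt(outer(d1^2, d2^2, `+`))
  cv <- sill * exp(-dd / range)
  lam <- Re(stats::fft(cv))
  lam[lam < 0] <- 0  # tiny negative eigenvalues from the embedding
  scale <- sqrt(lam / (m1 * m2))
  out <- vector("list", n_fields)
  with_seed(seed, {
    i <- 1L
    while (i <= n_fields) {
      eps <- matrix(stats::rnorm(m1 * m2), m1, m2) +
        1i * matrix(stats::rnorm(m1 * m2), m1, m2)
      z <- stats::fft(scale * eps)
      out[[i]] <- Re(z)[seq_len(n_row), seq_len(n_col), drop = FALSE]
      i <- i + 1L
      if (i <= n_fields) {
        out[[i]] <- Im(z)[seq_len(n_row), seq_len(n_col), drop = FALSE]
        i <- i + 1L
      }
    }
  })
  out
}

#' Generate yearly exposure surfaces
#'
#' Each year's surface is a deterministic west-to-east linear gradient plus a
#' zero-mean Gaussian random field with exponential covariance
#' `C(h) = sill * exp(-h/range)`; consecutive years share the field through
#' AR(1) persistence (default 0.8) so that lagged predictors are realistically
#' collinear.  Surfaces are truncated below at 0.5 micrograms/m3.
#'
#' @param region a [generate_region()] result.
#' @param config the matching [generator_config()].
#' @return named list (by year) of `exposure_grid` objects.
#' @export
generate_exposure_fields <- function(region, config) {
  stopifnot(inherits(region, "study_region"),
            inherits(config, "generator_config"))
  assert_that(config$field_range > 0, "field_range must be > 0")
  lat <- region$lattice
  cpa <- config$cells_per_area
  n_row <- lat$n_rows * cpa
  n_col <- lat$n_cols * cpa
  cellsize <- lat$cell_deg / cpa
  years <- seq(config$years_exposure[1], config$years_exposure[2])

  # west-to-east gradient on cell-center longitudes, centred on the domain
  lon_centers <- lat$origin_lon + (seq_len(n_col) - 0.5) * cellsize
  grad_row <- config$field_gradient * (lon_centers - mean(lon_centers))
  base <- matrix(grad_row, n_row, n_col, byrow = TRUE) + config$field_mean

  innov <- grf_fields(n_row, n_col, cellsize, config$field_sill,
                      config$field_range, length(years),
                      derive_seed(config$seed, "exposure_field"))
  rho <- config$ar1
  grids <- vector("list", length(years))
  field <- NULL
  for (t in seq_along(years)) {
    field <- if (t == 1) innov[[1]] else rho * field + sqrt(1 - rho^2) * innov[[t]]
    vals <- pmax(base + field, 0.5)
    grids[[t]] <- exposure_grid(
      year = years[t], cell_size = cellsize,
      origin = c(lon = lat$origin_lon, lat = lat$origin_lat),
      values = vals[n_row:1, , drop = FALSE]  # row 1 = northernmost
    )
  }
  stats::setNames(grids, as.character(years))
}

#' Generate an unbalanced outcome panel
#'
#' Rates follow the distributed-lag linear model
#' `rate(t, i) = alpha + sum_k beta_loc[k] * loc_lag_k + sum_k
#' lambda_reg[k] * reg_lag_k + eps`, with `eps ~ N(0, sigma_eps^2)` drawn
#' independently for mortality and morbidity, floored at 0.01 per 100,000.
#' Areas enter the registry in a random order according to the schedule and
#' never exit, giving the unbalanced monotone coverage pattern of a growing
#' registry network.
#'
#' @param region a [generate_region()] result.
#' @param exposure_panel data frame with columns `area_id`, `year`,
#'   `mean_pm25` covering every outcome year minus up to 8 lag years
#'   (see [build_exposure_panel()]).
#' @param config the matching [generator_config()].
#' @return data frame (class `outcome_panel`) with columns `area_id`,
#'   `year`, `mortality_rate`, `morbidity_rate`, `population`.
#' @export
generate_outcomes <- function(region, exposure_panel, config) {
  stopifnot(inherits(region, "study_region"),
            inherits(config, "generator_config"))
  ids <- region_ids(region)
  out_years <- seq(config$years_outcome[1], config$years_outcome[2])
  need_years <- seq(min(out_years) - 8L, max(out_years))
  have <- unique(exposure_panel$year)
  missing_years <- setdiff(need_years, have)
  assert_that(length(missing_years) == 0,
              sprintf("exposure panel lacks lag history for year(s): %s",
                      paste(missing_years, collapse = ", ")),
              "lagcast_missing_lag_years")

  # local exposure lookup [area, year]
  loc <- matrix(NA_real_, length(ids), length(need_years),
                dimnames = list(ids, as.character(need_years)))
  idx <- cbind(match(exposure_panel$area_id, ids),
               match(exposure_panel$year, need_years))
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  loc[idx[keep, , drop = FALSE]] <- exposure_panel$mean_pm25[keep]
  assert_that(!anyNA(loc), "exposure panel does not cover every area-year")

  # regional mean (queen neighbors) per year, Eq-style unweighted mean
  reg <- vapply(seq_along(need_years), function(j) {
    regional_mean(stats::setNames(loc[, j], ids), region)
  }, numeric(length(ids)))
  dimnames(reg) <- dimnames(loc)

  # registry entry order: random without replacement among uncovered areas
  sched <- config$registry_schedule
  entry <- with_seed(derive_seed(config$seed, "registry_entry"), {
    sample(ids, max(sched))
  })
  covered <- lapply(sched, function(k) sort(entry[seq_len(k)]))

  rows <- do.call(rbind, lapply(seq_along(out_years), function(t) {
    data.frame(area_id = covered[[t]], year = out_years[t],
               stringsAsFactors = FALSE)
  }))

  lag_mat <- function(mat, yrs, lags = 0:8) {
    vapply(lags, function(k) {
      mat[cbind(match(rows$area_id, ids),
                match(rows$year - k, as.integer(colnames(mat))))]
    }, numeric(nrow(rows)))
  }
  L <- lag_mat(loc)
  Rg <- lag_mat(reg)
  mu <- drop(L %*% config$beta_loc + Rg %*% config$lambda_reg)

  pop <- vapply(seq_len(nrow(rows)), function(i) {
    region$areas[[rows$area_id[i]]]$population_by_year[[as.character(rows$year[i])]]
  }, numeric(1))

  panel <- with_seed(derive_seed(config$seed, "outcome_noise"), {
    if (config$poisson_counts) {
      lam_mort <- pmax(config$alpha + mu, 0.01) / 1e5 * pop
      lam_morb <- pmax(config$alpha_morbidity + mu, 0.01) / 1e5 * pop
      mort <- stats::rpois(length(lam_mort), lam_mort) / pop * 1e5
      morb <- stats::rpois(length(lam_morb), lam_morb) / pop * 1e5
    } else {
      mort <- config$alpha + mu + stats::rnorm(length(mu), 0, config$sigma_eps)
      morb <- config$alpha_morbidity + mu +
        stats::rnorm(length(mu), 0, config$sigma_eps)
    }
    data.frame(
      area_id = rows$area_id, year = rows$year,
      mortality_rate = pmax(mort, 0.01),
      morbidity_rate = pmax(morb, 0.01),
      population = pop, stringsAsFactors = FALSE
    )
  })
  class(panel) <- c("outcome_panel", "data.frame")
  panel
}

#' Run the full generator
#'
#' Convenience wrapper: region, exposure surfaces, area-level exposure panel
#' and outcome panel from one config.
#'
#' @param config a [generator_config()].
#' @return list with `region`, `grids`, `exposure`, `outcomes`.
#' @export
generate_all <- function(config) {
  region <- generate_region(config)
  grids <- generate_exposure_fields(region, config)
  exposure <- build_exposure_panel(grids, region)
  outcomes <- generate_outcomes(region, exposure, config)
  list(region = region, grids = grids, exposure = exposure,
       outcomes = outcomes)
}
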