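# Exposure handling: gridded surfaces, grid-to-area aggregation, registry
# filtering/merging rules and WHO guideline classification.

#' Construct an exposure grid
#'
#' A single year's gridded concentration surface.  `values` is oriented like
#' an ESRI ASCII raster: row 1 is the northernmost row, `origin` is the
#' lower-left corner of the grid.
#'
#' @param year integer year.
#' @param cell_size cell edge in decimal degrees.
#' @param origin numeric `c(lon, lat)` of the lower-left corner.
#' @param values numeric matrix of concentrations (micrograms/m3);
#'   `NA` marks NODATA.
#' @return an object of class `exposure_grid`.
#' @export
exposure_grid <- function(year, cell_size, origin, values) {
  assert_that(cell_size > 0, "cell_size must be > 0")
  values <- as.matrix(values)
  assert_that(all(values[!is.na(values)] >= 0),
              "concentrations must be nonnegative")
  structure(list(year = as.integer(year), cell_size = cell_size,
                 origin = c(lon = unname(origin[1]), lat = unname(origin[2])),
                 values = values),
            class = "exposure_grid")
}

#' @export
print.exposure_grid <- function(x, ...) {
  cat(sprintf("exposure_grid %d: %dx%d cells @ %g deg, origin (%g, %g)\n",
              x$year, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin["lon"], x$origin["lat"]))
  invisible(x)
}

# cell-center coordinates of every grid cell, row-major over the matrix
grid_cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  lon <- grid$origin["lon"] + (seq_len(nc) - 0.5) * cs
  lat <- grid$origin["lat"] + (nr - seq_len(nr) + 0.5) * cs  # row 1 = north
  list(lon = lon, lat = lat)
}

# Ray-casting point-in-polygon with explicit boundary detection.
# Returns integer: 0 outside, 1 inside, 2 on boundary (within eps).
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- length(px)
  res <- integer(n)
  vx <- poly[, 1]; vy <- poly[, 2]
  m <- length(vx)
  if (vx[1] != vx[m] || vy[1] != vy[m]) {
    vx <- c(vx, vx[1]); vy <- c(vy, vy[1]); m <- m + 1
  }
  inside <- logical(n); boundary <- logical(n)
  for (e in seq_len(m - 1)) {
    x1 <- vx[e]; y1 <- vy[e]; x2 <- vx[e + 1]; y2 <- vy[e + 1]
    # boundary: distance from point to segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
      boundary <- boundary | d2 <= eps^2
    } else {
      boundary <- boundary | ((px - x1)^2 + (py - y1)^2 <= eps^2)
    }
    # crossing test (half-open in y to avoid double counting at vertices)
    cross <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, cross & !is.na(cross))
  }
  res[inside] <- 1L
  res[boundary] <- 2L
  res
}

#' Aggregate a gridded surface to one area
#'
#' Unweighted arithmetic mean of all non-NODATA cell-center values falling
#' inside the area polygon.  A cell center exactly on a polygon boundary is
#' assigned to the area with the lexicographically smallest `area_id` among
#' all areas of `region` whose closed polygon contains it; when `region` is
#' omitted, boundary centers count toward the queried area.  This convention
#' is declared for cross-platform determinism.
#'
#' @param grid an [exposure_grid()].
#' @param area one element of `study_region$areas`.
#' @param region optional `study_region` used to resolve boundary ties.
#' @return list with `mean_pm25` and `n_cells`.
#' @export
aggregate_grid_to_area <- function(grid, area, region = NULL) {
  stopifnot(inherits(grid, "exposure_grid"))
  cc <- grid_cell_centers(grid)
  poly <- area$polygon
  # bbox prefilter (grow by eps to keep boundary candidates)
  eps <- 1e-9
  ci <- which(cc$lon >= min(poly[, 1]) - eps & cc$lon <= max(poly[, 1]) + eps)
  ri <- which(cc$lat >= min(poly[, 2]) - eps & cc$lat <= max(poly[, 2]) + eps)
  if (length(ci) == 0 || length(ri) == 0) {
    stop_lagcast(sprintf("empty intersection: no grid cells inside area '%s'",
                         area$area_id), "lagcast_empty_intersection")
  }
  px <- rep(cc$lon[ci], each = length(ri))
  py <- rep(cc$lat[ri], times = length(ci))
  loc <- point_in_polygon(px, py, poly)
  take <- loc == 1L
  bnd <- which(loc == 2L)
  if (length(bnd) > 0) {
    if (is.null(region)) {
      take[bnd] <- TRUE
    } else {
      for (b in bnd) {
        owner <- area$area_id
        for (other in region$areas) {
          if (other$area_id >= owner) next
          if (point_in_polygon(px[b], py[b], other$polygon) > 0L) {
            owner <- other$area_id
          }
        }
        if (owner == area$area_id) take[b] <- TRUE
      }
    }
  }
  vals <- grid$values[cbind(rep(ri, times = length(ci)),
                            rep(ci, each = length(ri)))][take]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop_lagcast(sprintf("empty intersection: no grid cells inside area '%s'",
                         area$area_id), "lagcast_empty_intersection")
  }
  list(mean_pm25 = mean(vals), n_cells = length(vals))
}

#' Build an area-level exposure panel from yearly grids
#'
#' Aggregates every grid to every area.  For generator lattices whose grid
#' resolution exactly subdivides the area cells, a fast index-based path is
#' used (it is tested to agree with the polygon path); otherwise each area is
#' aggregated via [aggregate_grid_to_area()].
#'
#' @param grids named list (by year) of [exposure_grid()] objects.
#' @param region a `study_region`.
#' @return data frame with columns `area_id`, `year`, `mean_pm25`, `n_cells`.
#' @export
build_exposure_panel <- function(grids, region) {
  use_fast <- FALSE
  lat <- region$lattice
  if (!is.null(lat)) {
    g <- grids[[1]]
    cpa <- lat$cell_deg / g$cell_size
    aligned <- abs(cpa - round(cpa)) < 1e-9 &&
      abs(g$origin["lon"] - lat$origin_lon) < 1e-9 &&
      abs(g$origin["lat"] - lat$origin_lat) < 1e-9 &&
      nrow(g$values) == lat$n_rows * round(cpa) &&
      ncol(g$values) == lat$n_cols * round(cpa)
    use_fast <- isTRUE(aligned)
  }
  ids <- region_ids(region)
  if (use_fast) {
    cpa <- as.integer(round(lat$cell_deg / grids[[1]]$cell_size))
    nr <- lat$n_rows * cpa; nc <- lat$n_cols * cpa
    # matrix row 1 is the northernmost grid row -> lattice row n_rows
    arow <- lat$n_rows - (ceiling(seq_len(nr) / cpa) - 1L)
    acol <- ceiling(seq_len(nc) / cpa)
    fac <- factor(area_id_for(rep(arow, times = nc), rep(acol, each = nr)),
                  levels = ids)
    out <- lapply(grids, function(g) {
      v <- as.vector(g$values)
      ok <- !is.na(v)
      mean_v <- rowsum(v[ok], fac[ok]) / as.vector(table(fac[ok]))
      data.frame(area_id = ids, year = g$year,
                 mean_pm25 = as.vector(mean_v)[match(ids, rownames(mean_v))],
                 n_cells = as.vector(table(fac[ok]))[match(ids, levels(fac))],
                 stringsAsFactors = FALSE)
    })
  } else {
    out <- lapply(grids, function(g) {
      agg <- lapply(region$areas, function(a)
        aggregate_grid_to_area(g, a, region))
      data.frame(area_id = ids, year = g$year,
                 mean_pm25 = vapply(agg, `[[`, 0, "mean_pm25"),
                 n_cells = vapply(agg, `[[`, 0L, "n_cells"),
                 stringsAsFactors = FALSE)
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' WHO guideline exceedance classification
#'
#' Returns the set of WHO annual-mean PM2.5 thresholds strictly exceeded by
#' a concentration: the air quality guideline AQG (10 micrograms/m3) and the
#' interim targets IT-3 (15), IT-2 (25) and IT-1 (35).
#'
#' @param conc nonnegative concentration in micrograms/m3 (scalar).
#' @return character vector, subset of `c("AQG", "IT-3", "IT-2", "IT-1")`,
#'   ordered from lowest to highest threshold.
#' @export
classify_who <- function(conc) {
  assert_that(length(conc) == 1 && is.finite(conc), "conc must be a finite scalar")
  assert_that(conc >= 0, "concentration must be nonnegative")
  thr <- c("AQG" = 10, "IT-3" = 15, "IT-2" = 25, "IT-1" = 35)
  names(thr)[conc > thr]
}

#' Pool small areas into one rate
#'
#' Merges several areas' event counts and populations into a single crude
#' rate per 100,000 using the total combined population -- the pooled rate,
#' not the mean of rates.
#'
#' @param counts event counts (deaths or cases) per area.
#' @param populations person counts per area, all > 0.
#' @return pooled rate per 100,000.
#' @export
merge_areas <- function(counts, populations) {
  assert_that(length(counts) >= 1, "merge_areas needs at least one record")
  assert_that(length(counts) == length(populations),
              "counts and populations must align")
  assert_that(all(populations > 0), "populations must be > 0")
  assert_that(all(counts >= 0), "counts must be nonnegative")
  1e5 * sum(counts) / sum(populations)
}

#' Pool small areas given rates instead of counts
#'
#' Convenience wrapper around [merge_areas()]: reconstructs counts from crude
#' rates (`count = rate * population / 1e5`) then pools.
#'
#' @param rates crude rates per 100,000.
#' @param populations person counts, all > 0.
#' @return pooled rate per 100,000.
#' @export
merge_area_rates <- function(rates, populations) {
  merge_areas(rates * populations / 1e5, populations)
}

#' Drop records with a zero outcome
#'
#' Removes every panel record whose mortality rate or morbidity rate is 0;
#' a record is retained only if both are positive.  The count of dropped
#' records is reported via `message()`.
#'
#' @param panel outcome panel data frame (`area_id`, `year`,
#'   `mortality_rate`, `morbidity_rate`, `population`).
#' @return the filtered panel (possibly empty).
#' @export
filter_zero_outcomes <- function(panel) {
  keep <- panel$mortality_rate > 0 & panel$morbidity_rate > 0
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("filter_zero_outcomes: dropped %d record(s) with a zero rate",
                    dropped))
  }
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
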