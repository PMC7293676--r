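# Plain-text serialization: ESRI ASCII grids, GeoJSON areas, CSV panels,
# sparse-triplet weights, and fitted-model JSON.

#' Write an exposure grid as an ESRI ASCII raster
#'
#' @param grid an [exposure_grid()].
#' @param path output file path (`.asc`).
#' @param nodata NODATA sentinel written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[["lon"]]),
    sprintf("yllcorner %.10g", grid$origin[["lat"]]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII raster as an exposure grid
#'
#' @param path `.asc` file path.
#' @param year year to stamp on the grid (default 0; the format itself
#'   carries no year).
#' @return an [exposure_grid()].
#' @export
read_esri_ascii <- function(path, year = 0L) {
  lines <- readLines(path, n = 6)
  hdr <- lapply(strsplit(lines, "\\s+"), function(x) x)
  key <- tolower(vapply(hdr, `[[`, "", 1))
  val <- as.numeric(vapply(hdr, `[[`, "", 2))
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == val[["nodata_value"]]] <- NA
  exposure_grid(year = year, cell_size = val[["cellsize"]],
                origin = c(lon = val[["xllcorner"]], lat = val[["yllcorner"]]),
                values = v)
}

#' Write exposure grids in long CSV form
#'
#' Columns `lon`, `lat`, `year`, `pm25` -- cell centers only, NODATA cells
#' omitted.
#'
#' @param grids named list of [exposure_grid()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_exposure_long <- function(grids, path) {
  rows <- lapply(grids, function(g) {
    cc <- grid_cell_centers(g)
    df <- data.frame(
      lon = rep(cc$lon, each = nrow(g$values)),
      lat = rep(cc$lat, times = ncol(g$values)),
      year = g$year,
      pm25 = as.vector(g$values)
    )
    df[!is.na(df$pm25), , drop = FALSE]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a study region as a GeoJSON FeatureCollection
#'
#' One polygon Feature per area with properties `area_id` and
#' `population_<year>`.
#'
#' @param region a `study_region`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_areas_geojson <- function(region, path) {
  features <- lapply(region$areas, function(a) {
    props <- c(list(area_id = a$area_id),
               stats::setNames(as.list(unname(a$population_by_year)),
                               paste0("population_",
                                      names(a$population_by_year))))
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(a$polygon)), function(i)
          c(a$polygon[i, 1], a$polygon[i, 2])))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection of areas
#'
#' Rebuilds a `study_region`; adjacency is recomputed as queen contiguity
#' (any shared polygon vertex, after rounding to 1e-9 degrees).
#'
#' @param path GeoJSON file written by [write_areas_geojson()].
#' @return a `study_region` (without lattice metadata).
#' @export
read_areas_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  areas <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(poly) <- c("lon", "lat")
    props <- f$properties
    pop_keys <- grep("^population_", names(props), value = TRUE)
    pops <- stats::setNames(as.numeric(unlist(props[pop_keys])),
                            sub("^population_", "", pop_keys))
    m <- nrow(poly)
    verts <- if (all(poly[1, ] == poly[m, ])) poly[-m, , drop = FALSE] else poly
    list(area_id = props$area_id, polygon = poly,
         centroid = c(lon = mean(verts[, 1]), lat = mean(verts[, 2])),
         population_by_year = pops)
  })
  ids <- vapply(areas, `[[`, "", "area_id")
  names(areas) <- ids
  vert_key <- lapply(areas, function(a)
    unique(paste(round(a$polygon[, 1], 9), round(a$polygon[, 2], 9))))
  adjacency <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    nb <- character(0)
    for (j in seq_along(ids)) {
      if (i == j) next
      if (any(vert_key[[i]] %in% vert_key[[j]])) nb <- c(nb, ids[j])
    }
    adjacency[[i]] <- sort(nb)
  }
  structure(list(areas = areas, adjacency = adjacency, lattice = NULL),
            class = "study_region")
}

#' Write / read an outcome panel CSV
#'
#' Columns: `area_id`, `year`, `mortality_rate`, `morbidity_rate`,
#' `population`.
#'
#' @param panel outcome panel data frame.
#' @param path CSV path.
#' @return `path` (write) / the panel (read).
#' @export
write_outcome_panel <- function(panel, path) {
  utils::write.csv(panel[, c("area_id", "year", "mortality_rate",
                             "morbidity_rate", "population")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcome_panel
#' @export
read_outcome_panel <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(p) <- c("outcome_panel", "data.frame")
  p
}

#' Write / read an exposure panel CSV
#'
#' Columns: `area_id`, `year`, `mean_pm25`, `n_cells`.
#'
#' @param panel exposure panel data frame.
#' @param path CSV path.
#' @return `path` (write) / the panel (read).
#' @export
write_exposure_panel <- function(panel, path) {
  utils::write.csv(panel[, c("area_id", "year", "mean_pm25", "n_cells")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exposure_panel
#' @export
read_exposure_panel <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write spatial weights as a sparse triplet CSV
#'
#' Columns `i_id`, `j_id`, `w`; zero weights omitted.
#'
#' @param weights a `spatial_weights` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(weights, path) {
  nz <- which(weights$W != 0, arr.ind = TRUE)
  df <- data.frame(i_id = weights$ids[nz[, 1]], j_id = weights$ids[nz[, 2]],
                   w = weights$W[nz])
  df <- df[order(df$i_id, df$j_id), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Kind, hyperparameters, and either coefficients or the recursive node
#' list; [model_from_json()] restores a predict-capable object.
#'
#' @param model a `lagcast_model`.
#' @param path optional path; when given, JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
model_to_json <- function(model, path = NULL) {
  strip <- function(node) {
    if (isTRUE(node$leaf)) {
      if (!is.null(node$model)) {
        list(leaf = TRUE, n = node$n,
             coefficients = as.list(node$model$fit$coefficients),
             intercept = node$model$fit$intercept)
      } else {
        list(leaf = TRUE, n = node$n, value = node$value)
      }
    } else {
      list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
           n = node$n, left = strip(node$left), right = strip(node$right))
    }
  }
  obj <- list(kind = model$kind, feature_names = model$feature_names,
              hyper = model$hyper, n_train = model$n_train)
  if (model$kind %in% c("ridge", "pls")) {
    obj$coefficients <- as.list(model$fit$coefficients)
    obj$intercept <- model$fit$intercept
  } else {
    obj$root <- strip(model$fit$root)
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname model_to_json
#' @param json JSON string or file path.
#' @export
model_from_json <- function(json) {
  obj <- if (file.exists(json)) jsonlite::read_json(json) else
    jsonlite::fromJSON(json, simplifyVector = FALSE)
  features <- unlist(obj$feature_names)
  rebuild <- function(node) {
    if (isTRUE(node$leaf)) {
      if (!is.null(node$coefficients)) {
        coefs <- stats::setNames(as.numeric(unlist(node$coefficients)),
                                 names(node$coefficients))
        lm_leaf <- new_lagcast_model("ridge",
                                     list(coefficients = coefs,
                                          intercept = node$intercept),
                                     features, list(), node$n)
        list(leaf = TRUE, n = node$n, model = lm_leaf)
      } else {
        list(leaf = TRUE, n = node$n, value = node$value)
      }
    } else {
      list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
           n = node$n, left = rebuild(node$left), right = rebuild(node$right))
    }
  }
  fit <- if (obj$kind %in% c("ridge", "pls")) {
    list(coefficients = stats::setNames(as.numeric(unlist(obj$coefficients)),
                                        names(obj$coefficients)),
         intercept = obj$intercept)
  } else {
    list(root = rebuild(obj$root))
  }
  new_lagcast_model(obj$kind, fit, features, obj$hyper, obj$n_train)
}

#' Write a kriged surface as ESRI ASCII plus a point CSV
#'
#' @param surface a [ordinary_kriging()] result.
#' @param asc_path raster output path (prediction layer).
#' @param csv_path CSV output path with `lon`, `lat`, `predicted`,
#'   `variance`.
#' @return invisibly, the two paths.
#' @export
write_kriged_surface <- function(surface, asc_path, csv_path) {
  g <- exposure_grid(0L, surface$cell_size, surface$origin,
                     pmax(surface$prediction, 0))
  g$values <- surface$prediction  # allow negative kriged rates verbatim
  write_esri_ascii(g, asc_path)
  cc <- grid_cell_centers(g)
  df <- data.frame(
    lon = rep(cc$lon, each = nrow(surface$prediction)),
    lat = rep(cc$lat, times = ncol(surface$prediction)),
    predicted = as.vector(surface$prediction),
    variance = as.vector(surface$variance)
  )
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(c(asc_path, csv_path))
}
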