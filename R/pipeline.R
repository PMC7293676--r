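# End-to-end pipeline: simulate -> aggregate -> design -> correlate ->
# moran -> evaluate -> forecast -> map.  Stages communicate through files
# only, so the dependency graph is explicit and acyclic and each stage can
# be run alone from the command line.

PIPELINE_STAGES <- c("simulate", "aggregate", "design", "correlate",
                     "moran", "evaluate", "forecast", "map")

#' Pipeline configuration
#'
#' A flat key-value configuration for [run_pipeline()].  Defaults give a
#' reduced-size simulate-mode run (10x10 lattice, 50 validation loops) that
#' completes in minutes; raise `n_rows`/`n_cols` to 19 and `loops` to 1000
#' for a full-scale panel mirroring a 339-registry network.
#'
#' @param n_rows,n_cols lattice size of the simulated region.
#' @param seed master seed; every random substream derives from it.
#' @param cells_per_area exposure grid cells per area side.
#' @param sigma_eps outcome noise SD (rate per 100,000).
#' @param max_lag deepest exposure lag (default 8).
#' @param train_fraction training share of the random splits.
#' @param loops validation loops.
#' @param combo_folds folds for combination weights.
#' @param n_forecast_years years forecast past the last outcome year
#'   (default 2).
#' @param kriging_cell_size cell size of forecast maps, degrees.
#' @param kriging_neighbors Kriging neighborhood size.
#' @param moran_assumption inference assumption for Moran's I.
#' @param responses outcome columns evaluated and forecast.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_rows = 10L, n_cols = 10L, seed = 1L,
                            cells_per_area = 5L, sigma_eps = 12,
                            max_lag = 8L, train_fraction = 0.9,
                            loops = 50L, combo_folds = 5L,
                            n_forecast_years = 2L,
                            kriging_cell_size = 0.5,
                            kriging_neighbors = 25L,
                            moran_assumption = "randomization",
                            responses = c("mortality_rate", "morbidity_rate")) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              seed = as.integer(seed),
              cells_per_area = as.integer(cells_per_area),
              sigma_eps = sigma_eps, max_lag = as.integer(max_lag),
              train_fraction = train_fraction, loops = as.integer(loops),
              combo_folds = as.integer(combo_folds),
              n_forecast_years = as.integer(n_forecast_years),
              kriging_cell_size = kriging_cell_size,
              kriging_neighbors = as.integer(kriging_neighbors),
              moran_assumption = moran_assumption,
              responses = responses)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline config as key=value text
#'
#' @param cfg a [pipeline_config()].
#' @param path text file path.
#' @return `path` (write) / the config (read).
#' @export
write_pipeline_config <- function(cfg, path) {
  keys <- setdiff(names(cfg), "responses")
  lines <- c(vapply(keys, function(k) sprintf("%s=%s", k, format(cfg[[k]])),
                    ""),
             sprintf("responses=%s", paste(cfg$responses, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) x[2]),
                          vapply(kv, `[[`, "", 1))
  defaults <- pipeline_config()
  for (k in names(vals)) {
    if (k == "responses") {
      defaults[[k]] <- strsplit(vals[[k]], ",")[[1]]
    } else if (k == "moran_assumption") {
      defaults[[k]] <- vals[[k]]
    } else {
      defaults[[k]] <- as.numeric(vals[[k]])
      if (defaults[[k]] == round(defaults[[k]])) {
        defaults[[k]] <- as.integer(defaults[[k]])
      }
    }
  }
  defaults
}

gen_config_from <- function(cfg) {
  generator_config(n_rows = cfg$n_rows, n_cols = cfg$n_cols,
                   sigma_eps = cfg$sigma_eps,
                   cells_per_area = cfg$cells_per_area,
                   seed = derive_seed(cfg$seed, "generator"))
}

log_stage <- function(dir, msg) {
  message(sprintf("[lagcast] %s", msg))
  cat(sprintf("%s\n", msg), file = file.path(dir, "run.log"), append = TRUE)
}

stage_simulate <- function(cfg, dir) {
  gc_ <- gen_config_from(cfg)
  region <- generate_region(gc_)
  grids <- generate_exposure_fields(region, gc_)
  exposure <- build_exposure_panel(grids, region)
  outcomes <- generate_outcomes(region, exposure, gc_)
  write_areas_geojson(region, file.path(dir, "areas.geojson"))
  grid_dir <- file.path(dir, "grids")
  dir.create(grid_dir, showWarnings = FALSE)
  for (g in grids) {
    write_esri_ascii(g, file.path(grid_dir, sprintf("pm25_%d.asc", g$year)))
  }
  write_outcome_panel(outcomes, file.path(dir, "outcomes.csv"))
  list(years_exposure = gc_$years_exposure, years_outcome = gc_$years_outcome)
}

load_region <- function(cfg, dir) {
  # regenerate the lattice from the seed: byte-identical to the GeoJSON and
  # keeps the fast aggregation path; the GeoJSON remains the interchange copy
  generate_region(gen_config_from(cfg))
}

stage_aggregate <- function(cfg, dir) {
  region <- load_region(cfg, dir)
  files <- sort(list.files(file.path(dir, "grids"), "\\.asc$",
                           full.names = TRUE))
  years <- as.integer(sub(".*_(\\d+)\\.asc$", "\\1", files))
  grids <- stats::setNames(
    lapply(seq_along(files), function(i) read_esri_ascii(files[i], years[i])),
    as.character(years))
  panel <- build_exposure_panel(grids, region)
  write_exposure_panel(panel, file.path(dir, "exposure_panel.csv"))
  list(n_records = nrow(panel))
}

stage_design <- function(cfg, dir) {
  region <- load_region(cfg, dir)
  exposure <- read_exposure_panel(file.path(dir, "exposure_panel.csv"))
  outcomes <- read_outcome_panel(file.path(dir, "outcomes.csv"))
  outcomes <- filter_zero_outcomes(outcomes)
  regional <- regional_panel(exposure, region)
  design <- build_lag_design(exposure, regional, outcomes,
                             max_lag = cfg$max_lag)
  utils::write.csv(design, file.path(dir, "lag_design.csv"),
                   row.names = FALSE)
  list(n_rows = nrow(design))
}

read_design <- function(cfg, dir) {
  design <- utils::read.csv(file.path(dir, "lag_design.csv"),
                            stringsAsFactors = FALSE)
  attr(design, "max_lag") <- cfg$max_lag
  class(design) <- c("lag_design", "data.frame")
  design
}

stage_correlate <- function(cfg, dir) {
  design <- read_design(cfg, dir)
  tab <- pearson_table(design)
  utils::write.csv(tab, file.path(dir, "correlations.csv"), row.names = FALSE)
  list(r_range = range(tab$r, na.rm = TRUE))
}

stage_moran <- function(cfg, dir) {
  region <- load_region(cfg, dir)
  exposure <- read_exposure_panel(file.path(dir, "exposure_panel.csv"))
  outcomes <- read_outcome_panel(file.path(dir, "outcomes.csv"))
  cents <- region_centroids(region)
  rows <- list()
  add_row <- function(variable, year, x, ids) {
    if (length(x) < 4 || stats::sd(x) == 0) return()
    w <- inverse_distance_weights(cents[ids, , drop = FALSE], ids = ids)
    mr <- morans_i(stats::setNames(x, ids), w,
                   assumption = cfg$moran_assumption,
                   seed = derive_seed(cfg$seed, paste0("moran_", variable, year)))
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, year = year, I = mr$I, expected = mr$expected,
      variance = mr$variance, z = mr$z, p = mr$p_value,
      assumption = mr$assumption, stringsAsFactors = FALSE)
  }
  for (y in sort(unique(outcomes$year))) {
    sub <- outcomes[outcomes$year == y, ]
    add_row("mortality", y, sub$mortality_rate, sub$area_id)
    add_row("morbidity", y, sub$morbidity_rate, sub$area_id)
    esub <- exposure[exposure$year == y, ]
    add_row("pm25", y, esub$mean_pm25, esub$area_id)
  }
  res <- do.call(rbind, rows)
  utils::write.csv(res, file.path(dir, "moran.csv"), row.names = FALSE)
  list(n_tests = nrow(res))
}

stage_evaluate <- function(cfg, dir) {
  design <- read_design(cfg, dir)
  out <- list()
  for (resp in cfg$responses) {
    rep_ <- run_validation(design, response = resp,
                           train_fraction = cfg$train_fraction,
                           loops = cfg$loops,
                           seed = derive_seed(cfg$seed, paste0("eval_", resp)),
                           combo_folds = cfg$combo_folds)
    tab <- rep_$table
    tab$response <- resp
    out[[resp]] <- tab
  }
  res <- do.call(rbind, out)
  res <- res[, c("response", "model", "metric", "mean", "sd")]
  utils::write.csv(res, file.path(dir, "evaluation.csv"), row.names = FALSE)
  list(table = res)
}

# lowest mean MSE wins; ties go to the simpler family
select_best_model <- function(eval_tab, response) {
  order_pref <- c("ridge", "pls", "regression_tree", "model_tree",
                  "combination")
  mse <- eval_tab[eval_tab$metric == "MSE" & eval_tab$response == response, ]
  mse$pref <- match(mse$model, order_pref)
  mse <- mse[order(mse$mean, mse$pref), ]
  mse$model[1]
}

forecast_design <- function(cfg, dir, years) {
  region <- load_region(cfg, dir)
  exposure <- read_exposure_panel(file.path(dir, "exposure_panel.csv"))
  regional <- regional_panel(exposure, region)
  fake_out <- data.frame(area_id = rep(region_ids(region), length(years)),
                         year = rep(years, each = length(region_ids(region))),
                         mortality_rate = 1, morbidity_rate = 1,
                         stringsAsFactors = FALSE)
  build_lag_design(exposure, regional, fake_out, max_lag = cfg$max_lag)
}

stage_forecast <- function(cfg, dir) {
  design <- read_design(cfg, dir)
  eval_tab <- utils::read.csv(file.path(dir, "evaluation.csv"),
                              stringsAsFactors = FALSE)
  last_year <- max(design$year)
  fyears <- last_year + seq_len(cfg$n_forecast_years)
  fdesign <- forecast_design(cfg, dir, fyears)
  Xf <- as_feature_matrix(as.data.frame(fdesign)[, design_predictors(fdesign),
                                                 drop = FALSE])
  X <- as_feature_matrix(as.data.frame(design)[, design_predictors(design),
                                               drop = FALSE])
  preds <- fdesign[, c("area_id", "year")]
  meta <- list()
  for (resp in cfg$responses) {
    y <- design[[resp]]
    best <- select_best_model(eval_tab, resp)
    seed_f <- derive_seed(cfg$seed, paste0("forecast_", resp))
    specs <- default_model_specs()
    if (best == "combination") {
      res <- fit_and_predict_all(X, y, Xf, specs, cfg$combo_folds, seed_f)
      preds[[paste0("predicted_", sub("_rate$", "", resp))]] <-
        res$predictions$combination
      meta[[resp]] <- list(best_model = best,
                           weights = as.list(res$weights$weights))
    } else {
      m <- fit_model_spec(specs[[best]], X, y, seed = seed_f)
      preds[[paste0("predicted_", sub("_rate$", "", resp))]] <- predict(m, Xf)
      meta[[resp]] <- list(best_model = best)
    }
  }
  preds$model <- vapply(cfg$responses,
                        function(r) meta[[r]]$best_model, "")[1]
  utils::write.csv(preds, file.path(dir, "forecast.csv"), row.names = FALSE)
  meta
}

stage_map <- function(cfg, dir) {
  region <- load_region(cfg, dir)
  preds <- utils::read.csv(file.path(dir, "forecast.csv"),
                           stringsAsFactors = FALSE)
  cents <- region_centroids(region)
  lat <- region$lattice
  tg <- list(origin = c(lon = lat$origin_lon, lat = lat$origin_lat),
             cell_size = cfg$kriging_cell_size,
             n_rows = as.integer(round(lat$n_rows * lat$cell_deg /
                                         cfg$kriging_cell_size)),
             n_cols = as.integer(round(lat$n_cols * lat$cell_deg /
                                         cfg$kriging_cell_size)))
  map_dir <- file.path(dir, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  outs <- character(0)
  for (resp in cfg$responses) {
    col <- paste0("predicted_", sub("_rate$", "", resp))
    for (y in sort(unique(preds$year))) {
      sub <- preds[preds$year == y, ]
      xy <- cents[sub$area_id, , drop = FALSE]
      emp <- empirical_variogram(xy, sub[[col]],
                                 n_lags = min(12, nrow(sub) - 1))
      vg <- fit_variogram(emp)
      ks <- ordinary_kriging(xy, sub[[col]], vg, tg,
                             k_neighbors = cfg$kriging_neighbors)
      base <- file.path(map_dir, sprintf("%s_%d", sub("_rate$", "", resp), y))
      write_kriged_surface(ks, paste0(base, ".asc"), paste0(base, ".csv"))
      outs <- c(outs, paste0(base, ".asc"))
    }
  }
  list(maps = basename(outs))
}

#' Run the full pipeline
#'
#' Executes every stage in order on a simulated panel, writing all
#' intermediate artifacts plus a manifest to `out_dir`.  The run is fully
#' reproducible: re-running with the same config produces byte-identical
#' CSV outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param stages stages to run, in order (default: all).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg, out_dir, stages = PIPELINE_STAGES) {
  stopifnot(inherits(cfg, "pipeline_config"))
  assert_that(all(stages %in% PIPELINE_STAGES), "unknown stage name")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if ("simulate" %in% stages) {
    unlink(file.path(out_dir, "run.log"))
  }
  meta <- list()
  for (st in stages) {
    log_stage(out_dir, sprintf("stage %s: start", st))
    res <- tryCatch(
      switch(st,
        simulate = stage_simulate(cfg, out_dir),
        aggregate = stage_aggregate(cfg, out_dir),
        design = stage_design(cfg, out_dir),
        correlate = stage_correlate(cfg, out_dir),
        moran = stage_moran(cfg, out_dir),
        evaluate = stage_evaluate(cfg, out_dir),
        forecast = stage_forecast(cfg, out_dir),
        map = stage_map(cfg, out_dir)
      ),
      error = function(e) {
        log_stage(out_dir, sprintf("stage %s: FAILED (%s)", st,
                                   conditionMessage(e)))
        stop_lagcast(sprintf("pipeline stage '%s' failed: %s", st,
                             conditionMessage(e)),
                     "lagcast_stage_failure")
      }
    )
    meta[[st]] <- res
    log_stage(out_dir, sprintf("stage %s: done", st))
  }

  cfg_path <- file.path(out_dir, "config.txt")
  write_pipeline_config(cfg, cfg_path)
  manifest <- list(
    package = "lagcast",
    version = as.character(utils::packageVersion("lagcast")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), character(0))],
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = stages,
    forecast = meta$forecast,
    artifacts = sort(setdiff(list.files(out_dir),
                             c("manifest.json", "run.log")))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
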