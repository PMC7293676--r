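# Distributed-lag design assembly and pooled Pearson correlation table.

#' Regional exposure panel from a local exposure panel
#'
#' Computes, for every area and year, the unweighted mean exposure of the
#' area's queen-contiguity neighbors.  Neighbors contribute regardless of
#' registry coverage: the full exposure surface is used.
#'
#' @param exposure data frame with `area_id`, `year`, `mean_pm25`.
#' @param region a `study_region`.
#' @return data frame with `area_id`, `year`, `reg_pm25`.
#' @export
regional_panel <- function(exposure, region) {
  ids <- region_ids(region)
  years <- sort(unique(exposure$year))
  out <- lapply(years, function(y) {
    sub <- exposure[exposure$year == y, ]
    v <- stats::setNames(sub$mean_pm25, sub$area_id)
    data.frame(area_id = ids, year = y,
               reg_pm25 = unname(regional_mean(v, region)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

lag_col_names <- function(max_lag) {
  c(sprintf("loc_lag_%d", 0:max_lag), sprintf("reg_lag_%d", 0:max_lag))
}

#' Assemble the lagged exposure-response design
#'
#' One row per retained (area, year) outcome record, with 2 * (max_lag + 1)
#' predictors: the area's own exposure in the outcome year and each of the
#' previous `max_lag` years (`loc_lag_0..loc_lag_8` by default) and the
#' neighbors' mean exposure over the same years (`reg_lag_0..reg_lag_8`).
#' Rows missing any lag value are dropped and counted.
#'
#' @param exposure local exposure panel (`area_id`, `year`, `mean_pm25`).
#' @param regional regional panel (`area_id`, `year`, `reg_pm25`), e.g. from
#'   [regional_panel()].
#' @param outcomes outcome panel (`area_id`, `year`, `mortality_rate`,
#'   `morbidity_rate`).
#' @param max_lag deepest lag in years (default 8).
#' @return data frame (class `lag_design`) with `area_id`, `year`, the
#'   predictor columns in fixed order, then `mortality_rate`,
#'   `morbidity_rate`.
#' @export
build_lag_design <- function(exposure, regional, outcomes, max_lag = 8L) {
  assert_that(max_lag >= 0, "max_lag must be >= 0")
  max_lag <- as.integer(max_lag)
  loc_key <- paste(exposure$area_id, exposure$year)
  reg_key <- paste(regional$area_id, regional$year)
  loc_val <- stats::setNames(exposure$mean_pm25, loc_key)
  reg_val <- stats::setNames(regional$reg_pm25, reg_key)

  preds <- matrix(NA_real_, nrow(outcomes), 2 * (max_lag + 1),
                  dimnames = list(NULL, lag_col_names(max_lag)))
  for (k in 0:max_lag) {
    key <- paste(outcomes$area_id, outcomes$year - k)
    preds[, sprintf("loc_lag_%d", k)] <- unname(loc_val[key])
    preds[, sprintf("reg_lag_%d", k)] <- unname(reg_val[key])
  }
  complete <- stats::complete.cases(preds)
  dropped <- sum(!complete)
  if (dropped > 0) {
    message(sprintf("build_lag_design: dropped %d row(s) lacking lag history",
                    dropped))
  }
  assert_that(any(complete),
              "no outcome row has complete lag history; check exposure years")
  design <- cbind(
    outcomes[complete, c("area_id", "year"), drop = FALSE],
    as.data.frame(preds[complete, , drop = FALSE]),
    outcomes[complete, c("mortality_rate", "morbidity_rate"), drop = FALSE]
  )
  rownames(design) <- NULL
  attr(design, "max_lag") <- max_lag
  class(design) <- c("lag_design", "data.frame")
  design
}

#' Predictor column names of a lag design
#' @param design a `lag_design`.
#' @return character vector, `loc_lag_0..k` then `reg_lag_0..k`.
#' @export
design_predictors <- function(design) {
  lag_col_names(attr(design, "max_lag") %||% 8L)
}

#' Pooled Pearson correlations between outcomes and every lag predictor
#'
#' All (area, year) rows of the unbalanced panel are pooled, unweighted, and
#' a standard Pearson correlation with a two-sided t-test is computed for
#' each response (mortality, morbidity) against each of the lag predictors.
#' Pairs involving a constant column are reported as `NA`.
#'
#' @param design a [build_lag_design()] result.
#' @return data frame (class `correlation_table`) with columns `response`,
#'   `predictor`, `scale` ("local"/"regional"), `lag`, `r`, `p`.
#' @export
pearson_table <- function(design) {
  assert_that(nrow(design) >= 3, "need at least 3 rows for correlations")
  preds <- design_predictors(design)
  responses <- c(mortality = "mortality_rate", morbidity = "morbidity_rate")
  rows <- list()
  for (rn in names(responses)) {
    y <- design[[responses[[rn]]]]
    for (pc in preds) {
      x <- design[[pc]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x, y, method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      lag <- as.integer(sub(".*_(\\d+)$", "\\1", pc))
      rows[[length(rows) + 1]] <- data.frame(
        response = rn, predictor = pc,
        scale = if (startsWith(pc, "loc")) "local" else "regional",
        lag = lag, r = r, p = p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Reshape a correlation table to the wide report layout
#'
#' Rows are response x scale, columns are lags 0..k -- the layout used in
#' registry-panel reports.
#'
#' @param tab a [pearson_table()] result.
#' @return data frame with columns `response`, `scale`, `lag_0` ... `lag_k`.
#' @export
format_correlation_table <- function(tab) {
  lags <- sort(unique(tab$lag))
  combos <- unique(tab[, c("response", "scale")])
  out <- combos
  for (k in lags) {
    out[[sprintf("lag_%d", k)]] <- mapply(function(rs, sc) {
      tab$r[tab$response == rs & tab$scale == sc & tab$lag == k]
    }, combos$response, combos$scale)
  }
  rownames(out) <- NULL
  out
}
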