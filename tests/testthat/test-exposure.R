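# Grid-to-area aggregation, WHO classification, merging, zero filtering.

unit_grid <- function(values, cell_size = 1, origin = c(0, 0), year = 2000) {
  exposure_grid(year, cell_size, origin, values)
}

square_area <- function(x0, y0, x1, y1, id = "A") {
  list(area_id = id,
       polygon = cbind(lon = c(x0, x1, x1, x0, x0),
                       lat = c(y0, y0, y1, y1, y0)),
       centroid = c(lon = (x0 + x1) / 2, lat = (y0 + y1) / 2),
       population_by_year = c("2000" = 1e5))
}

test_that("aggregation averages interior cell centers", {
  g <- unit_grid(matrix(c(10, 20), 1, 2))        # centers (0.5,0.5), (1.5,0.5)
  res <- aggregate_grid_to_area(g, square_area(0, 0, 2, 1))
  expect_equal(res$mean_pm25, 15)
  expect_equal(res$n_cells, 2L)

  # 10x10 grid, value = column index; polygon covering columns 3..6
  v <- matrix(rep(1:10, times = 10), 10, 10, byrow = TRUE)
  g10 <- unit_grid(v, cell_size = 1)
  area <- square_area(2, 0, 6, 10)               # centers 2.5..5.5 -> cols 3..6
  res10 <- aggregate_grid_to_area(g10, area)
  # brute-force oracle over all cell centers
  cc <- expand.grid(lon = seq(0.5, 9.5), lat = seq(0.5, 9.5))
  inside <- cc$lon > 2 & cc$lon < 6
  expect_equal(res10$mean_pm25, mean(cc$lon[inside] + 0.5))  # col = lon + .5
  expect_equal(res10$mean_pm25, 4.5)
  expect_equal(res10$n_cells, 40L)
})

test_that("empty intersections raise a named error", {
  g <- unit_grid(matrix(c(NA_real_, NA_real_), 1, 2))
  expect_error(aggregate_grid_to_area(g, square_area(0, 0, 2, 1, "A7")),
               "empty intersection.*A7")
  g2 <- unit_grid(matrix(5, 1, 1))
  expect_error(aggregate_grid_to_area(g2, square_area(10, 10, 11, 11, "B")),
               "empty intersection")
})

test_that("boundary centers go to the lexicographically smallest area", {
  # two unit squares sharing the edge x = 1; grid centers sit ON boundaries:
  # cell size 1, origin (0.5, 0) -> centers at x = 1.0 and 2.0, y = 0.5
  g <- exposure_grid(2000, 1, c(0.5, 0), matrix(c(3, 9), 1, 2))
  a <- square_area(0, 0, 1, 1, "a_left")        # x = 1 on its boundary
  b <- square_area(1, 0, 2, 1, "b_right")       # x = 1 and x = 2 on boundary
  region <- structure(list(areas = list(a_left = a, b_right = b),
                           adjacency = list(a_left = "b_right",
                                            b_right = "a_left"),
                           lattice = NULL), class = "study_region")
  ra <- aggregate_grid_to_area(g, a, region)
  expect_equal(ra$n_cells, 1L)                  # the x = 1 center, owned by a_left
  expect_equal(ra$mean_pm25, 3)
  rb <- aggregate_grid_to_area(g, b, region)
  expect_equal(rb$n_cells, 1L)                  # only the interior x = 2... boundary
  expect_equal(rb$mean_pm25, 9)
})

test_that("area mean is bounded by contributing cell values", {
  set.seed(31)
  for (rep in 1:10) {
    v <- matrix(runif(100, 5, 60), 10, 10)
    g <- unit_grid(v)
    x0 <- runif(1, 0, 4); y0 <- runif(1, 0, 4)
    area <- square_area(x0, y0, x0 + runif(1, 2, 5), y0 + runif(1, 2, 5))
    res <- aggregate_grid_to_area(g, area)
    expect_gte(res$mean_pm25, min(v))
    expect_lte(res$mean_pm25, max(v))
  }
})

test_that("the lattice fast path agrees with the polygon path", {
  cfg <- small_config(seed = 11)
  region <- generate_region(cfg)
  grids <- generate_exposure_fields(region, cfg)
  fast <- build_exposure_panel(grids[1], region)
  slow_region <- region
  slow_region$lattice <- NULL                    # force the polygon path
  slow <- build_exposure_panel(grids[1], slow_region)
  expect_equal(fast$mean_pm25, slow$mean_pm25, tolerance = 1e-12)
  expect_equal(fast$n_cells, slow$n_cells)
})

test_that("WHO threshold classification is correct and monotone", {
  expect_equal(classify_who(12), "AQG")
  expect_setequal(classify_who(36), c("AQG", "IT-3", "IT-2", "IT-1"))
  expect_length(classify_who(9), 0)
  expect_equal(classify_who(15), "AQG")          # strict exceedance at 15
  expect_error(classify_who(-1), "nonnegative")
  set.seed(5)
  for (i in 1:50) {
    a <- runif(1, 0, 50); b <- a + runif(1, 0, 20)
    expect_true(all(classify_who(a) %in% classify_who(b)))
  }
})

test_that("merging pools counts over the combined population", {
  expect_equal(merge_areas(c(5, 15), c(50000, 150000)), 10)
  expect_equal(merge_areas(5, 100000), 5)
  # equal populations: pooled rate = unweighted mean of rates
  expect_equal(merge_area_rates(c(10, 20, 30), rep(2e5, 3)), 20)
  expect_error(merge_areas(numeric(0), numeric(0)), "at least one")
  expect_error(merge_areas(3, 0), "> 0")
  # count preservation: pooled rate * total pop / 1e5 = total count
  set.seed(8)
  counts <- rpois(6, 40); pops <- round(runif(6, 1e4, 1e6))
  pooled <- merge_areas(counts, pops)
  expect_equal(pooled * sum(pops) / 1e5, sum(counts), tolerance = 1e-12)
})

test_that("records with a zero outcome are dropped", {
  panel <- data.frame(
    area_id = sprintf("a%d", 1:10), year = 2010,
    mortality_rate = c(0, 5, 3, 0, 8, 2, 9, 4, 6, 1),
    morbidity_rate = c(12, 7, 0, 4, 9, 3, 5, 2, 8, 6),
    population = 1e5
  )
  expect_message(out <- filter_zero_outcomes(panel), "3 record")
  expect_equal(nrow(out), 7)
  expect_true(all(out$mortality_rate > 0 & out$morbidity_rate > 0))
  expect_false("a1" %in% out$area_id)   # zero mortality, positive morbidity
})

test_that("ESRI ASCII and long-CSV round trips preserve the grid", {
  g <- exposure_grid(2005, 0.25, c(100, 30),
                     matrix(c(1.5, NA, 3.25, 4, 5, 6), 2, 3))
  tmp <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(g, tmp)
  g2 <- read_esri_ascii(tmp, year = 2005)
  expect_equal(g2$values, g$values)
  expect_equal(g2$cell_size, 0.25)
  expect_equal(unname(g2$origin), c(100, 30))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_exposure_long(list(g), csv)
  long <- read.csv(csv)
  expect_equal(nrow(long), 5)                    # NODATA omitted
  expect_named(long, c("lon", "lat", "year", "pm25"))
})
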