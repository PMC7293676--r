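# Generator: lattice geography, exposure fields, outcome panels.

test_that("lattice regions have the right queen adjacency", {
  r22 <- generate_region(generator_config(n_rows = 2, n_cols = 2))
  expect_length(r22$areas, 4)
  # every pair adjacent on a 2x2 lattice (corner contact counts)
  for (id in names(r22$adjacency)) {
    expect_setequal(r22$adjacency[[id]], setdiff(names(r22$areas), id))
  }

  r33 <- generate_region(generator_config(n_rows = 3, n_cols = 3))
  degrees <- lengths(r33$adjacency)
  expect_equal(unname(degrees[["r002c002"]]), 8)   # center
  corner_ids <- c("r001c001", "r001c003", "r003c001", "r003c003")
  expect_equal(unname(degrees[corner_ids]), rep(3, 4))
  expect_equal(sum(degrees), 40)  # ordered neighbor pairs

  # adjacency is irreflexive and symmetric
  for (id in names(r33$adjacency)) {
    expect_false(id %in% r33$adjacency[[id]])
    for (nb in r33$adjacency[[id]]) {
      expect_true(id %in% r33$adjacency[[nb]])
    }
  }
})

test_that("degenerate lattices are rejected", {
  expect_error(generator_config(n_rows = 1, n_cols = 3), "at least 4 areas")
  expect_error(generate_region(generator_config(n_rows = 1, n_cols = 4)),
               "2x2")
})

test_that("the generator is deterministic given the seed", {
  cfg <- small_config(seed = 42)
  a <- suppressMessages(generate_all(cfg))
  b <- suppressMessages(generate_all(cfg))
  expect_identical(a$region, b$region)
  expect_identical(a$grids, b$grids)
  expect_identical(a$outcomes, b$outcomes)
  c_ <- suppressMessages(generate_all(small_config(seed = 43)))
  expect_false(identical(a$outcomes$mortality_rate,
                         c_$outcomes$mortality_rate))
})

test_that("zero sill yields the pure deterministic gradient", {
  cfg <- small_config(field_sill = 0, field_gradient = 2, field_mean = 30)
  region <- generate_region(cfg)
  grids <- generate_exposure_fields(region, cfg)
  g <- grids[[1]]
  # constant within columns, linear in longitude, identical across years
  expect_equal(max(apply(g$values, 2, function(col) diff(range(col)))), 0)
  cc <- lagcast:::grid_cell_centers(g)
  expect_equal(g$values[1, ],
               pmax(30 + 2 * (cc$lon - mean(cc$lon)), 0.5),
               ignore_attr = TRUE)
  expect_identical(grids[[1]]$values, grids[[10]]$values)
})

test_that("with no gradient the field mean approaches the configured mean", {
  # Monte-Carlo: 100 replicate 50x50 fields; the replicate means scatter
  # around 0 with the SE of a correlated field's spatial mean
  means <- vapply(1:100, function(s) {
    mean(lagcast:::grf_fields(50, 50, 0.1, sill = 80, range = 0.5,
                              n_fields = 1, seed = s)[[1]])
  }, numeric(1))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-9)
  # marginal variance matches the sill (pooled across replicates)
  vars <- vapply(1:20, function(s) {
    stats::var(as.vector(lagcast:::grf_fields(50, 50, 0.1, 80, 0.5,
                                              1, seed = s)[[1]]))
  }, numeric(1))
  expect_lt(abs(mean(vars) - 80) / 80, 0.1)
})

test_that("outcomes follow the noise-free lag model exactly", {
  # all coefficients zero: every rate equals the intercept
  cfg <- small_config(sigma_eps = 0, beta_loc = rep(0, 9),
                      lambda_reg = rep(0, 9), alpha = 40,
                      alpha_morbidity = 40)
  sim <- suppressMessages(generate_all(cfg))
  expect_equal(unique(sim$outcomes$mortality_rate), 40)
  expect_equal(unique(sim$outcomes$morbidity_rate), 40)

  # identity mapping through loc_lag_0
  cfg2 <- small_config(sigma_eps = 0, beta_loc = c(1, rep(0, 8)),
                       lambda_reg = rep(0, 9), alpha = 5)
  sim2 <- suppressMessages(generate_all(cfg2))
  key <- paste(sim2$exposure$area_id, sim2$exposure$year)
  loc0 <- sim2$exposure$mean_pm25[match(
    paste(sim2$outcomes$area_id, sim2$outcomes$year), key)]
  expect_equal(sim2$outcomes$mortality_rate - 5, loc0, tolerance = 1e-12)
})

test_that("default registry schedule gives 34 areas in 2006 and 339 in 2014", {
  cfg <- generator_config(seed = 2)   # default 19x19 lattice
  sim <- suppressMessages(generate_all(cfg))
  counts <- table(sim$outcomes$year)
  expect_equal(unname(counts[["2006"]]), 34)
  expect_equal(unname(counts[["2014"]]), 339)
  expect_equal(nrow(sim$outcomes), 1294)
})

test_that("registry coverage is monotone: areas enter and never exit", {
  sim <- suppressMessages(generate_all(small_config(seed = 7)))
  years <- sort(unique(sim$outcomes$year))
  for (i in seq_along(years)[-1]) {
    prev <- sim$outcomes$area_id[sim$outcomes$year == years[i - 1]]
    curr <- sim$outcomes$area_id[sim$outcomes$year == years[i]]
    expect_true(all(prev %in% curr))
  }
})

test_that("insufficient lag history is refused naming the missing years", {
  cfg <- small_config()
  region <- generate_region(cfg)
  grids <- generate_exposure_fields(region, cfg)
  exposure <- build_exposure_panel(grids, region)
  truncated <- exposure[exposure$year >= 2000, ]
  expect_error(generate_outcomes(region, truncated, cfg), "1998, 1999")
})

test_that("Poisson-count mode produces valid rates from counts", {
  cfg <- small_config(poisson_counts = TRUE, seed = 3)
  sim <- suppressMessages(generate_all(cfg))
  expect_true(all(sim$outcomes$mortality_rate >= 0.01))
  # rate * population / 1e5 must be a whole count (up to the 0.01 floor)
  counts <- sim$outcomes$mortality_rate * sim$outcomes$population / 1e5
  whole <- abs(counts - round(counts)) < 1e-6
  floored <- sim$outcomes$mortality_rate == 0.01
  expect_true(all(whole | floored))
})
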