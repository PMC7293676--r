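# Shared fixtures, all built in code at test time.

# small generator world: 6x6 lattice, coarse grid; ~140 panel rows
small_config <- function(seed = 1L, ...) {
  generator_config(n_rows = 6, n_cols = 6, cells_per_area = 4, seed = seed,
                   ...)
}

small_design <- function(seed = 1L, ...) {
  cfg <- small_config(seed = seed, ...)
  sim <- suppressMessages(generate_all(cfg))
  suppressMessages(build_lag_design(
    sim$exposure, regional_panel(sim$exposure, sim$region),
    filter_zero_outcomes(sim$outcomes)))
}

# hand-built region: a 1 x n strip of unit squares with queen adjacency
strip_region <- function(n) {
  areas <- lapply(seq_len(n), function(i) {
    x0 <- i - 1
    list(area_id = sprintf("s%02d", i),
         polygon = cbind(lon = c(x0, x0 + 1, x0 + 1, x0, x0),
                         lat = c(0, 0, 1, 1, 0)),
         centroid = c(lon = x0 + 0.5, lat = 0.5),
         population_by_year = c("2006" = 1e5))
  })
  ids <- vapply(areas, `[[`, "", "area_id")
  names(areas) <- ids
  adjacency <- lapply(seq_len(n), function(i) {
    ids[setdiff(intersect(c(i - 1, i + 1), seq_len(n)), i)]
  })
  names(adjacency) <- ids
  structure(list(areas = areas, adjacency = adjacency, lattice = NULL),
            class = "study_region")
}

# binary weights from an explicit edge list (used for rook-lattice oracles)
edge_weights <- function(n, edges, ids = sprintf("a%d", seq_len(n))) {
  W <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    W[edges[k, 1], edges[k, 2]] <- 1
    W[edges[k, 2], edges[k, 1]] <- 1
  }
  lagcast:::new_spatial_weights(ids, W, "queen_binary")
}

# all leaves of a fitted tree model
tree_leaves <- function(node) {
  if (node$leaf) list(node) else c(tree_leaves(node$left), tree_leaves(node$right))
}

# brute-force single-split search: minimizes total SSE over every midpoint
# of every feature; independent of the C++ implementation
brute_force_split <- function(X, y, min_leaf) {
  best <- list(sse = Inf, feature = 0L, threshold = NA_real_)
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (thr in (xs[-1] + xs[-length(xs)]) / 2) {
      l <- y[X[, j] <= thr]; r <- y[X[, j] > thr]
      if (length(l) < min_leaf || length(r) < min_leaf) next
      sse <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
      if (sse < best$sse - 1e-12) {
        best <- list(sse = sse, feature = j, threshold = thr)
      }
    }
  }
  best
}
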