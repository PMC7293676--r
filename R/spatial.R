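# Spatial weights, regional-scale exposure, and Global Moran's I.

new_spatial_weights <- function(ids, W, kind, row_standardized = FALSE) {
  dimnames(W) <- list(ids, ids)
  S0 <- sum(W)
  assert_that(all(diag(W) == 0), "weights must have a zero diagonal")
  assert_that(all(W >= 0), "weights must be nonnegative")
  assert_that(S0 > 0, "degenerate weights: S0 = 0 (all areas are islands)")
  structure(list(ids = ids, W = W, kind = kind,
                 row_standardized = row_standardized, S0 = S0),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights (%s): n = %d, S0 = %g%s\n", x$kind,
              length(x$ids), x$S0,
              if (x$row_standardized) ", row-standardized" else ""))
  invisible(x)
}

#' Queen-contiguity binary weights
#'
#' `w_ij = 1` when areas i and j share at least one boundary point (edge or
#' corner), 0 otherwise.  Islands (areas with no neighbor) are permitted but
#' reported; a region in which every area is an island is rejected.
#'
#' @param region a `study_region` (its adjacency relation encodes queen
#'   contiguity).
#' @return a `spatial_weights` object, `kind = "queen_binary"`.
#' @export
queen_weights <- function(region) {
  ids <- region_ids(region)
  assert_that(length(ids) >= 2, "need at least 2 areas")
  n <- length(ids)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- region$adjacency[[ids[i]]]
    W[i, match(nb, ids)] <- 1
  }
  islands <- ids[rowSums(W) == 0]
  if (length(islands) > 0) {
    message(sprintf("queen_weights: %d island area(s): %s",
                    length(islands), paste(islands, collapse = ", ")))
  }
  new_spatial_weights(ids, W, "queen_binary")
}

#' Inverse-distance weights
#'
#' `w_ij = 1 / d_ij^power` with planar Euclidean distances in degrees
#' (optionally great-circle km), zeroed beyond `cutoff` when one is given.
#' Not row-standardized by default.
#'
#' @param centroids two-column matrix (lon, lat); rownames used as ids.
#' @param power distance exponent (default 1).
#' @param cutoff distance beyond which weights are 0; `NULL` = no cutoff.
#' @param ids area ids (default rownames of `centroids`).
#' @param great_circle if `TRUE`, use haversine distances in km.
#' @param row_standardize divide each row by its sum.
#' @return a `spatial_weights` object, `kind = "inverse_distance"`.
#' @export
inverse_distance_weights <- function(centroids, power = 1, cutoff = NULL,
                                     ids = rownames(centroids),
                                     great_circle = FALSE,
                                     row_standardize = FALSE) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  assert_that(n >= 2, "need at least 2 points")
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(n))
  if (great_circle) {
    d <- haversine_matrix(centroids)
  } else {
    d <- as.matrix(stats::dist(centroids))
  }
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    pr <- which(d == 0 & upper.tri(d), arr.ind = TRUE)[1, ]
    stop_lagcast(sprintf("coincident centroids: '%s' and '%s' (infinite weight)",
                         ids[pr[1]], ids[pr[2]]), "lagcast_coincident_points")
  }
  W <- 1 / d^power
  diag(W) <- 0
  if (!is.null(cutoff)) W[d > cutoff] <- 0
  if (row_standardize) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  new_spatial_weights(ids, W, "inverse_distance", row_standardize)
}

haversine_matrix <- function(coords) {
  rad <- pi / 180
  lon <- coords[, 1] * rad; lat <- coords[, 2] * rad
  n <- length(lon)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    a <- sin((lat[j] - lat[i]) / 2)^2 +
      cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
    dij <- 2 * 6371 * asin(pmin(1, sqrt(a)))
    d[i, j] <- dij; d[j, i] <- dij
  }
  d
}

#' Row-standardize a weight matrix
#'
#' @param weights a `spatial_weights` object.
#' @return a new `spatial_weights` with each nonzero row summing to 1.
#' @export
row_standardize <- function(weights) {
  W <- weights$W
  rs <- rowSums(W)
  W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  new_spatial_weights(weights$ids, W, weights$kind, row_standardized = TRUE)
}

#' Regional-scale value: unweighted mean over contiguity neighbors
#'
#' For each area, the arithmetic mean of the values of its queen-contiguity
#' neighbors.  This is the "regional scale" of the exposure-response design:
#' the surrounding areas' concentration, unweighted.  Islands get `NA`.
#'
#' @param values named numeric vector covering every area of `region`.
#' @param region a `study_region`.
#' @return named numeric vector in region order.
#' @export
regional_mean <- function(values, region) {
  ids <- region_ids(region)
  assert_that(all(ids %in% names(values)),
              "values must cover every area of the region")
  v <- values[ids]
  out <- vapply(ids, function(id) {
    nb <- region$adjacency[[id]]
    if (length(nb) == 0) NA_real_ else mean(v[nb])
  }, numeric(1))
  stats::setNames(out, ids)
}

#' Global Moran's I with analytic or permutation inference
#'
#' Computes `I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i
#' (x_i - xbar)^2`, its expectation `E[I] = -1/(n-1)`, and a z-test of
#' spatial randomness under the normality or randomization closed-form
#' variance, or by Monte-Carlo permutation of the values over locations.
#' The default is the randomization assumption.
#'
#' @param x numeric vector of area values (named or in weights order).
#' @param weights a `spatial_weights` object.
#' @param assumption one of `"randomization"`, `"normality"`,
#'   `"permutation"`.
#' @param n_perm permutation replicates (permutation assumption only).
#' @param seed seed for the permutation stream.
#' @return an object of class `moran_result` with fields `I`, `expected`,
#'   `variance`, `z`, `p_value`, `n`, `assumption`.
#' @export
morans_i <- function(x, weights,
                     assumption = c("randomization", "normality", "permutation"),
                     n_perm = 999, seed = 1L) {
  assumption <- match.arg(assumption)
  stopifnot(inherits(weights, "spatial_weights"))
  W <- weights$W
  n <- length(weights$ids)
  assert_that(n >= 4, "Moran's I inference needs n >= 4")
  if (!is.null(names(x))) {
    assert_that(all(weights$ids %in% names(x)),
                "x must cover every area in the weights")
    x <- x[weights$ids]
  }
  assert_that(length(x) == n, "x must align with the weights")
  S0 <- weights$S0
  assert_that(S0 > 0, "S0 = 0: weights are degenerate")
  z <- x - mean(x)
  m2 <- sum(z^2)
  if (m2 <= 0) {
    stop_lagcast("zero variance, Moran's I undefined (x is constant)",
                 "lagcast_constant_values")
  }
  I_of <- function(zv) (n / S0) * drop(zv %*% W %*% zv) / sum(zv^2)
  I <- I_of(z)
  E <- -1 / (n - 1)

  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  if (assumption == "normality") {
    V <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - E^2
    zstat <- (I - E) / sqrt(V)
    p <- 2 * stats::pnorm(-abs(zstat))
  } else if (assumption == "randomization") {
    b2 <- n * sum(z^4) / m2^2
    num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
      b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
    V <- num / ((n - 1) * (n - 2) * (n - 3) * S0^2) - E^2
    zstat <- (I - E) / sqrt(V)
    p <- 2 * stats::pnorm(-abs(zstat))
  } else {
    perms <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        zp <- sample(z)
        I_of(zp)
      }, numeric(1))
    })
    V <- stats::var(perms)
    zstat <- (I - mean(perms)) / stats::sd(perms)
    p <- min(1, 2 * min((1 + sum(perms >= I)) / (n_perm + 1),
                        (1 + sum(perms <= I)) / (n_perm + 1)))
  }
  structure(list(I = I, expected = E, variance = V, z = zstat,
                 p_value = p, n = n, assumption = assumption),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f), z = %.3f, p = %.4g [%s, n = %d]\n",
              x$I, x$expected, x$z, x$p_value, x$assumption, x$n))
  invisible(x)
}
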