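#' @useDynLib lagcast, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor cor.test dist fft lm optim pnorm predict
#'   quantile rnorm rpois runif sd var
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG to `seed`, runs `code`, and restores the caller's RNG state,
#' so that seeded generator calls do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed for a named random substream.  Every stage of the
# pipeline draws from its own substream derived from the single user seed, so
# stages can be re-run or reordered without changing each other's draws.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483399) + 1L
}

stop_lagcast <- function(msg, code = "lagcast_error") {
  cond <- structure(
    class = c(code, "lagcast_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

assert_that <- function(ok, msg, code = "lagcast_error") {
  if (!isTRUE(ok)) stop_lagcast(msg, code)
  invisible(TRUE)
}

# column standard deviations without the per-column apply() overhead
col_sds <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  sqrt(pmax(colSums(X^2) - n * m^2, 0) / (n - 1))
}
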