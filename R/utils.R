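#' @import methods
#' @useDynLib prepattn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aov arima.sim coef complete.cases cor dgamma lm.fit
#'   median pt qt quantile rbinom rlnorm rnorm runif sd t.test uniroot var
#' @importFrom utils head modifyList read.csv tail write.csv write.table
NULL

#' Derive a child seed from a parent seed and a key path
#'
#' One user-facing seed fans out to per-stage / per-participant / per-run
#' random streams so partial re-runs are stable: the keys are hashed with a
#' small multiplicative scheme over a 31-bit ring. The same parent seed and
#' key path always yield the same child seed.
#'
#' @param seed parent integer seed.
#' @param ... key path components (coerced to character), e.g.
#'   `childSeed(1, "participant", 3)`.
#' @return an integer seed below 2^31.
#' @export
childSeed <- function(seed, ...) {
  keys <- vapply(list(...), as.character, character(1))
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    for (ch in utf8ToInt(k)) {
      h <- (h * 131 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG state (seeded), restoring the caller's
# .Random.seed afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Clip correlations away from +/-1 so the Fisher transform stays finite on
# degenerate fixtures (identical patterns).
clipR <- function(r, eps = 1e-12) {
  pmin(pmax(r, -1 + eps), 1 - eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assertProb <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stopf("'%s' must be a probability in [0, 1]", name)
  }
  invisible(x)
}
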