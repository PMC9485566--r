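# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' perturb the caller's random stream. A `NULL` seed uses the current
#' stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-unit sub-seed, kept below 2^31 - 1.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483587 + 1)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("'%s' must be a single positive number", name)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_invalid("'%s' must be a single non-negative number", name)
  invisible(x)
}

# Trapezoidal integral of y over x (or unit-spaced grid).
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# Linear interpolation of the x where y crosses `level`, scanning segment
# [i, i+1]. Assumes y[i] and y[i+1] bracket the level.
cross_interp <- function(x, y, i, level) {
  dy <- y[i + 1] - y[i]
  if (dy == 0) return(x[i])
  x[i] + (level - y[i]) / dy * (x[i + 1] - x[i])
}
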