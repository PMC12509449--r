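# Internal helpers: argument checking, seeded randomness, truncated draws.

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "capnovent_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_input <- function(msg) abort(msg, "capnovent_input_error")
abort_config <- function(msg) abort(msg, "capnovent_config_error")
abort_domain <- function(msg) abort(msg, "capnovent_domain_error")
abort_numerical <- function(msg) abort(msg, "capnovent_numerical_error")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x)) {
    abort_input(sprintf("`%s` must be a finite numeric value", name))
  }
  if (any(!is.finite(x)) || any(x < lower) || any(x > upper)) {
    abort_input(sprintf("`%s` must lie in [%g, %g]", name, lower, upper))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort_input(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    abort_input(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so no function in the package mutates global RNG state.
#' A `NULL` seed evaluates `code` under the ambient RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_number(seed, "seed")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stream seed from a master seed
#'
#' Deterministic integer hash used to give each stochastic stage of a study
#' its own seed; changing one stage's stream index never perturbs another's.
#' Result is always in `[1, 2^31 - 2]`.
#'
#' @param master Master seed (integer).
#' @param stream Stream index (integer >= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(master, stream) {
  check_number(master, "master")
  check_number(stream, "stream")
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(master) %% m) * 48271 + (abs(stream) %% m) * 16807 + 12345
  as.integer(x %% (m - 1) + 1)
}

# Symmetrically truncated normal draw via inverse-CDF: one uniform per value,
# exactly zero mean shift relative to the untruncated law.
rtnorm <- function(n, mean = 0, sd = 1, z = 2.5) {
  if (any(sd < 0)) abort_input("`sd` must be >= 0")
  lo <- stats::pnorm(-z)
  u <- stats::runif(n, lo, 1 - lo)
  mean + sd * stats::qnorm(u)
}

# Trapezoidal cumulative integral on a uniform grid.
cumtrapz <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(numeric(n) * 0)
  c(0, cumsum((y[-n] + y[-1]) / 2 * dt))
}

# First n primes (n small).
first_primes <- function(n) {
  out <- integer(0)
  x <- 2L
  while (length(out) < n) {
    if (all(x %% out != 0L)) out <- c(out, x)
    x <- x + 1L
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
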