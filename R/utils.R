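# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn
#' @importFrom stats pnorm qnorm runif rnorm rbinom optim optimize uniroot
#'   pf pchisq t.test wilcox.test sd setNames
#' @importFrom utils head tail
NULL

# Draw from a Gaussian truncated below at `floor` (inverse-CDF method).
# Durations in this package are never allowed to reach zero; 0.1 hr is the
# floor used throughout.
rtnorm_floor <- function(n, mean, sd, floor = 0.1) {
  if (sd == 0) {
    return(rep(max(mean, floor), n))
  }
  lo <- pnorm((floor - mean) / sd)
  qnorm(runif(n, lo, 1)) * sd + mean
}

# Snap an event time up to the first observation at which it would be seen
# (wells are inspected every `interval` hours).
snap_up <- function(t, interval) {
  ceiling(t / interval) * interval
}

# Evaluate `expr` under a temporary seed when `seed` is non-NULL, leaving the
# caller's RNG stream untouched.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    abort(sprintf(
      "`%s` must be in %s%s, %s]; got %s.",
      name, if (strict_lower) "(" else "[", format(lower), format(upper),
      format(x)
    ))
  }
  invisible(x)
}

check_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s.",
      what, if (length(missing) > 1) "s" else "", toString(missing)
    ))
  }
  invisible(data)
}
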