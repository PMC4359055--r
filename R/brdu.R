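#' Least-squares fit of BrdU incorporation kinetics
#'
#' Fits the saturating label-incorporation curve
#' `F(t) = plateau * (1 - 2^(-t / doubling_time))` to a time course of
#' label-positive fractions. The base-2 form makes the half-time of the fit
#' literally equal to the population doubling time, which is the quantity
#' reported. Days are converted to hours internally; the doubling time is
#' reported in hours.
#'
#' @param series A data frame with columns `day` and `fraction_labelled`
#'   (replicates as extra rows are fine). A `time_hours` column may be
#'   supplied instead of `day`.
#' @return An object of class `brdu_fit`: `doubling_time` (hours),
#'   `plateau`, `r_squared`, `residual_ss`, `n_points`, `data`. Supports
#'   [tidy()], [glance()], [autoplot()][ggplot2::autoplot()] and
#'   `predict()`.
#' @export
#' @examples
#' series <- data.frame(day = 0:12)
#' series$fraction_labelled <- 1 - 2^(-series$day * 24 / 60)
#' fit_brdu(series)
fit_brdu <- function(series) {
  if (!"time_hours" %in% names(series)) {
    check_columns(series, c("day", "fraction_labelled"), "`series`")
    series$time_hours <- series$day * 24
  }
  check_columns(series, c("time_hours", "fraction_labelled"), "`series`")
  pts <- series[stats::complete.cases(
    series[, c("time_hours", "fraction_labelled")]
  ), ]
  t <- pts$time_hours
  y <- pts$fraction_labelled
  if (length(unique(t)) < 4) {
    abort("A BrdU fit needs at least 4 distinct time points.",
      class = "hsc_insufficient_data"
    )
  }
  if (all(y == 0)) {
    abort("All labelled fractions are zero: no signal to fit.",
      class = "hsc_insufficient_signal"
    )
  }

  ss <- function(par) {
    sum((y - brdu_expectation(t, par[1], par[2]))^2)
  }
  # Initial half-time: first time the series crosses half its maximum.
  ymax <- max(y)
  above <- which(y >= ymax / 2 & t > 0)
  td0 <- if (length(above) > 0) max(t[above[1]], 1) else max(t) / 2
  lower <- c(0.5, 1e-3)
  upper <- c(20 * max(t), 1)
  best <- NULL
  for (td_start in unique(c(td0, td0 / 2, td0 * 2))) {
    for (pl_start in unique(pmin(1, c(ymax, ymax * 1.1)))) {
      fit <- tryCatch(
        optim(c(td_start, pl_start), ss,
          method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 10000, factr = 10)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
  }
  if (is.null(best)) {
    abort("BrdU fit failed to converge.", class = "hsc_fit_failure")
  }
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      doubling_time = best$par[1],
      plateau = best$par[2],
      r_squared = if (ss_tot > 0) 1 - best$value / ss_tot else NA_real_,
      residual_ss = best$value,
      n_points = length(t),
      n_params = 2L,
      converged = best$convergence == 0,
      data = tibble::tibble(time_hours = t, fraction_labelled = y)
    ),
    class = "brdu_fit"
  )
}

#' @export
print.brdu_fit <- function(x, ...) {
  cat(sprintf(
    "BrdU incorporation fit: doubling time %.1f h, plateau %.3f, R^2 %.4f\n",
    x$doubling_time, x$plateau, x$r_squared
  ))
  invisible(x)
}

#' @export
predict.brdu_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_hours else newdata$time_hours
  brdu_expectation(t, object$doubling_time, object$plateau)
}

#' Fit BrdU kinetics per subtype
#'
#' @param series A data frame with columns `subtype`, `day`,
#'   `fraction_labelled` (e.g. from [simulate_brdu_series()]).
#' @return A tibble with one row per subtype: `subtype`, `doubling_time`
#'   (hours), `plateau`, `r_squared`, `n_points`.
#' @export
fit_brdu_kinetics <- function(series) {
  check_columns(series, "subtype", "`series`")
  purrr::map_dfr(unique(series$subtype), function(st) {
    fit <- fit_brdu(series[series$subtype == st, , drop = FALSE])
    tibble::tibble(
      subtype = st,
      doubling_time = fit$doubling_time,
      plateau = fit$plateau,
      r_squared = fit$r_squared,
      n_points = fit$n_points
    )
  })
}

# Pooled fit under the shared-doubling-time null: one doubling time, one
# plateau per group. Used by doubling_time_ratio().
fit_brdu_shared_td <- function(t_a, y_a, t_b, y_b) {
  ss <- function(par) {
    sum((y_a - brdu_expectation(t_a, par[1], par[2]))^2) +
      sum((y_b - brdu_expectation(t_b, par[1], par[3]))^2)
  }
  t_all <- c(t_a, t_b)
  y_all <- c(y_a, y_b)
  above <- which(y_all >= max(y_all) / 2 & t_all > 0)
  td0 <- if (length(above) > 0) max(t_all[above[1]], 1) else max(t_all) / 2
  best <- NULL
  for (td_start in c(td0, td0 / 2, td0 * 2)) {
    fit <- tryCatch(
      optim(c(td_start, min(1, max(y_a)), min(1, max(y_b))), ss,
        method = "L-BFGS-B",
        lower = c(0.5, 1e-3, 1e-3), upper = c(20 * max(t_all), 1, 1),
        control = list(maxit = 10000, factr = 10)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    abort("Shared-doubling-time fit failed.", class = "hsc_fit_failure")
  }
  list(
    residual_ss = best$value,
    n_points = length(t_all),
    n_params = 3L
  )
}

#' Ratio of doubling times between two BrdU fits
#'
#' Reports `doubling_time(a) / doubling_time(b)` -- with the LT fit first
#' this is the fold difference in division frequency between subsets -- and
#' tests whether the two series share a doubling time with an extra
#' sum-of-squares F test (null: one common doubling time, separate
#' plateaus).
#'
#' @param fit_a,fit_b [fit_brdu()] results (conventionally LT then ST).
#' @return A one-row tibble: `ratio`, `doubling_time_a`, `doubling_time_b`
#'   (hours), `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
doubling_time_ratio <- function(fit_a, fit_b) {
  if (!inherits(fit_a, "brdu_fit") || !inherits(fit_b, "brdu_fit")) {
    abort("`fit_a` and `fit_b` must be `brdu_fit` objects.")
  }
  shared <- fit_brdu_shared_td(
    fit_a$data$time_hours, fit_a$data$fraction_labelled,
    fit_b$data$time_hours, fit_b$data$fraction_labelled
  )
  test <- compare_fits_extra_ss(shared, fit_a, fit_b)
  tibble::tibble(
    ratio = fit_a$doubling_time / fit_b$doubling_time,
    doubling_time_a = fit_a$doubling_time,
    doubling_time_b = fit_b$doubling_time,
    statistic = test$statistic,
    df1 = test$df1,
    df2 = test$df2,
    p.value = test$p.value
  )
}
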