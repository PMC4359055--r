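# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("plateau", "log_ec50", "ec50_hours", "slope"),
    estimate = c(x$plateau, x$log_ec50, x$ec50_hours, x$slope)
  )
}

#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    residual_ss = x$residual_ss,
    ec50_hours = x$ec50_hours,
    nobs = x$n_points,
    converged = x$converged
  )
}

#' @export
tidy.brdu_fit <- function(x, ...) {
  tibble::tibble(
    term = c("doubling_time", "plateau"),
    estimate = c(x$doubling_time, x$plateau)
  )
}

#' @export
glance.brdu_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    residual_ss = x$residual_ss,
    doubling_time = x$doubling_time,
    nobs = x$n_points,
    converged = x$converged
  )
}

#' @export
tidy.lda_fit <- function(x, ...) {
  tibble::tibble(
    term = "frequency",
    estimate = x$frequency,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
}

#' @export
glance.lda_fit <- function(x, ...) {
  tibble::tibble(
    frequency = x$frequency,
    one_in = ifelse(x$frequency > 0, 1 / x$frequency, Inf),
    log_likelihood = x$log_likelihood,
    flagged = x$flagged,
    boundary = x$boundary,
    nobs = sum(x$table$n_recipients)
  )
}

#' @export
tidy.hsc_sim <- function(x, ...) {
  tidyr::pivot_longer(x$series, -"time_hours",
    names_to = "series", values_to = "value"
  )
}

#' @export
glance.hsc_sim <- function(x, ...) {
  d <- divisions_per_year(x)
  tibble::tibble(
    hypothesis = x$params$hypothesis,
    horizon_days = x$params$horizon_days,
    lt_divisions_per_year = d$divisions_per_year[d$subtype == "LT"],
    st_divisions_per_year = d$divisions_per_year[d$subtype == "ST"],
    lt_interdivision_days = d$interdivision_days[d$subtype == "LT"],
    final_progenitors = x$final$n_progenitor
  )
}

#' @export
tidy.hsc_replicates <- function(x, ...) {
  x$series_summary
}

#' @export
glance.hsc_replicates <- function(x, ...) {
  lt <- x$runs[x$runs$subtype == "LT", ]
  tibble::tibble(
    hypothesis = x$params$hypothesis,
    n_runs = x$n_runs,
    lt_divisions_per_year = mean(lt$divisions_per_year),
    lt_divisions_per_year_sd = sd(lt$divisions_per_year),
    lt_interdivision_days = mean(lt$interdivision_days)
  )
}
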