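#' Cumulative division curve from single-cell tracks
#'
#' Builds the cumulative fraction of wells that have divided as a function of
#' time, excluding dead wells. For `division = 1` the time axis is hours
#' since mitogenic stimulation and the denominator is all non-dead wells.
#' For `division = 2` the curve is built on the cell-cycle-transit axis --
#' hours from a well's observed first division to its observed second -- and
#' the denominator is the non-dead wells with an observed first division.
#' The transit axis is what makes the fitted half-maximal time of the second
#' curve an estimate of the G1-S-G2-M transit time, so that
#' `t_g0_exit = t_first_div - t_second_div` is nonnegative in expectation.
#'
#' @param tracks A data frame of tracks as produced by
#'   [simulate_division_tracks()] (columns `subtype`, `died`,
#'   `first_division_time`, `second_division_time`). If several subtypes are
#'   present a curve is computed for each.
#' @param division 1 (first division) or 2 (second division, transit axis).
#' @return A tibble with columns `subtype` (if present), `time`,
#'   `fraction_divided` and `n_alive` (the denominator). Fractions are
#'   nondecreasing in time within each subtype.
#' @export
cumulative_division_curve <- function(tracks, division = 1) {
  check_columns(
    tracks, c("died", "first_division_time", "second_division_time"),
    "`tracks`"
  )
  if (!division %in% c(1, 2)) abort("`division` must be 1 or 2.")

  interval <- attr(tracks, "observation_interval") %||% {
    tt <- tracks$first_division_time
    tt <- tt[!is.na(tt) & tt > 0]
    if (length(tt) == 0) abort("Cannot infer the observation interval.")
    min(tt)
  }
  last_obs <- if (!is.null(attr(tracks, "observation_times"))) {
    max(attr(tracks, "observation_times"))
  } else {
    max(c(tracks$first_division_time, tracks$second_division_time, interval),
      na.rm = TRUE
    )
  }
  grid <- seq(interval, last_obs, by = interval)

  one_curve <- function(df) {
    alive <- df[!df$died, , drop = FALSE]
    if (division == 1) {
      events <- alive$first_division_time
      n_alive <- nrow(alive)
    } else {
      alive <- alive[!is.na(alive$first_division_time), , drop = FALSE]
      events <- alive$second_division_time - alive$first_division_time
      n_alive <- nrow(alive)
    }
    if (n_alive < 5) {
      abort(
        sprintf(
          "Insufficient data: %d usable wells (need at least 5).", n_alive
        ),
        class = "hsc_insufficient_data"
      )
    }
    events <- events[!is.na(events)]
    tibble::tibble(
      time = grid,
      fraction_divided = vapply(
        grid, function(t) sum(events <= t) / n_alive, numeric(1)
      ),
      n_alive = n_alive
    )
  }

  out <- if ("subtype" %in% names(tracks) &&
    length(unique(tracks$subtype)) > 1) {
    dplyr::reframe(
      dplyr::group_by(tibble::as_tibble(tracks), .data$subtype),
      one_curve(dplyr::pick(dplyr::everything()))
    )
  } else {
    res <- one_curve(tracks)
    if ("subtype" %in% names(tracks)) {
      res <- dplyr::mutate(res, subtype = tracks$subtype[1], .before = 1)
    }
    res
  }
  attr(out, "division") <- division
  class(out) <- c("division_curve", class(out))
  out
}

#' Log-logistic sigmoid on a log10 time axis
#'
#' `plateau / (1 + 10^(slope * (log_ec50 - log10(t))))`: the characteristic
#' time is the half-plateau point, `10^log_ec50` hours.
#'
#' @param t Time, hours (> 0).
#' @param plateau,log_ec50,slope Curve parameters.
#' @return The expected cumulative divided fraction at `t`.
#' @export
sigmoid_model <- function(t, plateau, log_ec50, slope) {
  plateau / (1 + 10^(slope * (log_ec50 - log10(t))))
}

#' Least-squares sigmoid fit of a cumulative division curve
#'
#' Fits `F(t) = plateau / (1 + 10^(slope * (log_ec50 - log10(t))))` to a
#' cumulative division curve by least squares (multi-start quasi-Newton
#' minimisation of the residual sum of squares). `ec50_hours = 10^log_ec50`
#' is the time at half-plateau and is the characteristic division time
#' reported downstream (`t_first_div`, `t_second_div`). Points at
#' `time <= 0` are dropped (log axis).
#'
#' @param curve A data frame with columns `time` (hours) and
#'   `fraction_divided`, typically from [cumulative_division_curve()] for a
#'   single subtype.
#' @return An object of class `sigmoid_fit`: a list with elements `plateau`,
#'   `log_ec50`, `ec50_hours`, `slope`, `r_squared`, `residual_ss`,
#'   `n_points`, `converged` and the fitted `data`. Supports [tidy()],
#'   [glance()], [autoplot()][ggplot2::autoplot()] and `predict()`.
#' @export
#' @examples
#' curve <- data.frame(time = seq(12, 132, 12))
#' curve$fraction_divided <- sigmoid_model(curve$time, 0.9, log10(40), 4)
#' fit <- fit_sigmoid(curve)
#' glance(fit)
fit_sigmoid <- function(curve) {
  check_columns(curve, c("time", "fraction_divided"), "`curve`")
  pts <- curve[curve$time > 0, c("time", "fraction_divided")]
  pts <- pts[stats::complete.cases(pts), ]
  t <- pts$time
  y <- pts$fraction_divided
  if (length(t) < 4) {
    abort("A sigmoid fit needs at least 4 positive-time points.",
      class = "hsc_insufficient_data"
    )
  }
  if (all(y == 0)) {
    abort("All fractions are zero: no signal to fit.",
      class = "hsc_insufficient_signal"
    )
  }
  plateau_est <- max(y)
  if (!any(y < 0.4 * plateau_est) || !any(y > 0.6 * plateau_est)) {
    abort(
      paste(
        "Curve does not bracket its half-maximum:",
        "need points below 0.4 and above 0.6 of the plateau estimate."
      ),
      class = "hsc_insufficient_data"
    )
  }

  ss <- function(par) {
    sum((y - sigmoid_model(t, par[1], par[2], par[3]))^2)
  }
  # Time at which the curve first crosses half its maximum (log10 hours).
  above <- which(y >= plateau_est / 2)
  lec50_0 <- log10(t[above[1]])
  lower <- c(1e-3, log10(min(t)) - 0.5, 0.2)
  upper <- c(1, log10(max(t)) + 0.5, 30)
  starts <- expand.grid(
    plateau = unique(pmin(1, c(plateau_est, plateau_est * 1.05))),
    log_ec50 = lec50_0 + c(-0.15, 0, 0.15),
    slope = c(1, 2, 4, 8)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), ss,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    abort("Sigmoid fit failed to converge from any start.",
      class = "hsc_fit_failure"
    )
  }
  # Final polish at tight tolerance.
  polished <- tryCatch(
    optim(best$par, ss,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = 10000, factr = 10)
    ),
    error = function(e) best
  )
  if (polished$value <= best$value) best <- polished

  par <- best$par
  ss_res <- best$value
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      plateau = par[1],
      log_ec50 = par[2],
      ec50_hours = 10^par[2],
      slope = par[3],
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      residual_ss = ss_res,
      n_points = length(t),
      n_params = 3L,
      converged = best$convergence == 0,
      data = tibble::tibble(time = t, fraction_divided = y)
    ),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "Sigmoid fit: EC50 %.2f h (log10 %.3f), slope %.2f, plateau %.3f\n",
    x$ec50_hours, x$log_ec50, x$slope, x$plateau
  ))
  cat(sprintf(
    "  R-squared %.4f, residual SS %.3g, %d points\n",
    x$r_squared, x$residual_ss, x$n_points
  ))
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time else newdata$time
  sigmoid_model(t, object$plateau, object$log_ec50, object$slope)
}

#' Derive the kinetic triplet from first- and second-division fits
#'
#' `t_first_div` is the half-plateau time of the first-division curve,
#' `t_second_div` that of the second-division (transit-axis) curve, and the
#' G0-exit duration is their difference. A negative G0-exit duration is
#' returned, not clipped, but flagged: it can occur by sampling noise even
#' though the second division is empirically always faster than the first.
#'
#' @param first_fit,second_fit [fit_sigmoid()] results for the first- and
#'   second-division curves of one subtype in one sample.
#' @param subtype,sample_id Labels carried into the output.
#' @return A one-row tibble: `sample_id`, `subtype`, `t_first_div`,
#'   `t_second_div`, `t_g0_exit`, `r_squared_first`, `r_squared_second`,
#'   `flagged`.
#' @export
derive_kinetics <- function(first_fit, second_fit, subtype = NA_character_,
                            sample_id = NA_character_) {
  if (!inherits(first_fit, "sigmoid_fit") ||
    !inherits(second_fit, "sigmoid_fit")) {
    abort("`first_fit` and `second_fit` must be `sigmoid_fit` objects.")
  }
  t1 <- first_fit$ec50_hours
  t2 <- second_fit$ec50_hours
  tibble::tibble(
    sample_id = sample_id,
    subtype = subtype,
    t_first_div = t1,
    t_second_div = t2,
    t_g0_exit = t1 - t2,
    r_squared_first = first_fit$r_squared,
    r_squared_second = second_fit$r_squared,
    flagged = (t1 - t2) < 0
  )
}

#' Full division-kinetics pipeline for one tracked sample
#'
#' Convenience wrapper running [cumulative_division_curve()] and
#' [fit_sigmoid()] for the first and second division of each subtype and
#' assembling the kinetic triplet via [derive_kinetics()].
#'
#' @param tracks A tracks data frame (see [simulate_division_tracks()]).
#' @param sample_id Label for the sample (e.g. one cord-blood donor).
#' @return A tibble with one row per subtype (see [derive_kinetics()]), plus
#'   `n_wells`, the number of non-dead wells behind the first-division curve.
#' @export
fit_division_kinetics <- function(tracks, sample_id = "sample") {
  subtypes <- unique(tracks$subtype)
  purrr::map_dfr(subtypes, function(st) {
    sub <- tracks[tracks$subtype == st, , drop = FALSE]
    for (a in c("observation_times", "horizon", "observation_interval")) {
      attr(sub, a) <- attr(tracks, a)
    }
    c1 <- cumulative_division_curve(sub, division = 1)
    c2 <- cumulative_division_curve(sub, division = 2)
    row <- derive_kinetics(
      fit_sigmoid(c1), fit_sigmoid(c2),
      subtype = st, sample_id = sample_id
    )
    row$n_wells <- c1$n_alive[1]
    row
  })
}

#' Paired comparison of kinetic parameters across samples
#'
#' Standard two-sided paired t test, pairing by position (samples must be in
#' the same order in both vectors), as used to compare LT- and ST-HSC
#' parameters measured in the same cord-blood donors.
#'
#' @param values_a,values_b Numeric vectors of equal length (>= 2), hours.
#' @return A one-row tibble: `estimate` (mean of `values_a - values_b`),
#'   `statistic`, `df`, `p.value`, `conf.low`, `conf.high`.
#' @export
paired_compare <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    abort("`values_a` and `values_b` must have the same length.")
  }
  if (length(values_a) < 2) abort("Need at least 2 pairs.")
  d <- values_a - values_b
  if (sd(d) == 0) {
    # Degenerate but well-defined: identical pairs carry no evidence.
    est <- mean(d)
    return(tibble::tibble(
      estimate = est,
      statistic = if (est == 0) 0 else sign(est) * Inf,
      df = length(d) - 1,
      p.value = if (est == 0) 1 else 0,
      conf.low = est, conf.high = est
    ))
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  tibble::tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2]
  )
}

#' Extra sum-of-squares F test for nested least-squares fits
#'
#' Compares a joint fit (one parameter set shared by two groups, fitted to
#' the pooled points) against separate per-group fits. Works for any fits
#' that expose `residual_ss`, `n_points` and `n_params`
#' ([fit_sigmoid()] and [fit_brdu()] results).
#'
#' @param fit_joint Fit to the pooled data under the shared-parameter null.
#' @param fit_a,fit_b Separate fits to each group.
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p.value`,
#'   `ss_joint`, `ss_separate`.
#' @export
compare_fits_extra_ss <- function(fit_joint, fit_a, fit_b) {
  for (f in list(fit_joint, fit_a, fit_b)) {
    if (!all(c("residual_ss", "n_points", "n_params") %in% names(f))) {
      abort("Fits must expose `residual_ss`, `n_points` and `n_params`.")
    }
  }
  n <- fit_joint$n_points
  if (n != fit_a$n_points + fit_b$n_points) {
    abort("The joint fit must pool exactly the points of the two group fits.")
  }
  ss_joint <- fit_joint$residual_ss
  ss_sep <- fit_a$residual_ss + fit_b$residual_ss
  df_joint <- n - fit_joint$n_params
  df_sep <- n - fit_a$n_params - fit_b$n_params
  if (df_sep <= 0) {
    abort("Not enough points for separate fits (df <= 0).")
  }
  f_stat <- max(0, ((ss_joint - ss_sep) / (df_joint - df_sep)) /
    (ss_sep / df_sep))
  tibble::tibble(
    statistic = f_stat,
    df1 = df_joint - df_sep,
    df2 = df_sep,
    p.value = pf(f_stat, df_joint - df_sep, df_sep, lower.tail = FALSE),
    ss_joint = ss_joint,
    ss_separate = ss_sep
  )
}
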