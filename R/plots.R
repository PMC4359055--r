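# ggplot2 presentations of curves, fits and simulations.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_step
#'   geom_ribbon geom_hline geom_vline labs facet_wrap scale_y_log10
NULL

#' @export
ggplot2::autoplot

#' @export
autoplot.division_curve <- function(object, ...) {
  division <- attr(object, "division") %||% 1
  xlab <- if (identical(division, 2)) {
    "Time from first division (h)"
  } else {
    "Time since stimulation (h)"
  }
  p <- ggplot(object, aes(x = .data$time, y = .data$fraction_divided))
  if ("subtype" %in% names(object)) {
    p <- p + geom_step(aes(colour = .data$subtype)) +
      geom_point(aes(colour = .data$subtype))
  } else {
    p <- p + geom_step() + geom_point()
  }
  p + labs(x = xlab, y = "Cumulative fraction divided")
}

#' Cumulative division curves for a tracked experiment
#'
#' @param tracks A tracks data frame (see [simulate_division_tracks()]).
#' @param division 1 or 2, passed to [cumulative_division_curve()].
#' @return A ggplot.
#' @export
plot_division_curves <- function(tracks, division = 1) {
  autoplot(cumulative_division_curve(tracks, division))
}

#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time = exp(seq(log(min(object$data$time)), log(max(object$data$time)),
      length.out = 200
    ))
  )
  grid$fitted <- predict(object, grid)
  ggplot(object$data, aes(x = .data$time, y = .data$fraction_divided)) +
    geom_point() +
    geom_line(data = grid, aes(y = .data$fitted)) +
    geom_vline(xintercept = object$ec50_hours, linetype = "dashed") +
    labs(
      x = "Time (h)", y = "Cumulative fraction divided",
      subtitle = sprintf(
        "EC50 %.1f h, R² = %.3f", object$ec50_hours, object$r_squared
      )
    )
}

#' @export
autoplot.brdu_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time_hours = seq(0, max(object$data$time_hours), length.out = 200)
  )
  grid$fitted <- predict(object, grid)
  ggplot(object$data, aes(x = .data$time_hours / 24,
    y = .data$fraction_labelled)) +
    geom_point() +
    geom_line(data = grid, aes(x = .data$time_hours / 24, y = .data$fitted)) +
    labs(
      x = "Time (days)", y = "Fraction BrdU-positive",
      subtitle = sprintf(
        "Doubling time %.0f h, R² = %.3f",
        object$doubling_time, object$r_squared
      )
    )
}

#' @export
autoplot.lda_fit <- function(object, ...) {
  # Classic limiting-dilution presentation: log fraction of non-engrafted
  # recipients against dose is linear with slope -frequency.
  tab <- object$table
  tab$frac_neg <- pmax(
    (tab$n_recipients - tab$n_engrafted) / tab$n_recipients, 1e-3
  )
  grid <- tibble::tibble(dose = seq(0, max(tab$dose), length.out = 100))
  grid$frac_neg <- exp(-object$frequency * grid$dose)
  ggplot(tab, aes(x = .data$dose, y = .data$frac_neg)) +
    geom_point() +
    geom_line(data = grid) +
    scale_y_log10() +
    labs(
      x = "Dose (cells)", y = "Fraction non-engrafted (log scale)",
      subtitle = sprintf(
        "Frequency 1 in %.1f (95%% CI %.1f-%.1f)",
        1 / object$frequency, 1 / object$ci_high, 1 / object$ci_low
      )
    )
}

#' @export
autoplot.hsc_replicates <- function(object, ...) {
  s <- object$series_summary
  ggplot(s, aes(x = .data$time_hours / 24, y = .data$mean)) +
    geom_ribbon(
      aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      alpha = 0.3
    ) +
    geom_line() +
    facet_wrap(~series, scales = "free_y") +
    labs(
      x = "Time (days)", y = "Mean ± SD over runs",
      subtitle = sprintf(
        "%s, %d runs", object$params$hypothesis, object$n_runs
      )
    )
}
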