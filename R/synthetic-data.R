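#' Configuration for synthetic single-cell division tracking
#'
#' Describes an in-vitro single-cell division-tracking experiment: single
#' LT-HSCs and ST-HSCs are sorted one per well, exposed to a mitogenic
#' stimulus at time 0, and inspected at fixed intervals (twice a day by
#' default) over a fixed horizon. Each cell's (latent) time to first division
#' is the sum of a G0-exit duration and a cell-cycle-transit duration; the
#' second division follows after an independent transit draw. Durations are
#' Gaussian, truncated below at 0.1 hr. A fraction of wells dies before
#' dividing and is excluded from downstream curves.
#'
#' Default between-subtype structure: LT-HSCs exit G0 5.8 hr more slowly than
#' ST-HSCs and their cycle transit is 3.2 hr longer, so the mean time to
#' first division differs by 9 hr. Absolute anchors (LT: 23 + 33 hr,
#' ST: 17.2 + 29.8 hr) and the SDs are package choices; see the methods
#' vignette.
#'
#' @param n_wells_per_subtype Wells per subtype (default 288, i.e. 576 total).
#' @param horizon Length of the experiment in hours (default 140).
#' @param observation_interval Hours between inspections (default 12).
#' @param mean_g0_exit,sd_g0_exit Named numeric vectors (`LT`, `ST`) of the
#'   mean and SD of the G0-exit duration, hours.
#' @param mean_cycle_transit,sd_cycle_transit Same for the cycle-transit
#'   duration, hours.
#' @param death_probability Probability that a well dies before its first
#'   division (dead wells carry no division times).
#' @param seed Optional integer seed; when supplied the generator is
#'   deterministic and does not disturb the caller's RNG stream.
#'
#' @return A list of class `timing_config`.
#' @seealso [simulate_division_tracks()]
#' @export
#' @examples
#' cfg <- timing_config(n_wells_per_subtype = 24, seed = 1)
#' tracks <- simulate_division_tracks(cfg)
timing_config <- function(n_wells_per_subtype = 288,
                          horizon = 140,
                          observation_interval = 12,
                          mean_g0_exit = c(LT = 23.0, ST = 17.2),
                          sd_g0_exit = c(LT = 5, ST = 5),
                          mean_cycle_transit = c(LT = 33.0, ST = 29.8),
                          sd_cycle_transit = c(LT = 7, ST = 7),
                          death_probability = 0.1,
                          seed = NULL) {
  check_number(n_wells_per_subtype, "n_wells_per_subtype", lower = 1)
  check_number(horizon, "horizon", lower = 0, strict_lower = TRUE)
  check_number(observation_interval, "observation_interval",
    lower = 0, strict_lower = TRUE
  )
  if (horizon < observation_interval) {
    abort("`horizon` must be at least one `observation_interval`.")
  }
  check_number(death_probability, "death_probability", lower = 0, upper = 1)
  for (nm in c("mean_g0_exit", "sd_g0_exit", "mean_cycle_transit",
               "sd_cycle_transit")) {
    v <- get(nm)
    if (!all(c("LT", "ST") %in% names(v))) {
      abort(sprintf("`%s` must be named with elements 'LT' and 'ST'.", nm))
    }
    if (grepl("^mean", nm) && any(v[c("LT", "ST")] <= 0)) {
      abort(sprintf("`%s` must be positive.", nm))
    }
    if (grepl("^sd", nm) && any(v[c("LT", "ST")] < 0)) {
      abort(sprintf("`%s` must be nonnegative.", nm))
    }
  }
  structure(
    list(
      n_wells_per_subtype = as.integer(n_wells_per_subtype),
      horizon = horizon,
      observation_interval = observation_interval,
      mean_g0_exit = mean_g0_exit[c("LT", "ST")],
      sd_g0_exit = sd_g0_exit[c("LT", "ST")],
      mean_cycle_transit = mean_cycle_transit[c("LT", "ST")],
      sd_cycle_transit = sd_cycle_transit[c("LT", "ST")],
      death_probability = death_probability,
      seed = seed
    ),
    class = "timing_config"
  )
}

#' Simulate interval-censored single-cell division tracks
#'
#' Generates one row per well. Latent first-division times are
#' `g0_exit + cycle_transit` draws; latent second-division times add an
#' independent cycle-transit draw, so in expectation the second division is
#' shorter than the first by the mean G0-exit duration. Events are recorded
#' at the first inspection at or after they happen (snap-up interval
#' censoring); events after the last inspection before the horizon are
#' censored (`NA`). Dead wells carry no observed division times.
#'
#' @param config A [timing_config()].
#' @return A tibble with columns `well_id`, `subtype`, `died`,
#'   `first_division_time`, `second_division_time` (observed, hours, `NA` if
#'   censored or dead) and the latent event times
#'   `latent_first_division_time`, `latent_second_division_time` (simulation
#'   truth, available for validation). The observation grid is attached as
#'   attributes `observation_times` and `horizon`.
#' @export
simulate_division_tracks <- function(config = timing_config()) {
  if (!inherits(config, "timing_config")) {
    abort("`config` must be created with `timing_config()`.")
  }
  with_seed_if(config$seed, {
    n <- config$n_wells_per_subtype
    interval <- config$observation_interval
    obs_times <- seq(interval, config$horizon, by = interval)
    last_obs <- obs_times[length(obs_times)]

    one_subtype <- function(subtype) {
      g0 <- rtnorm_floor(n, config$mean_g0_exit[[subtype]],
        config$sd_g0_exit[[subtype]]
      )
      t1 <- rtnorm_floor(n, config$mean_cycle_transit[[subtype]],
        config$sd_cycle_transit[[subtype]]
      )
      t2 <- rtnorm_floor(n, config$mean_cycle_transit[[subtype]],
        config$sd_cycle_transit[[subtype]]
      )
      latent_first <- g0 + t1
      latent_second <- latent_first + t2
      died <- runif(n) < config$death_probability
      obs_first <- snap_up(latent_first, interval)
      obs_second <- snap_up(latent_second, interval)
      obs_first[obs_first > last_obs | died] <- NA_real_
      obs_second[obs_second > last_obs | died] <- NA_real_
      # A censored first division censors the second even if the (snapped)
      # second time would fall on the grid.
      obs_second[is.na(obs_first)] <- NA_real_
      tibble::tibble(
        subtype = subtype,
        died = died,
        first_division_time = obs_first,
        second_division_time = obs_second,
        latent_first_division_time = latent_first,
        latent_second_division_time = latent_second
      )
    }

    out <- dplyr::bind_rows(one_subtype("LT"), one_subtype("ST"))
    out <- dplyr::mutate(out,
      well_id = sprintf("%s_%03d", .data$subtype, dplyr::row_number()),
      .by = "subtype"
    )
    out <- dplyr::relocate(out, "well_id")
    attr(out, "observation_times") <- obs_times
    attr(out, "horizon") <- config$horizon
    attr(out, "observation_interval") <- interval
    out
  })
}

#' Configuration for synthetic BrdU incorporation time courses
#'
#' The fraction of label-positive cells follows the saturating curve
#' `plateau * (1 - 2^(-t / doubling_time))`, so the half-time of the curve
#' equals the population doubling time by construction. Additive Gaussian
#' noise is truncated so fractions stay in `[0, 1]`.
#'
#' Default doubling times (LT 122.4 hr, ST 72 hr, ratio 1.7) sit at the
#' midpoint of the 1.5- to 1.9-fold range reported for the relative division
#' frequency of the two subsets.
#'
#' @param doubling_time Named numeric (`LT`, `ST`), hours.
#' @param plateau Saturation plateau, in (0, 1].
#' @param sampling_days Days at which samples are taken (default 0:12).
#' @param replicates Replicates per (subtype, day).
#' @param noise_sd SD of the additive noise on the labelled fraction.
#' @param seed Optional integer seed.
#' @return A list of class `brdu_config`.
#' @export
brdu_config <- function(doubling_time = c(LT = 122.4, ST = 72),
                        plateau = 0.95,
                        sampling_days = 0:12,
                        replicates = 3,
                        noise_sd = 0.03,
                        seed = NULL) {
  if (!all(c("LT", "ST") %in% names(doubling_time)) ||
    any(doubling_time[c("LT", "ST")] <= 0)) {
    abort("`doubling_time` must have positive elements named 'LT' and 'ST'.")
  }
  check_number(plateau, "plateau", lower = 0, upper = 1, strict_lower = TRUE)
  if (length(sampling_days) == 0) {
    abort("`sampling_days` must not be empty.")
  }
  if (any(sampling_days < 0)) abort("`sampling_days` must be nonnegative.")
  check_number(replicates, "replicates", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(
      doubling_time = doubling_time[c("LT", "ST")],
      plateau = plateau,
      sampling_days = sort(unique(sampling_days)),
      replicates = as.integer(replicates),
      noise_sd = noise_sd,
      seed = seed
    ),
    class = "brdu_config"
  )
}

# Noiseless saturating incorporation curve; `t_hours` and `doubling_time` in
# hours.
brdu_expectation <- function(t_hours, doubling_time, plateau) {
  plateau * (1 - 2^(-t_hours / doubling_time))
}

#' Simulate BrdU incorporation time courses
#'
#' @param config A [brdu_config()].
#' @return A tibble with columns `subtype`, `day`, `replicate`,
#'   `fraction_labelled` (in `[0, 1]`).
#' @export
simulate_brdu_series <- function(config = brdu_config()) {
  if (!inherits(config, "brdu_config")) {
    abort("`config` must be created with `brdu_config()`.")
  }
  with_seed_if(config$seed, {
    grid <- tidyr::expand_grid(
      subtype = c("LT", "ST"),
      day = config$sampling_days,
      replicate = seq_len(config$replicates)
    )
    mu <- unname(brdu_expectation(
      grid$day * 24, config$doubling_time[grid$subtype], config$plateau
    ))
    frac <- mu + rnorm(nrow(grid), 0, config$noise_sd)
    grid$fraction_labelled <- pmin(pmax(frac, 0), 1)
    grid
  })
}

#' Design of a limiting-dilution transplantation assay
#'
#' @param doses Cells transplanted per recipient at each dose level.
#' @param recipients_per_dose Number of recipients per dose (recycled).
#' @param true_frequency Frequency of repopulating cells among plated cells
#'   (in `[0, 1]`); each recipient engrafts independently with probability
#'   `1 - exp(-dose * true_frequency)` (single-hit Poisson model).
#' @param seed Optional integer seed.
#' @return A list of class `lda_design`.
#' @export
lda_design <- function(doses = c(50, 100, 200, 400),
                       recipients_per_dose = 5,
                       true_frequency = 1 / 100,
                       seed = NULL) {
  if (length(doses) == 0 || any(doses <= 0)) {
    abort("`doses` must be positive.")
  }
  if (any(recipients_per_dose < 1)) {
    abort("`recipients_per_dose` must be at least 1.")
  }
  check_number(true_frequency, "true_frequency", lower = 0, upper = 1)
  structure(
    list(
      doses = doses,
      recipients_per_dose = rep_len(
        as.integer(recipients_per_dose), length(doses)
      ),
      true_frequency = true_frequency,
      seed = seed
    ),
    class = "lda_design"
  )
}

#' Simulate engraftment counts for a limiting-dilution assay
#'
#' @param design An [lda_design()].
#' @return A tibble with columns `dose`, `n_recipients`, `n_engrafted`.
#' @export
simulate_lda_counts <- function(design = lda_design()) {
  if (!inherits(design, "lda_design")) {
    abort("`design` must be created with `lda_design()`.")
  }
  with_seed_if(design$seed, {
    p <- 1 - exp(-design$doses * design$true_frequency)
    tibble::tibble(
      dose = design$doses,
      n_recipients = design$recipients_per_dose,
      n_engrafted = rbinom(length(p), design$recipients_per_dose, p)
    )
  })
}
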