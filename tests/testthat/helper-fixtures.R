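# Shared fixtures: small, fast configurations used across test files.

# A reduced tracking experiment (fewer wells) that still supports sigmoid
# fits.
small_timing_config <- function(seed = 1, ...) {
  timing_config(n_wells_per_subtype = 96, seed = seed, ...)
}

# Tracks for a single subtype with hand-set observed division times.
manual_tracks <- function(first, second = NA_real_, died = FALSE,
                          interval = 12, horizon = 140) {
  n <- max(length(first), length(second), length(died))
  out <- tibble::tibble(
    well_id = sprintf("w%02d", seq_len(n)),
    subtype = "LT",
    died = rep_len(died, n),
    first_division_time = rep_len(first, n),
    second_division_time = rep_len(second, n),
    latent_first_division_time = rep_len(first, n),
    latent_second_division_time = rep_len(second, n)
  )
  attr(out, "observation_interval") <- interval
  attr(out, "observation_times") <- seq(interval, horizon, by = interval)
  out
}

# Noiseless cumulative curve drawn from the sigmoid model itself.
model_curve <- function(plateau = 0.9, ec50 = 40, slope = 4,
                        times = seq(12, 132, by = 12)) {
  tibble::tibble(
    time = times,
    fraction_divided = sigmoid_model(times, plateau, log10(ec50), slope)
  )
}

# Small, fast ABM parameter set (short horizon) for structural tests.
small_abm_params <- function(horizon_days = 60, ...) {
  abm_params(horizon_days = horizon_days, ...)
}

# Forced-signal matrix builder: `on_hours` of full signal followed by
# silence, for the given parameter set.
forced_window <- function(params, on_hours) {
  args_steps <- as.integer(round(params$horizon_days * 24 / params$dt))
  m <- matrix(0, nrow = args_steps, ncol = 2)
  on_steps <- as.integer(round(on_hours / params$dt))
  if (on_steps > 0) m[seq_len(min(on_steps, args_steps)), ] <- 1
  m
}
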