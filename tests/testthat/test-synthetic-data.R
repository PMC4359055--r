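# Synthetic division tracks, BrdU series and limiting-dilution tables.

test_that("division times snap up to the next inspection", {
  cfg <- timing_config(
    n_wells_per_subtype = 10,
    mean_g0_exit = c(LT = 20, ST = 20), sd_g0_exit = c(LT = 0, ST = 0),
    mean_cycle_transit = c(LT = 24, ST = 24),
    sd_cycle_transit = c(LT = 0, ST = 0),
    death_probability = 0, seed = 1
  )
  tracks <- simulate_division_tracks(cfg)
  # True first division at 44 h is first seen at the 48 h inspection; the
  # second (true 68 h) at 72 h.
  expect_true(all(tracks$first_division_time == 48))
  expect_true(all(tracks$second_division_time == 72))
})

test_that("default configuration yields 576 wells and valid censoring", {
  tracks <- simulate_division_tracks(timing_config(seed = 42))
  expect_equal(nrow(tracks), 576)
  expect_equal(as.vector(table(tracks$subtype)), c(288L, 288L))

  obs <- c(tracks$first_division_time, tracks$second_division_time)
  obs <- obs[!is.na(obs)]
  expect_true(all(obs %% 12 == 0))
  expect_true(all(obs <= 140))
  # Dead wells never carry observed division times.
  expect_true(all(is.na(tracks$first_division_time[tracks$died])))
  # Ordering holds whenever both divisions are observed.
  both <- !is.na(tracks$first_division_time) &
    !is.na(tracks$second_division_time)
  expect_true(all(tracks$second_division_time[both] >
    tracks$first_division_time[both] - 1e-9))
})

test_that("generation is deterministic given the seed", {
  a <- simulate_division_tracks(timing_config(seed = 7))
  b <- simulate_division_tracks(timing_config(seed = 7))
  expect_identical(a, b)
  c <- simulate_division_tracks(timing_config(seed = 8))
  expect_false(identical(a$latent_first_division_time,
    c$latent_first_division_time))
})

test_that("latent means and death fraction match their Monte-Carlo targets", {
  cfg <- timing_config(n_wells_per_subtype = 5000, seed = 99)
  tracks <- simulate_division_tracks(cfg)
  lt <- tracks[tracks$subtype == "LT", ]
  target <- cfg$mean_g0_exit[["LT"]] + cfg$mean_cycle_transit[["LT"]]
  se <- sd(lt$latent_first_division_time) / sqrt(nrow(lt))
  # Truncation at the 0.1 h floor shifts the mean by < 0.05 h at defaults.
  expect_lt(abs(mean(lt$latent_first_division_time) - target), 3 * se + 0.05)

  p_hat <- mean(tracks$died)
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(tracks)))
})

test_that("timing_config rejects invalid settings", {
  expect_error(timing_config(horizon = 6), "observation_interval")
  expect_error(timing_config(mean_g0_exit = c(LT = -1, ST = 10)), "positive")
  expect_error(timing_config(death_probability = 1.5), "death_probability")
})

test_that("BrdU expectation halves at the doubling time", {
  cfg <- brdu_config(
    doubling_time = c(LT = 48, ST = 48), plateau = 1,
    noise_sd = 0, replicates = 1, sampling_days = 0:12, seed = 1
  )
  series <- simulate_brdu_series(cfg)
  lt <- series[series$subtype == "LT", ]
  expect_equal(lt$fraction_labelled[lt$day == 2], 0.5)
  expect_equal(lt$fraction_labelled[lt$day == 4], 0.75)
})

test_that("noisy BrdU fractions always stay in [0, 1]", {
  for (s in 1:200) {
    series <- simulate_brdu_series(brdu_config(noise_sd = 0.25, seed = s))
    expect_true(all(series$fraction_labelled >= 0 &
      series$fraction_labelled <= 1))
  }
})

test_that("brdu_config validates its inputs", {
  expect_error(brdu_config(sampling_days = numeric(0)), "empty")
  expect_error(brdu_config(doubling_time = c(LT = 0, ST = 48)), "positive")
})

test_that("limiting-dilution counts follow the single-hit model", {
  zero <- simulate_lda_counts(lda_design(true_frequency = 0, seed = 1))
  expect_true(all(zero$n_engrafted == 0))

  # Closed-form single-hit expectation at one dose: 1 - exp(-1).
  big <- simulate_lda_counts(lda_design(
    doses = 100, recipients_per_dose = 1e6,
    true_frequency = 1 / 100, seed = 2
  ))
  frac <- big$n_engrafted / big$n_recipients
  expect_lt(abs(frac - (1 - exp(-1))), 3 * sqrt(0.632 * 0.368 / 1e6))

  a <- simulate_lda_counts(lda_design(seed = 5))
  b <- simulate_lda_counts(lda_design(seed = 5))
  expect_identical(a, b)
})
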