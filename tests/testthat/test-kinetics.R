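# Cumulative curves, sigmoid fits, kinetic triplets and group tests.

test_that("cumulative curve is a step function of the observed divisions", {
  tracks <- manual_tracks(first = rep(48, 10))
  curve <- cumulative_division_curve(tracks, division = 1)
  expect_equal(curve$fraction_divided[curve$time < 48], rep(0, 3))
  expect_true(all(curve$fraction_divided[curve$time >= 48] == 1))
})

test_that("dead wells are excluded from the denominator", {
  tracks <- manual_tracks(
    first = c(rep(60, 5), rep(NA, 5)),
    died = c(rep(FALSE, 5), rep(TRUE, 5))
  )
  curve <- cumulative_division_curve(tracks, division = 1)
  expect_equal(curve$n_alive[1], 5)
  expect_equal(curve$fraction_divided[curve$time == 60], 1)
})

test_that("fewer than five usable wells is an explicit error", {
  tracks <- manual_tracks(first = rep(48, 4))
  expect_error(
    cumulative_division_curve(tracks),
    class = "hsc_insufficient_data"
  )
})

test_that("second-division curves live on the cycle-transit axis", {
  tracks <- manual_tracks(first = rep(48, 8), second = rep(84, 8))
  curve <- cumulative_division_curve(tracks, division = 2)
  # Transit of 36 h: all mass at 36 on the transit axis, not at 84.
  expect_equal(curve$fraction_divided[curve$time == 24], 0)
  expect_equal(curve$fraction_divided[curve$time == 36], 1)
})

test_that("curves from synthetic tracks are nondecreasing", {
  for (s in 1:25) {
    tracks <- simulate_division_tracks(small_timing_config(seed = s))
    for (div in 1:2) {
      curve <- cumulative_division_curve(tracks, division = div)
      for (st in unique(curve$subtype)) {
        f <- curve$fraction_divided[curve$subtype == st]
        expect_true(all(diff(f) >= 0))
        expect_true(all(f >= 0 & f <= 1))
      }
    }
  }
})

test_that("sigmoid fit recovers its own model to four significant digits", {
  curve <- model_curve(plateau = 0.9, ec50 = 40, slope = 4)
  fit <- fit_sigmoid(curve)
  expect_equal(fit$plateau, 0.9, tolerance = 5e-4)
  expect_equal(fit$ec50_hours, 40, tolerance = 5e-4)
  expect_equal(fit$slope, 4, tolerance = 5e-3)
  expect_gt(fit$r_squared, 0.999999)
})

test_that("fitted residual SS never exceeds the best 20^3 grid point", {
  grid <- expand.grid(
    plateau = seq(0.05, 1, length.out = 20),
    log_ec50 = seq(log10(12), log10(132), length.out = 20),
    slope = seq(0.5, 10, length.out = 20)
  )
  for (s in c(2, 11)) {
    tracks <- simulate_division_tracks(small_timing_config(seed = s))
    curve <- cumulative_division_curve(
      tracks[tracks$subtype == "LT", ],
      division = 1
    )
    fit <- fit_sigmoid(curve)
    grid_ss <- vapply(seq_len(nrow(grid)), function(i) {
      sum((curve$fraction_divided -
        sigmoid_model(curve$time, grid$plateau[i], grid$log_ec50[i],
          grid$slope[i]))^2)
    }, numeric(1))
    expect_lte(fit$residual_ss, min(grid_ss) + 1e-12)
    # Fit sanity: the half-maximal time lies inside the observed range.
    expect_gt(fit$ec50_hours, min(curve$time))
    expect_lt(fit$ec50_hours, max(curve$time))
  }
})

test_that("degenerate curves raise explicit errors", {
  flat <- tibble::tibble(time = seq(12, 72, 12), fraction_divided = 0)
  expect_error(fit_sigmoid(flat), class = "hsc_insufficient_signal")
  expect_error(
    fit_sigmoid(model_curve()[1:3, ]),
    class = "hsc_insufficient_data"
  )
})

test_that("the kinetic triplet is an exact difference and flags negatives", {
  f1 <- fit_sigmoid(model_curve(ec50 = 38.0))
  f2 <- fit_sigmoid(model_curve(ec50 = 32.2))
  k <- derive_kinetics(f1, f2, subtype = "LT", sample_id = "CB1")
  expect_equal(k$t_g0_exit, k$t_first_div - k$t_second_div)
  expect_equal(k$t_g0_exit, 5.8, tolerance = 1e-3)
  expect_false(k$flagged)

  k0 <- derive_kinetics(f1, f1)
  expect_equal(k0$t_g0_exit, 0)

  neg <- derive_kinetics(f2, f1)
  expect_lt(neg$t_g0_exit, 0)
  expect_true(neg$flagged)
})

test_that("between-subtype first-division gap is recovered at paper scale", {
  gaps <- vapply(1:20, function(s) {
    tracks <- simulate_division_tracks(timing_config(seed = 300 + s))
    k <- fit_division_kinetics(tracks)
    k$t_first_div[k$subtype == "LT"] - k$t_first_div[k$subtype == "ST"]
  }, numeric(1))
  expect_lt(abs(mean(gaps) - 9), 2)
})

test_that("paired comparison behaves like a paired t test", {
  same <- paired_compare(c(10, 12, 14), c(10, 12, 14))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  shifted <- paired_compare(c(10, 12, 14), c(8, 9, 10))
  expect_equal(shifted$estimate, 3)
  ref <- t.test(c(10, 12, 14), c(8, 9, 10), paired = TRUE)
  expect_equal(shifted$p.value, ref$p.value)

  expect_error(paired_compare(1:3, 1:4), "length")
})

test_that("paired test holds its nominal type-I error under the null", {
  set.seed(123)
  reps <- 10000
  p <- vapply(seq_len(reps), function(i) {
    a <- rnorm(10)
    b <- rnorm(10)
    paired_compare(a, b)$p.value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("extra sum-of-squares F test separates distinct kinetics", {
  set.seed(42)
  times <- seq(12, 156, by = 12) # 13 points
  noisy <- function(ec50) {
    tibble::tibble(
      time = times,
      fraction_divided = pmin(pmax(
        sigmoid_model(times, 0.9, log10(ec50), 4) + rnorm(13, 0, 0.01),
        0
      ), 1)
    )
  }

  # Identical groups: the pooled fit explains the data exactly as well.
  a <- noisy(40)
  joint_same <- fit_sigmoid(dplyr::bind_rows(a, a))
  fa <- fit_sigmoid(a)
  same <- compare_fits_extra_ss(joint_same, fa, fa)
  expect_lt(same$statistic, 1e-3)
  expect_gt(same$p.value, 0.99)

  # Well-separated EC50s at low noise: strongly significant.
  b <- noisy(80)
  fb <- fit_sigmoid(b)
  joint <- fit_sigmoid(dplyr::bind_rows(a, b))
  diff <- compare_fits_extra_ss(joint, fa, fb)
  expect_lt(diff$p.value, 0.01)
  # Nested-model inequality.
  expect_lte(fa$residual_ss + fb$residual_ss, joint$residual_ss + 1e-12)
})
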