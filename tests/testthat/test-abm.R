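# Agent-based model: controller, stepper mechanics, replicates, injury.

test_that("demand signal is zero at target and maximal at empty pools", {
  p <- abm_params()
  at_target <- demand_signal(
    c(LT = 3360, ST = 3360, progenitor = 10000), p
  )
  expect_true(all(at_target$signal == 0))

  empty_prog <- demand_signal(c(LT = 3360, ST = 3360, progenitor = 0), p)
  # The progenitor-demand term saturates at 1 (full deficit) before noise.
  expect_equal(empty_prog$demand,
    rep(p$downstream_weight * 1, 2),
    tolerance = 1e-12
  )

  # Noise acts multiplicatively within +/- noise.
  base <- demand_signal(c(LT = 3360, ST = 3360, progenitor = 9000), p)
  hi <- demand_signal(c(LT = 3360, ST = 3360, progenitor = 9000), p,
    epsilon = 0.05
  )
  expect_equal(hi$signal / base$signal, rep(1.05, 2))
})

test_that("no demand means no divisions", {
  # Zero exit rate: progenitors never drain, no deficit ever arises.
  p <- small_abm_params(hsc_pool_exit_rate = 0)
  sim <- run_simulation(p, seed = 1)
  expect_equal(sum(unlist(sim$counters$divisions)), 0)
})

test_that("a single agent follows the deterministic event path", {
  p <- abm_params(
    hypothesis = "HYP2_2",
    target_pool_sizes = c(LT = 1, ST = 1, progenitor = 10),
    sd_g0_exit = c(LT = 0, ST = 0), sd_cycle_transit = c(LT = 0, ST = 0),
    lt_g0_exit_delay = 5.8, hsc_pool_exit_rate = 0, noise = 0,
    horizon_days = 4
  )
  sim <- run_simulation(p,
    seed = 1, forced_signal = forced_window(p, on_hours = 96),
    record_events = TRUE
  )
  lt_events <- sim$events[sim$events$compartment == 0, ]
  # Activation at 0, commitment at the end of G0 exit (17.2 + 5.8 h),
  # division one cycle transit (33 h) later.
  expect_identical(lt_events$type[1:3], c("activation", "commit", "division"))
  expect_equal(lt_events$time[1:3], c(0, 23, 56), tolerance = p$dt)
  st_events <- sim$events[sim$events$compartment == 1, ]
  expect_equal(st_events$time[1:3], c(0, 17, 47), tolerance = p$dt)
})

test_that("signal withdrawal before commitment aborts HYP2 but not HYP1", {
  base <- list(
    target_pool_sizes = c(LT = 1, ST = 1, progenitor = 10),
    sd_g0_exit = c(LT = 0, ST = 0), sd_cycle_transit = c(LT = 0, ST = 0),
    hsc_pool_exit_rate = 0, noise = 0, horizon_days = 5
  )
  p1 <- do.call(abm_params, c(list(hypothesis = "HYP1"), base))
  p2 <- do.call(abm_params, c(list(hypothesis = "HYP2_1"), base))
  # Signal window (10 h) shorter than the mean G0 exit (17.2 h).
  s1 <- run_simulation(p1, seed = 1, forced_signal = forced_window(p1, 10))
  s2 <- run_simulation(p2, seed = 1, forced_signal = forced_window(p2, 10))
  expect_equal(unlist(s1$counters$divisions), c(1, 1))
  expect_equal(unlist(s2$counters$divisions), c(0, 0))
  expect_equal(unlist(s2$counters$aborts), c(1, 1))
  expect_gte(sum(unlist(s1$counters$divisions)),
    sum(unlist(s2$counters$divisions)))
})

test_that("runs are deterministic given the seed", {
  p <- small_abm_params()
  a <- run_simulation(p, seed = 5)
  b <- run_simulation(p, seed = 5)
  expect_identical(a$series, b$series)
  c <- run_simulation(p, seed = 6)
  expect_false(identical(a$series, c$series))
})

test_that("bookkeeping balances exactly", {
  p <- small_abm_params()
  sim <- run_simulation(p, seed = 3)
  s <- sim$series
  # HSC divisions are conservative: one daughter stays, one is exported.
  expect_true(all(s$lt == 3360))
  expect_true(all(s$st == 3360))
  # Progenitors: initial + amplified exports - matured.
  ct <- sim$counters
  expect_equal(
    sim$final$n_progenitor,
    10000 + ct$prog_influx - ct$prog_efflux - ct$injury_removed
  )
  expect_equal(
    ct$prog_influx,
    p$progenitor_amplification * sum(unlist(ct$divisions))
  )
  # Cumulative division counts never decrease.
  expect_true(all(diff(s$divisions_lt) >= 0))
  expect_true(all(diff(s$divisions_st) >= 0))
})

test_that("zero horizon yields only the initial state", {
  p <- small_abm_params(horizon_days = 0)
  sim <- run_simulation(p, seed = 1)
  expect_equal(nrow(sim$series), 1)
  expect_error(divisions_per_year(sim), "horizon")
})

test_that("perturbation removes the requested progenitor fraction", {
  p <- abm_params(
    horizon_days = 4, injury_time_days = 2, injury_fraction = 0.01,
    hsc_pool_exit_rate = 0
  )
  sim <- run_simulation(p, seed = 2)
  expect_equal(sim$counters$injury_removed, 100)
  expect_equal(sim$series$progenitor[sim$series$time_hours == 54], 9900)

  wipe <- abm_params(
    horizon_days = 3, injury_time_days = 1, injury_fraction = 1
  )
  sim2 <- run_simulation(wipe, seed = 2)
  expect_equal(sim2$series$progenitor[sim2$series$time_hours == 30], 0)
})

test_that("replicate summaries are stochastic yet consistent", {
  p <- abm_params(horizon_days = 182)
  reps <- run_replicates(p, n_runs = 8, seed = 1)
  lt <- reps$runs[reps$runs$subtype == "LT", ]
  expect_equal(nrow(lt), 8)
  expect_gt(sd(lt$divisions_per_year), 0)
  expect_true(all(reps$series_summary$sd >= 0))

  # Ensemble means at 32 and 256 runs agree within 3 combined SEs.
  small <- run_replicates(p, n_runs = 32, seed = 2)
  big <- run_replicates(p, n_runs = 256, seed = 3)
  m1 <- small$runs$divisions_per_year[small$runs$subtype == "LT"]
  m2 <- big$runs$divisions_per_year[big$runs$subtype == "LT"]
  se <- sqrt(var(m1) / length(m1) + var(m2) / length(m2))
  expect_lt(abs(mean(m1) - mean(m2)), 3 * se)
})

test_that("a zero delay makes the two-parameter variants coincide", {
  p21 <- abm_params(hypothesis = "HYP2_1", horizon_days = 182)
  p22 <- abm_params(hypothesis = "HYP2_2", horizon_days = 182,
    lt_g0_exit_delay = 0)
  r21 <- run_replicates(p21, n_runs = 128, seed = 1)
  r22 <- run_replicates(p22, n_runs = 128, seed = 2)
  x <- r21$runs$divisions_per_year[r21$runs$subtype == "LT"]
  y <- r22$runs$divisions_per_year[r22$runs$subtype == "LT"]
  expect_gt(wilcox.test(x, y, exact = FALSE)$p.value, 0.01)
})

test_that("HYP1 reduces to HYP2.1 when the exit phase vanishes", {
  mk <- function(h) {
    # dt equals the (vanishing) exit mean here by design; the resolution
    # warning is expected.
    suppressWarnings(abm_params(
      hypothesis = h, horizon_days = 182,
      mean_g0_exit = c(LT = 0.5, ST = 0.5)
    ))
  }
  r1 <- run_replicates(mk("HYP1"), n_runs = 48, seed = 1)
  r2 <- run_replicates(mk("HYP2_1"), n_runs = 48, seed = 2)
  x <- r1$runs$divisions_per_year[r1$runs$subtype == "LT"]
  y <- r2$runs$divisions_per_year[r2$runs$subtype == "LT"]
  expect_gt(wilcox.test(x, y, exact = FALSE)$p.value, 0.01)
})

test_that("recovery time conventions hold", {
  p <- small_abm_params()
  sim <- run_simulation(p, seed = 1)
  expect_equal(recovery_time(sim)$recovery_hours, 0)

  pi <- abm_params(horizon_days = 6, injury_time_days = 2)
  simi <- run_simulation(pi, seed = 1)
  wide <- recovery_time(simi, "progenitor", tolerance = 1)
  expect_equal(wide$recovery_hours, 0)
  expect_false(wide$censored)
})

test_that("post-injury trajectories return toward the progenitor target", {
  p <- abm_params(horizon_days = 120, injury_time_days = 30)
  reps <- run_replicates(p, n_runs = 20, seed = 4)
  s <- reps$series_summary[reps$series_summary$series == "progenitor", ]
  dip <- min(s$mean[s$time_hours >= 720 & s$time_hours <= 780])
  late <- mean(s$mean[s$time_hours >= 2400])
  expect_lt(dip, late) # the ablation is visible and is recovered from
  expect_lt(abs(late - 10000) / 10000, 0.1)
})
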