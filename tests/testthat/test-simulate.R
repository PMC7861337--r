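test_that("trace generator is a pure function of its seed", {
  a <- simulate_fhr_trace(8, duration_s = 660, seed = 42)
  b <- simulate_fhr_trace(8, duration_s = 660, seed = 42)
  expect_identical(a$trace, b$trace)
  expect_identical(a$events, b$events)
  c <- simulate_fhr_trace(8, duration_s = 660, seed = 43)
  expect_false(isTRUE(all.equal(a$trace$bpm, c$trace$bpm)))
})

test_that("degenerate profile yields a constant trace at the intercept", {
  pr <- sim_profile(baseline_slope = 0, stv_ms_at_month6 = 0, stv_slope = 0,
                    accel_rate_per_min = setNames(rep(0, 4), 6:9),
                    decel_rate_per_min = setNames(rep(0, 4), 6:9))
  tr <- simulate_fhr_trace(7, pr, duration_s = 660, seed = 1)
  expect_true(all(tr$trace$bpm == pr$baseline_bpm_at_month6))
  expect_equal(nrow(tr$events), 0)
})

test_that("baseline trend and variability track the profile across months", {
  pr <- sim_profile()
  m6 <- simulate_fhr_trace(6, pr, 660, seed = 10)
  m9 <- simulate_fhr_trace(9, pr, 660, seed = 11)
  drop <- mean(m9$trace$bpm) - mean(m6$trace$bpm)
  expect_lt(abs(drop - 3 * pr$baseline_slope), 1.5)
  # epoch-level STV within 15% of target (event-free profile)
  pr0 <- sim_profile(accel_rate_per_min = setNames(rep(0, 4), 6:9),
                     decel_rate_per_min = setNames(rep(0, 4), 6:9))
  for (m in c(6, 9)) {
    tr <- simulate_fhr_trace(m, pr0, 660, seed = 20 + m)
    target <- pr0$stv_ms_at_month6 + pr0$stv_slope * (m - 6)
    got <- time_domain_features(tr$trace$bpm)$stv
    expect_lt(abs(got - target) / target, 0.15)
  }
})

test_that("planted events satisfy the Dawes detectability criteria", {
  for (s in 1:5) {
    tr <- simulate_fhr_trace(9, duration_s = 660, seed = s)
    if (nrow(tr$events) == 0) next
    expect_true(all(tr$events$end_s - tr$events$onset_s >= 15))
    expect_true(all(abs(tr$events$peak_dev_bpm) >= 15))
  }
})

test_that("growth-restriction lag evaluates the trajectory at earlier months", {
  pr <- sim_profile(stv_ms_at_month6 = 0, stv_slope = 0,
                    accel_rate_per_min = setNames(rep(0, 4), 6:9),
                    decel_rate_per_min = setNames(rep(0, 4), 6:9))
  # noise-free: LBW month 9 equals NBW at 9 - lag(9)
  lag9 <- pr$iugr_lag_months[["9"]]
  lbw <- simulate_fhr_trace(9, pr, 660, seed = 1, group = "LBW")
  expect_equal(lbw$effective_ga, 9 - lag9)
  nbw_base <- pr$baseline_bpm_at_month6 + pr$baseline_slope * (9 - lag9 - 6)
  expect_equal(mean(lbw$trace$bpm), nbw_base, tolerance = 1e-9)
})

test_that("Doppler envelope carries the FHR period, stated SNR and dropout", {
  fh <- rep(120, 2640)
  pr <- sim_profile(envelope_snr_db = Inf, dropout_fraction = 0)
  rec <- simulate_doppler_envelope(fh, pr, seed = 1, rate = 4000)
  w <- rec$samples[1:(3.75 * 4000)]
  env <- fetalga:::envelope_signal(w, 4000)
  pk <- fetalga:::autocorr_peak(env - mean(env), 4000)
  expect_equal(pk$lag_s, 0.5, tolerance = 0.01)
  # measured SNR within 1 dB of the profile value
  pr10 <- sim_profile(envelope_snr_db = 10, dropout_fraction = 0)
  rec10 <- simulate_doppler_envelope(fh, pr10, seed = 2, rate = 4000)
  clean <- attr(rec10, "clean")
  noise_sd <- attr(rec10, "noise_sd")
  snr <- 10 * log10(mean(clean^2) / noise_sd^2)
  expect_lt(abs(snr - 10), 1)
  # dropout fraction of 3.75-s blocks
  pr3 <- sim_profile(dropout_fraction = 0.3)
  rec3 <- simulate_doppler_envelope(fh, pr3, seed = 3, rate = 4000)
  expect_lt(abs(mean(!attr(rec3, "window_good")) - 0.3), 0.05)
})

test_that("blood-pressure draws rise with month and pass the arm screen", {
  pr <- sim_profile()
  s9 <- vapply(1:50, function(s) {
    mean(unlist(simulate_bp_reading(9, pr, seed = s)[c("sbp_left",
                                                       "sbp_right")]))
  }, numeric(1))
  s6 <- vapply(1:50, function(s) {
    mean(unlist(simulate_bp_reading(6, pr, seed = 100 + s)[c("sbp_left",
                                                             "sbp_right")]))
  }, numeric(1))
  expect_gt(mean(s9), mean(s6))
  for (s in 1:20) {
    expect_true(screen_bp(simulate_bp_reading(8, pr, seed = s))$included)
  }
  # zero slopes/jitter: both arms equal the intercepts
  pr0 <- sim_profile(sbp_slope = 0, dbp_slope = 0, mhr_slope = 0,
                     interarm_sd_mmhg = 0)
  bp <- simulate_bp_reading(9, pr0, seed = 1)
  expect_equal(bp$sbp_left, bp$sbp_right)
  expect_equal(bp$sbp_left, pr0$sbp_intercept)
  expect_equal(bp$dbp_left, pr0$dbp_intercept)
})

test_that("cohort honours LBW fraction, weight models and visit structure", {
  co <- simulate_cohort(100, lbw_fraction = 0.2, seed = 3, duration_s = 660)
  expect_equal(sum(co$newborns$lbw), 20)
  expect_identical(co$newborns$lbw, co$newborns$group == "LBW")
  # weight flag consistent with sex thresholds
  thr <- ifelse(co$newborns$sex == "male", 2.64, 2.57)
  expect_identical(co$newborns$birth_weight_kg < thr, co$newborns$lbw)
  # every recording longer than 10 min
  expect_true(all(vapply(co$visits$trace,
                         function(t) max(t$t_s) > 600, logical(1))))
  # NBW mean weight near 3.1 kg at n = 500
  co5 <- simulate_cohort(500, lbw_fraction = 0.16, seed = 4)
  w <- co5$newborns$birth_weight_kg[co5$newborns$group == "NBW"]
  expect_lt(abs(mean(w) - 3.1), 0.1)
  # different seeds differ
  co_b <- simulate_cohort(100, lbw_fraction = 0.2, seed = 5)
  expect_false(identical(co$newborns$birth_weight_kg,
                         co_b$newborns$birth_weight_kg))
})
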