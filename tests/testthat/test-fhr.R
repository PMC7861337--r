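test_that("window segmentation follows the 3.75 s / 0.25 s arithmetic", {
  rec <- doppler_recording(rep(0.1, 600 * 400), rate = 400)
  w <- segment_windows(rec)
  expect_equal(nrow(w), floor((600 - 3.75) / 0.25) + 1) # 2386
  expect_equal(w$onset_s[2] - w$onset_s[1], 0.25)
  # exactly one window at the boundary length
  one <- segment_windows(doppler_recording(rep(0.1, 3.75 * 400), 400))
  expect_equal(nrow(one), 1)
  expect_error(
    segment_windows(doppler_recording(rep(0.1, round(3.74 * 400)), 400)),
    "shorter"
  )
})

test_that("quality surrogate assigns the documented labels", {
  rate <- 4000
  n <- 3.75 * rate + 1
  expect_identical(classify_window_quality(rep(0, n), rate), "silence")
  t <- seq(0, 3.75, by = 1 / rate)
  expect_identical(classify_window_quality(sin(2 * pi * 60 * t), rate),
                   "interference")
  expect_identical(classify_window_quality(make_pulse_window(133), rate),
                   "good")
  set.seed(1)
  expect_identical(classify_window_quality(rnorm(n), rate), "low_snr")
})

test_that("autocorrelation FHR estimator recovers pulse-train rates", {
  expect_equal(estimate_fhr_window(make_pulse_window(120), 4000), 120,
               tolerance = 1 / 120)
  expect_equal(estimate_fhr_window(make_pulse_window(150), 4000), 150,
               tolerance = 1 / 150)
  set.seed(1)
  expect_true(is.na(estimate_fhr_window(rnorm(15001), 4000)))
})

test_that("good windows of synthetic envelopes estimate FHR accurately", {
  tr <- simulate_fhr_trace(8, duration_s = 660, seed = 5)
  for (snr in c(Inf, 10)) {
    pr <- sim_profile(envelope_snr_db = snr, dropout_fraction = 0)
    rec <- simulate_doppler_envelope(tr$trace$bpm, pr, seed = 2, rate = 4000)
    raw <- extract_fhr(rec)
    truth <- approx(tr$trace$t_s, tr$trace$bpm, xout = raw$t_s + 3.75 / 2,
                    rule = 2)$y
    err <- abs(raw$bpm[raw$valid] - truth[raw$valid])
    expect_gte(mean(err <= 5), 0.95)
    expect_lte(median(err), 2)
  }
})

test_that("cleaning applies the 65-175% rule with inclusive bounds", {
  raw <- raw_fhr(rep(140, 100))
  raw$bpm[50] <- 90 # 90/140 = 64.3% < 65% -> removed
  cl <- clean_fhr_series(raw)
  expect_identical(cl$provenance[50], "interpolated")
  expect_equal(cl$bpm[50], 140)
  raw$bpm[50] <- 91 # 65.0% exactly -> kept
  cl <- clean_fhr_series(raw)
  expect_identical(cl$provenance[50], "measured")
  expect_equal(cl$bpm[50], 91)
})

test_that("cleaning is identity on clean traces and idempotent on noisy ones", {
  cl <- clean_fhr_series(raw_fhr(rep(140, 100)))
  expect_equal(cl$bpm, rep(140, 100))
  expect_true(all(cl$provenance == "measured"))
  set.seed(2)
  x <- 140 + cumsum(rnorm(400, 0, 0.5))
  x[c(50, 200, 201, 320)] <- c(60, 230, 228, 75)
  c1 <- clean_fhr_series(raw_fhr(x))
  c2 <- clean_fhr_series(c1)
  expect_equal(c1$bpm, c2$bpm)
  # same length; interpolated fraction equals removed fraction
  expect_equal(nrow(c1), length(x))
  expect_equal(mean(c1$provenance == "interpolated"),
               1 - mean(c1$provenance == "measured"))
  expect_true(all(is.finite(c1$bpm)))
})

test_that("non-good windows are removed and interpolated", {
  raw <- raw_fhr(rep(140, 100))
  raw$bpm[30:35] <- 180          # plausible values but bad windows
  raw$label[30:35] <- "low_snr"
  raw$valid[30:35] <- FALSE
  cl <- clean_fhr_series(raw)
  expect_true(all(cl$provenance[30:35] == "interpolated"))
  expect_equal(cl$bpm[30:35], rep(140, 6))
})

test_that("cleaning errors when no stable segment exists", {
  set.seed(1)
  raw <- raw_fhr(140 + 40 * seq_len(30) %% 2 * rep(c(1, -1), 15))
  # alternating +-40 BPM: no 5-point run within 10 BPM
  expect_error(clean_fhr_series(raw), "no stable segment")
})

test_that("recording screen applies the strict >10 min and >=50% rules", {
  lab_good <- rep("good", 100)
  expect_false(screen_recording(594, lab_good)$included)   # 9.9 min
  expect_identical(screen_recording(594, lab_good)$reason, "duration")
  lab49 <- c(rep("good", 49), rep("low_snr", 51))
  s <- screen_recording(630, lab49)
  expect_false(s$included)
  expect_identical(s$reason, "quality")
  lab55 <- c(rep("good", 55), rep("silence", 45))
  expect_true(screen_recording(630, lab55)$included)
})

test_that("blood-pressure screen excludes arm mismatch and preeclampsia", {
  mk <- function(sl, sr, dl, dr) {
    tibble::tibble(sbp_left = sl, sbp_right = sr, dbp_left = dl,
                   dbp_right = dr, mhr_left = 80, mhr_right = 80)
  }
  s <- screen_bp(mk(120, 136, 70, 72))
  expect_false(s$included)
  expect_identical(s$reason, "arm difference")
  s <- screen_bp(mk(130, 132, 70, 72)) # mean SBP 131 > 130
  expect_false(s$included)
  expect_identical(s$reason, "possible preeclampsia")
  expect_true(screen_bp(mk(120, 118, 70, 72))$included)
})
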