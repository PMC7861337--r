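test_that("interbeat conversion is the exact 60000/S identity", {
  expect_equal(to_interbeat(150), 400)
  expect_equal(to_interbeat(120), 500)
  s <- c(60, 113.7, 240)
  expect_equal(60000 / to_interbeat(s), s)
  expect_error(to_interbeat(c(140, 0)), "positive")
})

test_that("epoch indexes follow the printed per-minute formulas", {
  # epochs alternate 400/410 ms: STV = |dT| = 10 everywhere, LTV = 10
  t_epochs <- rep(c(400, 410), 36)                 # 72 epochs = 3 min
  fhr <- rep(60000 / t_epochs, each = 10)          # constant within epoch
  f <- time_domain_features(fhr)
  expect_equal(f$stv, 10)
  expect_equal(f$ltv, 10)
  expect_equal(f$ii, 0)            # all |dT| equal -> sd 0
  # constant trace degenerate conventions
  f0 <- time_domain_features(rep(140, 720))
  expect_equal(f0$stv, 0)
  expect_equal(f0$ltv, 0)
  expect_equal(f0$pnn5, 0)
  expect_equal(f0$stv_ltv, 0)
  expect_equal(f0$basal_fhr, 140)
})

test_that("short-term variability is invariant to appending a copy", {
  set.seed(5)
  x <- 140 + as.numeric(arima.sim(list(ar = 0.5), 720))
  f1 <- time_domain_features(x)
  f2 <- time_domain_features(c(x, x))
  expect_equal(f1$stv, f2$stv, tolerance = 1e-12)
  expect_equal(f1$ltv, f2$ltv, tolerance = 1e-12)
})

test_that("non-linear panel honours degenerate and analytic cases", {
  f0 <- nonlinear_features(rep(400, 400))
  expect_equal(f0$apen, 0)
  expect_equal(f0$tone, 0)
  expect_equal(f0$entropy, 0)
  expect_equal(f0$lyapunov, 0)
  expect_equal(f0$gmi, 0)
  # each interval 1% shorter than the last -> tone = 1
  f1 <- nonlinear_features(500 * 0.99^(0:299))
  expect_equal(f1$tone, 1, tolerance = 1e-12)
  # regularity ordering: white noise more entropic than a sinusoid
  set.seed(2)
  noise <- 400 + 10 * rnorm(600)
  sine <- sin(2 * pi * (1:600) / 50)
  sine <- 400 + sine * 10 / sd(sine)
  expect_gt(nonlinear_features(noise)$apen, nonlinear_features(sine)$apen)
  expect_error(nonlinear_features(rep(400, 100)), "200 samples")
})

test_that("spectral band powers isolate tones in the printed bands", {
  t <- (0:1199) / 4
  s <- spectral_features(rep(140, 1200))
  expect_lte(s$lf + s$mf + s$hf, 1e-10)
  s1 <- spectral_features(140 + sin(2 * pi * 0.1 * t))
  expect_gte(s1$lf, 50 * (s1$mf + s1$hf))
  s3 <- spectral_features(140 + sin(2 * pi * 0.3 * t))
  expect_gte(s3$mf, 50 * (s3$lf + s3$hf))
  sh <- spectral_features(140 + sin(2 * pi * 0.7 * t))
  expect_gte(sh$hf, 50 * (sh$lf + sh$mf))
})

test_that("band powers are bounded by the series variance", {
  for (s in 1:5) {
    set.seed(s)
    x <- 140 + as.numeric(arima.sim(list(ar = 0.6), 2400))
    sp <- spectral_features(x)
    expect_lte(sp$lf + sp$mf + sp$hf, 1.05 * var(x))
  }
})

test_that("hemodynamic formulas match their printed definitions", {
  r <- tibble::tibble(sbp_left = 120, sbp_right = 122, dbp_left = 60,
                      dbp_right = 62, mhr_left = 78, mhr_right = 82)
  h <- hemodynamic_features(r)
  expect_equal(h$sbp, 121)
  expect_equal(h$dbp, 61)
  expect_equal(h$mhr, 80)
  expect_equal(h$pp, 60)
  expect_equal(h$map, 81)
  expect_equal(h$co, 9.6)
  expect_equal(h$rpp, 9680)
  expect_equal(h$si, 80 / 121)
  expect_equal(h$msi, 80 / 81)
  expect_equal(h$sv, 0.12)
  # SBP = DBP degenerate case
  r2 <- tibble::tibble(sbp_left = 100, sbp_right = 100, dbp_left = 100,
                       dbp_right = 100, mhr_left = 80, mhr_right = 80)
  h2 <- hemodynamic_features(r2)
  expect_equal(h2$pp, 0)
  expect_equal(h2$co, 0)
  expect_equal(h2$sv, 0)
})

test_that("full feature vector is complete, finite and deterministic", {
  tr <- simulate_fhr_trace(7, duration_s = 660, seed = 1)
  bp <- simulate_bp_reading(7, seed = 1)
  v1 <- build_feature_vector(tr$trace$bpm, bp)
  v2 <- build_feature_vector(tr$trace$bpm, bp)
  expect_identical(names(v1), feature_names())
  expect_equal(ncol(v1), 37)
  expect_true(all(vapply(v1, is.finite, logical(1))))
  expect_identical(v1, v2)
  # variance consistency
  expect_equal(v1$var_is, v1$std_is^2, tolerance = 1e-12)
  expect_equal(v1$stv_ltv, v1$stv / v1$ltv, tolerance = 1e-12)
})
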