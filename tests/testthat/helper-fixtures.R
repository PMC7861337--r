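# shared fixtures, built once per test run

# default-condition cohort with features (used by the model/proxy suites)
cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(n_patients = 150, seed = 1)
      ft <- cohort_features(co)
      cache <<- list(cohort = co, features = ft)
    }
    cache
  }
})

# reduced SVR grid reaching the printed C/epsilon ranges at coarser steps
test_grid_svr <- function() {
  list(cost = 2^seq(-1, 7, by = 2), epsilon = 2^c(-8, -6, -5))
}

# synthetic Doppler-like pulse train, period 60/bpm seconds
make_pulse_window <- function(bpm, rate = 4000, dur = 3.75) {
  t <- seq(0, dur, by = 1 / rate)
  p <- numeric(length(t))
  for (b in seq(0.1, dur, by = 60 / bpm)) {
    p <- p + exp(-((t - b) / 0.01)^2)
  }
  p
}

# raw FHR tibble wrapper
raw_fhr <- function(bpm, label = "good") {
  tibble::tibble(t_s = (seq_along(bpm) - 1) / 4, bpm = bpm,
                 valid = TRUE, label = label)
}
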