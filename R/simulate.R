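#' Simulation profile for the synthetic cohort generator
#'
#' Bundles the gestational-age (GA) trends the generator emulates: the
#' fetal heart-rate (FHR) baseline declines with advancing gestation
#' (roughly 15 BPM across the last trimester), short-term variability and
#' the acceleration rate increase as the autonomic system matures, and
#' maternal blood pressure rises through pregnancy. Growth-restricted
#' (low-birth-weight, LBW) fetuses are modelled with a maturation lag: at
#' month `m` their GA-dependent parameters are evaluated at
#' `m - iugr_lag_months[m]`.
#'
#' @param baseline_bpm_at_month6 FHR baseline at gestational month 6 (BPM).
#' @param baseline_slope Baseline change per gestational month (BPM/month,
#'   negative).
#' @param baseline_sd_bpm Between-subject SD of the baseline (BPM).
#' @param stv_ms_at_month6 Target epoch-scale short-term variability at
#'   month 6 (ms of interbeat change per 2.5-s epoch).
#' @param stv_slope STV change per month (ms/month, positive).
#' @param stv_sd_ms Between-subject SD of the STV target (ms).
#' @param ar1_phi AR(1) coefficient of the epoch-scale interbeat noise.
#' @param accel_rate_per_min,decel_rate_per_min Named numeric vectors
#'   (months "6".."9") of expected event counts per minute; the
#'   acceleration rate is non-decreasing in month.
#' @param sbp_intercept,sbp_slope,dbp_intercept,dbp_slope,mhr_intercept,mhr_slope
#'   Maternal systolic/diastolic pressure (mmHg) and heart rate (BPM) at
#'   month 6 and their per-month slopes.
#' @param bp_sd_mmhg,mhr_sd_bpm Between-subject SDs of the blood-pressure
#'   intercepts and maternal heart rate.
#' @param interarm_sd_mmhg SD of the left/right arm jitter (kept well below
#'   the 15-mmHg inclusion screen).
#' @param envelope_snr_db Signal-to-noise ratio of the synthetic Doppler
#'   envelope (dB).
#' @param dropout_fraction Fraction of 3.75-s windows rendered non-good
#'   (silence/noise), in `[0, 0.5)`.
#' @param iugr_lag_months Named numeric vector (months "6".."9") of the
#'   maturation lag applied to the LBW group, non-decreasing and >= 0.
#' @return An object of class `sim_profile` (a named list).
#' @export
sim_profile <- function(baseline_bpm_at_month6 = 143,
                        baseline_slope = -4.4,
                        baseline_sd_bpm = 5,
                        stv_ms_at_month6 = 5,
                        stv_slope = 1.0,
                        stv_sd_ms = 0.8,
                        ar1_phi = 0.5,
                        accel_rate_per_min = c("6" = 0.10, "7" = 0.15,
                                               "8" = 0.20, "9" = 0.25),
                        decel_rate_per_min = c("6" = 0.02, "7" = 0.02,
                                               "8" = 0.03, "9" = 0.03),
                        sbp_intercept = 103, sbp_slope = 2.0,
                        dbp_intercept = 64, dbp_slope = 1.5,
                        mhr_intercept = 82, mhr_slope = 2.0,
                        bp_sd_mmhg = 6, mhr_sd_bpm = 6,
                        interarm_sd_mmhg = 2,
                        envelope_snr_db = 10,
                        dropout_fraction = 0.1,
                        iugr_lag_months = c("6" = 0, "7" = 0.5,
                                            "8" = 1.0, "9" = 1.5)) {
  p <- list(baseline_bpm_at_month6 = baseline_bpm_at_month6,
            baseline_slope = baseline_slope,
            baseline_sd_bpm = baseline_sd_bpm,
            stv_ms_at_month6 = stv_ms_at_month6,
            stv_slope = stv_slope, stv_sd_ms = stv_sd_ms,
            ar1_phi = ar1_phi,
            accel_rate_per_min = accel_rate_per_min,
            decel_rate_per_min = decel_rate_per_min,
            sbp_intercept = sbp_intercept, sbp_slope = sbp_slope,
            dbp_intercept = dbp_intercept, dbp_slope = dbp_slope,
            mhr_intercept = mhr_intercept, mhr_slope = mhr_slope,
            bp_sd_mmhg = bp_sd_mmhg, mhr_sd_bpm = mhr_sd_bpm,
            interarm_sd_mmhg = interarm_sd_mmhg,
            envelope_snr_db = envelope_snr_db,
            dropout_fraction = dropout_fraction,
            iugr_lag_months = iugr_lag_months)
  class(p) <- "sim_profile"
  base_range <- baseline_bpm_at_month6 + baseline_slope * (0:3)
  if (any(base_range < 110 | base_range > 160)) {
    stop("sim_profile: baseline leaves the physiologic 110-160 BPM band ",
         "over months 6-9", call. = FALSE)
  }
  if (dropout_fraction < 0 || dropout_fraction >= 0.5) {
    stop("sim_profile: dropout_fraction must be in [0, 0.5)", call. = FALSE)
  }
  if (any(iugr_lag_months < 0) || is.unsorted(iugr_lag_months)) {
    stop("sim_profile: iugr_lag_months must be non-negative and ",
         "non-decreasing", call. = FALSE)
  }
  p
}

#' Effective gestational month after the growth-restriction lag
#' @noRd
effective_ga <- function(ga_months, profile, group) {
  if (identical(group, "LBW")) {
    ga_months - unname(profile$iugr_lag_months[as.character(ga_months)])
  } else {
    ga_months
  }
}

#' Simulate a 4-Hz fetal heart-rate trace with ground truth
#'
#' Generates a trace as baseline + epoch-scale AR(1) interbeat noise +
#' planted trapezoidal accelerations/decelerations. Epoch-scale noise is
#' calibrated so that the expected short-term variability (mean absolute
#' interbeat change between consecutive 2.5-s epochs) matches the profile
#' target at the (lag-adjusted) gestational month. Planted events satisfy
#' the Dawes criteria (>= 15 s, >= 15 BPM peak deviation).
#'
#' @param ga_months Gestational month, 6..9.
#' @param profile A [sim_profile()].
#' @param duration_s Trace duration in seconds (>= 630 so that >10-min
#'   recordings are producible; default 660).
#' @param seed Integer seed.
#' @param group `"NBW"` or `"LBW"`; the LBW group is generated at the
#'   lag-adjusted month.
#' @param baseline_offset_bpm,stv_offset_ms Subject-level offsets (used by
#'   [simulate_cohort()]; default 0).
#' @return A list with `trace` (tibble `t_s`, `bpm`), `events` (tibble
#'   `type`, `onset_s`, `end_s`, `peak_dev_bpm`), `baseline_bpm`,
#'   `ga_months`, `effective_ga`, `group`.
#' @export
simulate_fhr_trace <- function(ga_months, profile = sim_profile(),
                               duration_s = 660, seed = 1, group = "NBW",
                               baseline_offset_bpm = 0, stv_offset_ms = 0) {
  stopifnot(ga_months %in% 6:9, duration_s >= 630)
  set.seed(seed)
  eff <- effective_ga(ga_months, profile, group)
  baseline <- profile$baseline_bpm_at_month6 +
    profile$baseline_slope * (eff - 6) + baseline_offset_bpm
  if (baseline < 110 || baseline > 160) {
    stop("simulate_fhr_trace: baseline ", round(baseline, 1),
         " BPM outside 110-160", call. = FALSE)
  }
  fs <- 4
  n <- round(duration_s * fs)
  n_epochs <- ceiling(n / 10)          # 2.5-s epochs = 10 samples at 4 Hz
  stv_target <- max(0, profile$stv_ms_at_month6 +
                      profile$stv_slope * (eff - 6) + stv_offset_ms)
  phi <- profile$ar1_phi
  # Stationary AR(1) with variance s^2 has E|diff| = sqrt(2/pi)*s*sqrt(2(1-phi))
  s_eps <- if (stv_target > 0) {
    stv_target / (sqrt(2 / pi) * sqrt(2 * (1 - phi)))
  } else 0
  t_base_ms <- 60000 / baseline
  e <- numeric(n_epochs)
  if (s_eps > 0) {
    innov <- rnorm(n_epochs, 0, s_eps * sqrt(1 - phi^2))
    e[1] <- rnorm(1, 0, s_eps)
    for (k in 2:n_epochs) e[k] <- phi * e[k - 1] + innov[k]
  }
  t_ms <- rep(t_base_ms + e, each = 10)[seq_len(n)]
  s_bpm <- 60000 / t_ms

  # plant events: trapezoids with Dawes-compliant duration and peak
  minutes <- duration_s / 60
  ev <- list()
  plant <- function(type, rate) {
    n_ev <- rpois(1, rate * minutes)
    if (n_ev == 0) return(NULL)
    out <- vector("list", n_ev)
    for (i in seq_len(n_ev)) {
      dur <- runif(1, 20, 45)
      onset <- runif(1, 5, duration_s - dur - 5)
      peak <- runif(1, 17, 25) * if (type == "acceleration") 1 else -1
      out[[i]] <- tibble(type = type, onset_s = onset,
                         end_s = onset + dur, peak_dev_bpm = peak)
    }
    dplyr::bind_rows(out)
  }
  acc <- plant("acceleration",
               unname(profile$accel_rate_per_min[as.character(ga_months)]))
  dec <- plant("deceleration",
               unname(profile$decel_rate_per_min[as.character(ga_months)]))
  events <- dplyr::bind_rows(acc, dec)
  if (nrow(events) > 0) {
    # drop overlapping events (keep earlier onset) so runs stay maximal
    events <- dplyr::arrange(events, .data$onset_s)
    keep <- rep(TRUE, nrow(events))
    last_end <- -Inf
    for (i in seq_len(nrow(events))) {
      if (events$onset_s[i] <= last_end + 2) keep[i] <- FALSE
      else last_end <- events$end_s[i]
    }
    events <- events[keep, ]
    t_s <- (seq_len(n) - 1) / fs
    for (i in seq_len(nrow(events))) {
      o <- events$onset_s[i]; e2 <- events$end_s[i]
      pk <- events$peak_dev_bpm[i]
      ramp <- min(3, (e2 - o) / 5)
      shape <- pmin(1, pmax(0, pmin((t_s - o) / ramp, (e2 - t_s) / ramp)))
      s_bpm <- s_bpm + pk * shape
    }
  } else {
    events <- tibble(type = character(0), onset_s = numeric(0),
                     end_s = numeric(0), peak_dev_bpm = numeric(0))
  }
  s_bpm <- pmax(60, pmin(240, s_bpm))
  list(trace = tibble(t_s = (seq_len(n) - 1) / fs, bpm = s_bpm),
       events = events, baseline_bpm = baseline,
       ga_months = ga_months, effective_ga = eff, group = group)
}

#' Render a Doppler-like audio envelope from an FHR trace
#'
#' Produces an amplitude-modulated pulse train whose local fundamental
#' period is `60/FHR` seconds: beat times are obtained by integrating the
#' instantaneous rate, each beat contributes a raised-cosine burst of a
#' 500-Hz carrier, white noise is added at `envelope_snr_db`, and a
#' `dropout_fraction` of non-overlapping 3.75-s blocks is replaced by
#' silence or noise (ground-truth labels are attached).
#'
#' @param fhr_bpm Numeric vector, FHR at 4 Hz (values in 60..240).
#' @param profile A [sim_profile()] (uses `envelope_snr_db`,
#'   `dropout_fraction`).
#' @param seed Integer seed.
#' @param rate Audio sampling rate in Hz. 44100 is the canonical field
#'   value; lower rates give the same envelope structure cheaply.
#' @return A [doppler_recording()] with attributes `window_good` (logical
#'   per 3.75-s block) and `clean` (the noise-free signal, for SNR checks).
#' @export
simulate_doppler_envelope <- function(fhr_bpm, profile = sim_profile(),
                                      seed = 1, rate = 4000) {
  stopifnot(all(fhr_bpm >= 60 & fhr_bpm <= 240))
  set.seed(seed)
  fs_fhr <- 4
  duration_s <- length(fhr_bpm) / fs_fhr
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  # instantaneous rate (beats/s) -> cumulative phase -> beat times
  inst <- approx(x = (seq_along(fhr_bpm) - 1) / fs_fhr, y = fhr_bpm / 60,
                 xout = t, rule = 2)$y
  phase <- cumsum(inst) / rate
  beats <- which(diff(floor(phase)) == 1)
  x <- numeric(n)
  half <- round(0.05 * rate) # 100-ms raised-cosine burst
  burst_t <- seq(-half, half)
  win <- 0.5 * (1 + cos(pi * burst_t / half))
  carrier <- sin(2 * pi * 500 * burst_t / rate)
  amp <- 0.8 + 0.2 * runif(length(beats))
  for (b in seq_along(beats)) {
    idx <- beats[b] + burst_t
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + amp[b] * (win * carrier)[ok]
  }
  p_sig <- mean(x^2)
  snr <- profile$envelope_snr_db
  noise_sd <- if (is.finite(snr)) sqrt(p_sig / 10^(snr / 10)) else 0
  clean <- x
  x <- x + rnorm(n, 0, noise_sd)
  # dropout: non-overlapping 3.75-s blocks turned into silence or noise
  block <- round(3.75 * rate)
  n_blocks <- floor(n / block)
  good <- rep(TRUE, n_blocks)
  n_drop <- round(profile$dropout_fraction * n_blocks)
  if (n_drop > 0) {
    drop <- sample.int(n_blocks, n_drop)
    good[drop] <- FALSE
    for (b in drop) {
      idx <- ((b - 1) * block + 1):(b * block)
      if (runif(1) < 0.5) {
        x[idx] <- rnorm(block, 0, 1e-6)        # silence
        clean[idx] <- 0
      } else {
        x[idx] <- rnorm(block, 0, sqrt(p_sig) * 2) # noise burst
        clean[idx] <- 0
      }
    }
  }
  rec <- doppler_recording(x / max(1, max(abs(x))) * 0.95, rate)
  attr(rec, "window_good") <- good
  attr(rec, "clean") <- clean
  attr(rec, "noise_sd") <- noise_sd
  rec
}

#' Simulate a maternal blood-pressure reading
#'
#' Both arms are drawn around a GA-dependent trend with small inter-arm
#' jitter, so generated readings pass the 15-mmHg arm-difference screen.
#'
#' @param ga_months Gestational month, 6..9.
#' @param profile A [sim_profile()].
#' @param seed Integer seed.
#' @param sbp_offset,dbp_offset,mhr_offset Subject-level offsets.
#' @return Tibble with columns `sbp_left`, `sbp_right`, `dbp_left`,
#'   `dbp_right`, `mhr_left`, `mhr_right`.
#' @export
simulate_bp_reading <- function(ga_months, profile = sim_profile(), seed = 1,
                                sbp_offset = 0, dbp_offset = 0,
                                mhr_offset = 0) {
  stopifnot(ga_months %in% 6:9)
  set.seed(seed)
  d <- ga_months - 6
  dbp <- profile$dbp_intercept + profile$dbp_slope * d + dbp_offset
  pp <- (profile$sbp_intercept - profile$dbp_intercept) +
    (profile$sbp_slope - profile$dbp_slope) * d + (sbp_offset - dbp_offset)
  sbp <- dbp + max(pp, 10)
  mhr <- profile$mhr_intercept + profile$mhr_slope * d + mhr_offset
  jit <- function() {
    j <- rnorm(1, 0, profile$interarm_sd_mmhg)
    max(-7, min(7, j))
  }
  tibble(sbp_left = sbp + jit(), sbp_right = sbp + jit(),
         dbp_left = dbp + jit(), dbp_right = dbp + jit(),
         mhr_left = mhr + jit(), mhr_right = mhr + jit())
}

#' Simulate a full prenatal cohort with ground truth
#'
#' Draws patients with subject-level random effects, assigns them to the
#' NBW or LBW group, gives most patients one visit (90% one, 9% two, 1%
#' three) at months skewed toward late gestation, and generates per-visit
#' FHR traces and blood-pressure readings. Birth weights are drawn from
#' Normal(3.1, 0.3) kg for the NBW group and Normal(2.3, 0.4) kg for the
#' LBW group, truncated at 0.5 kg and at the sex-specific LBW threshold so
#' the group label and the weight flag agree.
#'
#' @param n_patients Number of patients (>= 10).
#' @param lbw_fraction Fraction of LBW patients, in (0, 0.5).
#' @param profile A [sim_profile()].
#' @param seed Integer seed.
#' @param duration_s Per-recording duration in seconds (> 600).
#' @return A list with `visits` (tibble; one row per visit with id columns,
#'   `ga_months`, `group`, BP columns and a `trace`/`events` list-column)
#'   and `newborns` (tibble `patient_id`, `sex`, `birth_weight_kg`, `lbw`,
#'   `group`).
#' @export
simulate_cohort <- function(n_patients = 150, lbw_fraction = 24 / 153,
                            profile = sim_profile(), seed = 1,
                            duration_s = 660) {
  stopifnot(n_patients >= 10, lbw_fraction > 0, lbw_fraction < 0.5)
  set.seed(seed)
  n_lbw <- round(n_patients * lbw_fraction)
  group <- c(rep("LBW", n_lbw), rep("NBW", n_patients - n_lbw))
  sex <- sample(c("male", "female"), n_patients, replace = TRUE)
  thr <- ifelse(sex == "male", 2.64, 2.57)
  draw_weight <- function(g, th) {
    mu <- if (g == "LBW") 2.3 else 3.1
    s <- if (g == "LBW") 0.4 else 0.3
    repeat {
      w <- rnorm(1, mu, s)
      if (w < 0.5) next
      if (g == "LBW" && w < th) return(w)
      if (g == "NBW" && w >= th) return(w)
    }
  }
  weight <- unname(mapply(draw_weight, group, thr))
  newborns <- tibble(patient_id = sprintf("P%03d", seq_len(n_patients)),
                     sex = sex, birth_weight_kg = weight,
                     lbw = group == "LBW", group = group)
  # subject-level random effects
  # subject baseline offsets are rejection-sampled so every visit's
  # baseline stays inside the physiologic 110-160 BPM band
  b_lo <- 110 - (profile$baseline_bpm_at_month6 + 3 * profile$baseline_slope)
  b_hi <- 160 - profile$baseline_bpm_at_month6
  draw_offset <- function() {
    repeat {
      o <- rnorm(1, 0, profile$baseline_sd_bpm)
      if (o > b_lo + 1 && o < b_hi - 1) return(o)
    }
  }
  re <- tibble(
    patient_id = newborns$patient_id,
    baseline_offset = vapply(seq_len(n_patients), function(i) draw_offset(),
                             numeric(1)),
    stv_offset = rnorm(n_patients, 0, profile$stv_sd_ms),
    sbp_offset = rnorm(n_patients, 0, profile$bp_sd_mmhg),
    dbp_offset = rnorm(n_patients, 0, profile$bp_sd_mmhg * 0.8),
    mhr_offset = rnorm(n_patients, 0, profile$mhr_sd_bpm)
  )
  n_visits <- sample(1:3, n_patients, replace = TRUE,
                     prob = c(0.90, 0.09, 0.01))
  month_probs <- c("6" = 0.05, "7" = 0.25, "8" = 0.28, "9" = 0.42)
  sub_seeds <- sample.int(2^31 - 2, n_patients * 3 * 2)
  rows <- list()
  k <- 0
  for (i in seq_len(n_patients)) {
    months <- sort(sample(6:9, n_visits[i], replace = FALSE,
                          prob = month_probs))
    for (v in seq_along(months)) {
      k <- k + 1
      s1 <- sub_seeds[2 * k - 1]
      s2 <- sub_seeds[2 * k]
      tr <- simulate_fhr_trace(months[v], profile, duration_s, seed = s1,
                               group = group[i],
                               baseline_offset_bpm = re$baseline_offset[i],
                               stv_offset_ms = re$stv_offset[i])
      bp <- simulate_bp_reading(months[v], profile, seed = s2,
                                sbp_offset = re$sbp_offset[i],
                                dbp_offset = re$dbp_offset[i],
                                mhr_offset = re$mhr_offset[i])
      rows[[k]] <- dplyr::bind_cols(
        tibble(patient_id = newborns$patient_id[i],
               visit_id = sprintf("%s-V%d", newborns$patient_id[i], v),
               ga_months = months[v], group = group[i]),
        bp,
        tibble(trace = list(tr$trace), events = list(tr$events),
               baseline_bpm = tr$baseline_bpm, effective_ga = tr$effective_ga)
      )
    }
  }
  list(visits = dplyr::bind_rows(rows), newborns = newborns)
}
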