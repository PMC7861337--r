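#' Convert an FHR series to an interbeat sequence
#'
#' `T(i) = 60000 / S(i)` with `S` the FHR in BPM, giving interbeat
#' intervals in ms (250-1000 ms for 60-240 BPM).
#'
#' @param fhr_bpm Gap-free FHR vector in BPM, all positive.
#' @return Numeric vector of interbeat intervals (ms).
#' @export
to_interbeat <- function(fhr_bpm) {
  if (any(fhr_bpm <= 0)) {
    stop("to_interbeat: FHR must be positive", call. = FALSE)
  }
  60000 / fhr_bpm
}

# 2.5-s epoch means (10 samples at 4 Hz); complete epochs only
epoch_means <- function(x, fs = 4, epoch_s = 2.5) {
  k <- round(epoch_s * fs)
  n_ep <- floor(length(x) / k)
  colMeans(matrix(x[seq_len(n_ep * k)], nrow = k))
}

#' Linear time-domain features of the interbeat sequence
#'
#' Per-minute epoch indexes (short-term variability, interval index,
#' long-term variability) computed on 24 2.5-s epochs per minute and
#' averaged across minutes; long-term irregularity as the mean over 3-min
#' segments of the interquartile range of
#' `sqrt(T(i)^2 + T(i-1)^2)`; plus whole-trace moments of the interbeat
#' sequence, the fraction of successive differences above 5 ms, the basal
#' FHR (mode outside events), the acceleration rate, and the PRSA
#' capacities.
#'
#' @param fhr_bpm Gap-free 4-Hz FHR vector (>= 3 whole minutes).
#' @param events Event tibble from [detect_events()] (may be empty).
#' @param fs Sampling rate (Hz).
#' @return One-row tibble with the 17 linear features.
#' @export
time_domain_features <- function(fhr_bpm, events = NULL, fs = 4) {
  n_min <- floor(length(fhr_bpm) / (60 * fs))
  if (n_min < 3) {
    stop("time_domain_features: need at least 3 whole minutes", call. = FALSE)
  }
  tib <- to_interbeat(fhr_bpm)
  spm <- 60 * fs
  per_min <- lapply(seq_len(n_min), function(j) {
    ep <- epoch_means(tib[((j - 1) * spm + 1):(j * spm)], fs)
    adiff <- abs(diff(ep))                      # |T_j(i) - T_j(i-1)|, i=2..24
    stv_j <- mean(adiff)
    list(stv = stv_j,
         ii = if (stv_j > 0) sd(adiff) / stv_j else 0,
         ltv = max(ep) - min(ep))
  })
  stv <- mean(vapply(per_min, `[[`, numeric(1), "stv"))
  ii <- mean(vapply(per_min, `[[`, numeric(1), "ii"))
  ltv <- mean(vapply(per_min, `[[`, numeric(1), "ltv"))
  # LTI over 3-min segments (72 epochs each)
  n_seg <- floor(n_min / 3)
  lti <- if (n_seg > 0) {
    mean(vapply(seq_len(n_seg), function(k) {
      ep <- epoch_means(tib[((k - 1) * 3 * spm + 1):(k * 3 * spm)], fs)
      m <- sqrt(ep[-1]^2 + ep[-length(ep)]^2)   # i = 2..72
      stats::IQR(m)
    }, numeric(1)))
  } else NA_real_
  if (is.null(events)) {
    events <- tibble(type = character(0), onset_s = numeric(0),
                     end_s = numeric(0))
  }
  # basal FHR: mode of integer-rounded BPM outside events, ties to median
  t_s <- (seq_along(fhr_bpm) - 1) / fs
  in_event <- rep(FALSE, length(fhr_bpm))
  for (i in seq_len(nrow(events))) {
    in_event <- in_event | (t_s >= events$onset_s[i] & t_s <= events$end_s[i])
  }
  base_samples <- round(fhr_bpm[!in_event])
  if (length(base_samples) == 0) base_samples <- round(fhr_bpm)
  tab <- table(base_samples)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  basal <- modes[which.min(abs(modes - median(base_samples)))]
  minutes <- length(fhr_bpm) / spm
  d <- diff(tib)
  m2 <- mean((tib - mean(tib))^2)
  m3 <- mean((tib - mean(tib))^3)
  m4 <- mean((tib - mean(tib))^4)
  tibble(
    stv = stv, ii = ii, ltv = ltv, lti = lti,
    stv_ltv = if (ltv > 0) stv / ltv else 0,
    basal_fhr = basal,
    acc_per_min = sum(events$type == "acceleration") / minutes,
    aac = prsa_capacity(fhr_bpm, "accel"),
    dac = prsa_capacity(fhr_bpm, "decel"),
    m_is = mean(tib), std_is = sd(tib), var_is = sd(tib)^2,
    rmssd_is = sqrt(mean(d^2)),
    std_rmssd_ratio = if (sqrt(mean(d^2)) > 0) {
      sd(tib) / sqrt(mean(d^2))
    } else 0,
    skewness_is = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis_is = if (m2 > 0) m4 / m2^2 - 3 else 0,
    pnn5 = mean(abs(d) > 5)
  )
}

# Higuchi fractal dimension with maximum interval k_max
higuchi_fd <- function(x, k_max = 5) {
  n <- length(x)
  lk <- vapply(seq_len(k_max), function(k) {
    lm <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      sum(abs(diff(x[idx]))) * (n - 1) / (floor((n - m) / k) * k) / k
    }, numeric(1))
    mean(lm, na.rm = TRUE)
  }, numeric(1))
  if (any(lk <= 0)) return(0)
  slope <- stats::lm.fit(cbind(1, log(seq_len(k_max))),
                         log(lk))$coefficients[2]
  if (is.finite(slope)) -unname(slope) else 0
}

# largest Lyapunov exponent, Rosenstein's method (per-sample units)
rosenstein_lyapunov <- function(x, dim = 1, lag = 2, theiler = 10,
                                fit_steps = 10) {
  if (sd(x) == 0) return(0)
  nn <- nn_index_cpp(x, dim, lag, theiler)
  div <- rosenstein_divergence_cpp(x, nn, fit_steps)
  ok <- is.finite(div)
  if (sum(ok) < 2) return(0)
  steps <- seq_len(fit_steps)[ok]
  unname(stats::lm.fit(cbind(1, steps), div[ok])$coefficients[2])
}

# histogram mutual information with equiprobable bins (bits)
hist_mi <- function(x, y, bins = 16) {
  qx <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  qy <- unique(quantile(y, probs = seq(0, 1, length.out = bins + 1)))
  if (length(qx) < 3 || length(qy) < 3) return(0)
  cx <- cut(x, qx, include.lowest = TRUE)
  cy <- cut(y, qy, include.lowest = TRUE)
  j <- table(cx, cy) / length(x)
  px <- rowSums(j); py <- colSums(j)
  nz <- j > 0
  sum(j[nz] * log2(j[nz] / outer(px, py)[nz]))
}

#' Non-linear and complexity features of the interbeat sequence
#'
#' Approximate entropy (m = 2, r = 0.1 SD), Higuchi fractal dimension
#' (k_max = 5), largest Lyapunov exponent (Rosenstein, embedding dimension
#' 1, lag 2), tone and entropy of the percentage differences of successive
#' beat intervals, and a generalized mutual information between the series
#' and its delay-1 copy (embedding dimension 3; histogram estimator with 16
#' equiprobable bins, averaged over the embedding coordinates, which for a
#' stationary series collapses to the lag-1 mutual information).
#'
#' Degenerate (constant) series return 0 for ApEn, the Lyapunov exponent,
#' entropy, GMI and tone.
#'
#' @param interbeat_ms Interbeat sequence in ms (length >= 200).
#' @param tone_binwidth,tone_range Histogram parameters for the
#'   percentage-difference distribution (percentage points).
#' @return One-row tibble with the 6 non-linear features.
#' @export
nonlinear_features <- function(interbeat_ms, tone_binwidth = 0.5,
                               tone_range = 20) {
  x <- as.numeric(interbeat_ms)
  if (length(x) < 200) {
    stop("nonlinear_features: need at least 200 samples", call. = FALSE)
  }
  s <- sd(x)
  apen <- apen_cpp(x, 2L, 0.1 * s)
  # percentage difference of successive beat intervals
  p <- 100 * (x[-length(x)] - x[-1]) / x[-length(x)]
  pc <- pmax(-tone_range, pmin(tone_range, p))
  breaks <- seq(-tone_range, tone_range, by = tone_binwidth)
  cnt <- tabulate(findInterval(pc, breaks, all.inside = TRUE),
                  nbins = length(breaks) - 1)
  pr <- cnt / sum(cnt)
  pr <- pr[pr > 0]
  entropy <- if (length(pr) > 1) -sum(pr * log2(pr)) else 0
  tibble(
    apen = apen,
    fractal_dim = higuchi_fd(x, 5),
    lyapunov = rosenstein_lyapunov(x, dim = 1, lag = 2),
    tone = mean(p),
    entropy = entropy,
    gmi = if (s > 0) hist_mi(x[-length(x)], x[-1]) else 0
  )
}

# Welch power spectral density (one-sided), Hann window
welch_psd <- function(x, fs, seg_len = 256, overlap = 0.5) {
  x <- x - mean(x)
  n <- length(x)
  seg_len <- min(seg_len, n)
  hop <- max(1, round(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)))
  u <- sum(w^2)
  acc <- numeric(seg_len)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)] * w
    acc <- acc + Mod(fft(seg))^2
  }
  psd <- acc / (length(starts) * fs * u)
  half <- seq_len(floor(seg_len / 2) + 1)
  psd <- psd[half]
  psd[c(-1, -length(psd))] <- 2 * psd[c(-1, -length(psd))]
  list(freq = (half - 1) * fs / seg_len, psd = psd)
}

# trapezoidal band power with interpolation at the exact band edges
band_power <- function(freq, psd, lo, hi) {
  f <- c(lo, freq[freq > lo & freq < hi], hi)
  p <- approx(freq, psd, xout = f, rule = 2)$y
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Spectral band powers of the FHR trace
#'
#' Welch periodogram (Hann window, 256-sample/64-s segments, 50% overlap)
#' of the mean-removed 4-Hz FHR, integrated over the low (0.03-0.15 Hz),
#' medium (0.15-0.5 Hz) and high (0.5-1 Hz) bands.
#'
#' @param fhr_bpm Gap-free 4-Hz FHR vector (>= 5 min).
#' @param fs Sampling rate (Hz).
#' @return One-row tibble `lf`, `mf`, `hf`, `lf_mf_hf_ratio`.
#' @export
spectral_features <- function(fhr_bpm, fs = 4) {
  if (length(fhr_bpm) < 5 * 60 * fs) {
    stop("spectral_features: need at least 5 min of data", call. = FALSE)
  }
  sp <- welch_psd(fhr_bpm, fs)
  lf <- band_power(sp$freq, sp$psd, 0.03, 0.15)
  mf <- band_power(sp$freq, sp$psd, 0.15, 0.50)
  hf <- band_power(sp$freq, sp$psd, 0.50, 1.00)
  tibble(lf = lf, mf = mf, hf = hf,
         lf_mf_hf_ratio = if (mf + hf > 0) lf / (mf + hf) else 0)
}

#' Maternal hemodynamic features from a blood-pressure reading
#'
#' Arm-averaged systolic/diastolic pressure and heart rate, and the
#' derived quantities: pulse pressure `PP = SBP - DBP`, mean arterial
#' pressure `MAP = (SBP + 2 DBP)/3`, cardiac output `CO = MHR x PP x
#' 0.002`, rate-pressure product `RPP = MHR x SBP`, shock index
#' `SI = MHR/SBP`, modified shock index `MSI = MHR/MAP` and stroke volume
#' `SV = CO/MHR` (identically `0.002 PP`).
#'
#' @param reading One-row data frame with both-arm SBP/DBP/MHR columns.
#' @return One-row tibble with the 10 hemodynamic features.
#' @export
hemodynamic_features <- function(reading) {
  r <- as.list(reading)
  sbp <- mean(c(r$sbp_left, r$sbp_right))
  dbp <- mean(c(r$dbp_left, r$dbp_right))
  mhr <- mean(c(r$mhr_left, r$mhr_right))
  pp <- sbp - dbp
  map <- (sbp + 2 * dbp) / 3
  co <- mhr * pp * 0.002
  tibble(sbp = sbp, dbp = dbp, mhr = mhr, pp = pp, map = map, co = co,
         rpp = mhr * sbp, si = mhr / sbp, msi = mhr / map,
         sv = 0.002 * pp) # CO/MHR simplified; exact SV = 0.002 PP identity
}

#' Build the full 37-feature vector for one visit
#'
#' Computes the baseline, valid-minute flags and Dawes events from the
#' gap-free FHR trace, then assembles the linear, non-linear, spectral and
#' hemodynamic feature groups in canonical order. Fails loudly, naming the
#' feature, if any value is non-finite.
#'
#' @param fhr_bpm Gap-free 4-Hz FHR vector (>= 5 whole minutes).
#' @param bp_reading One-row data frame with both-arm SBP/DBP/MHR columns.
#' @param fs Sampling rate (Hz).
#' @return One-row tibble with the 37 canonical feature columns.
#' @export
build_feature_vector <- function(fhr_bpm, bp_reading, fs = 4) {
  baseline <- compute_baseline(fhr_bpm, fs)
  flags <- flag_valid_minutes(baseline, fs)
  events <- detect_events(fhr_bpm, baseline, flags, fs)
  out <- dplyr::bind_cols(
    time_domain_features(fhr_bpm, events, fs),
    nonlinear_features(to_interbeat(fhr_bpm)),
    spectral_features(fhr_bpm, fs),
    hemodynamic_features(bp_reading)
  )[feature_names()]
  bad <- names(out)[!vapply(out, function(v) is.finite(v[1]), logical(1))]
  if (length(bad) > 0) {
    stop("build_feature_vector: non-finite feature(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Compute the feature table for a simulated cohort
#'
#' Maps [build_feature_vector()] over the visits of a [simulate_cohort()]
#' result, keeping the id columns.
#'
#' @param cohort List from [simulate_cohort()].
#' @return Tibble with `patient_id`, `visit_id`, `ga_months`, `group` and
#'   the 37 canonical feature columns.
#' @export
cohort_features <- function(cohort) {
  visits <- cohort$visits
  feats <- purrr::map(seq_len(nrow(visits)), function(i) {
    build_feature_vector(visits$trace[[i]]$bpm, visits[i, ])
  })
  dplyr::bind_cols(
    visits[c("patient_id", "visit_id", "ga_months", "group")],
    dplyr::bind_rows(feats)
  )
}
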