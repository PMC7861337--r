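#' Analysis window specification
#'
#' The Doppler recording is analysed with 3.75-s windows slid by 0.25 s,
#' which yields one FHR estimate every 0.25 s, i.e. a 4-Hz series.
#'
#' @param length_s Window length in seconds.
#' @param hop_s Hop between window onsets in seconds.
#' @return A list with `length_s`, `hop_s` and the derived `rate_hz`.
#' @export
window_spec <- function(length_s = 3.75, hop_s = 0.25) {
  stopifnot(length_s > 0, hop_s > 0)
  list(length_s = length_s, hop_s = hop_s, rate_hz = 1 / hop_s)
}

#' Enumerate analysis windows over a recording
#'
#' @param recording A [doppler_recording()].
#' @param spec A [window_spec()].
#' @return Tibble with one row per window: `window`, `onset_s`, `end_s`,
#'   `start_sample`, `end_sample`. Window `k` covers
#'   `[(k-1)*hop, (k-1)*hop + length)`.
#' @export
segment_windows <- function(recording, spec = window_spec()) {
  stopifnot(inherits(recording, "doppler_recording"))
  if (recording$duration_s < spec$length_s) {
    stop("segment_windows: recording shorter than one window (",
         recording$duration_s, " s < ", spec$length_s, " s)", call. = FALSE)
  }
  n_win <- floor((recording$duration_s - spec$length_s) / spec$hop_s) + 1
  k <- seq_len(n_win)
  onset <- (k - 1) * spec$hop_s
  len <- round(spec$length_s * recording$rate)
  start <- round(onset * recording$rate) + 1
  tibble(window = k, onset_s = onset, end_s = onset + spec$length_s,
         start_sample = start, end_sample = start + len - 1)
}

#' Rule-based surrogate window-quality classifier
#'
#' Stands in for the study's trained quality classifier with a transparent
#' rule set over the same label vocabulary: near-zero energy is `silence`;
#' dominant 50/60-Hz line power is `interference`; weak envelope
#' periodicity in the physiologic 60-240 BPM lag range is `low_snr`;
#' anything else is `good`. (`talking` exists in the vocabulary but is only
#' ever assigned through externally supplied labels.)
#'
#' @param window Numeric vector of audio samples (one 3.75-s window).
#' @param rate Sampling rate of `window` in Hz.
#' @param energy_threshold RMS below which the window is `silence`.
#' @param line_power_threshold Fraction of spectral power within +/-1 Hz of
#'   50/60 Hz above which the window is `interference`.
#' @param periodicity_threshold Minimum normalized autocorrelation peak of
#'   the envelope in the 0.25-1.0 s lag range for a `good` label.
#' @return A single label string.
#' @export
classify_window_quality <- function(window, rate,
                                    energy_threshold = 1e-4,
                                    line_power_threshold = 0.5,
                                    periodicity_threshold = 0.3) {
  x <- as.numeric(window)
  if (sqrt(mean(x^2)) < energy_threshold) return("silence")
  xm <- x - mean(x)
  n <- length(xm)
  sp <- Mod(fft(xm))^2
  freq <- (seq_len(n) - 1) * rate / n
  half <- freq <= rate / 2
  line <- half & ((freq >= 49 & freq <= 51) | (freq >= 59 & freq <= 61))
  if (sum(sp[line]) / sum(sp[half]) > line_power_threshold) {
    return("interference")
  }
  env <- envelope_signal(x, rate)
  pk <- autocorr_peak(env - mean(env), rate)
  if (is.na(pk$strength) || pk$strength < periodicity_threshold) {
    return("low_snr")
  }
  "good"
}

# rectified + moving-average (first spectral null at `cutoff_hz`) envelope;
# cumsum implementation so whole recordings are O(n)
envelope_signal <- function(x, rate, cutoff_hz = 25) {
  w <- max(1, round(rate / cutoff_hz))
  a <- abs(x)
  n <- length(a)
  if (w == 1) return(a)
  half <- w %/% 2
  cs <- cumsum(c(0, a))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (w - half - 1), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# FFT autocorrelation; strongest peak in the lag band [min_lag_s, max_lag_s]
# with parabolic sub-sample interpolation. strength = peak / zero-lag.
autocorr_peak <- function(x, rate, min_lag_s = 0.25, max_lag_s = 1.0) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  sp <- fft(c(x, rep(0, nfft - n)))
  ac <- Re(fft(Mod(sp)^2, inverse = TRUE))[seq_len(n)]
  if (ac[1] <= 0) return(list(lag_s = NA_real_, strength = NA_real_))
  lags <- round(min_lag_s * rate):round(max_lag_s * rate)
  lags <- lags[lags >= 1 & lags < n - 1]
  seg <- ac[lags + 1]
  # prefer the fundamental: shortest-lag local maximum close to the band
  # maximum (integer multiples of the period peak almost as high)
  i <- which.max(seg)
  loc <- which(diff(sign(diff(seg))) < 0) + 1
  cand <- loc[seg[loc] >= 0.85 * seg[i]]
  if (length(cand) > 0) i <- min(cand)
  lag <- lags[i]
  # parabolic interpolation around the discrete peak
  y0 <- ac[lag]; y1 <- ac[lag + 1]; y2 <- ac[lag + 2]
  denom <- y0 - 2 * y1 + y2
  frac <- if (abs(denom) > 1e-12) 0.5 * (y0 - y2) / denom else 0
  frac <- max(-0.5, min(0.5, frac))
  list(lag_s = (lag + frac) / rate, strength = seg[i] / ac[1])
}

#' Estimate FHR for one analysis window by envelope autocorrelation
#'
#' The window is rectified and low-pass filtered to obtain the envelope;
#' the autocorrelation is searched over lags 0.25-1.0 s (240 down to 60
#' BPM) and the FHR is 60 divided by the fundamental period in seconds.
#' When the normalized peak falls below `prominence_threshold` the estimate
#' is considered unreliable and `NA` is returned.
#'
#' @param window Numeric vector of audio samples.
#' @param rate Sampling rate in Hz.
#' @param prominence_threshold Minimum normalized autocorrelation peak.
#' @param decimate_to_hz Internal envelope rate used for the lag search.
#' @return FHR in BPM, or `NA_real_` when no reliable estimate exists.
#' @export
estimate_fhr_window <- function(window, rate, prominence_threshold = 0.3,
                                decimate_to_hz = 200) {
  env <- envelope_signal(window, rate)
  dec <- max(1, floor(rate / decimate_to_hz))
  env <- env[seq(1, length(env), by = dec)]
  r2 <- rate / dec
  env <- env - mean(env)
  if (all(abs(env) < 1e-12)) return(NA_real_)
  pk <- autocorr_peak(env, r2)
  if (is.na(pk$strength) || pk$strength < prominence_threshold) {
    return(NA_real_)
  }
  60 / pk$lag_s
}

#' Extract a raw 4-Hz FHR series from a Doppler recording
#'
#' Runs [segment_windows()], classifies (or accepts) window-quality labels,
#' and estimates FHR per window. One row is produced per window, i.e. at
#' 4 Hz for the default 0.25-s hop.
#'
#' @param recording A [doppler_recording()].
#' @param labels Optional externally supplied label vector (one per
#'   window), overriding the rule-based surrogate.
#' @param spec A [window_spec()].
#' @param prominence_threshold Minimum normalized autocorrelation peak for
#'   a reliable FHR estimate (and for the `good` label).
#' @param energy_threshold,line_power_threshold Surrogate-classifier
#'   thresholds, as in [classify_window_quality()].
#' @return Tibble `t_s`, `bpm` (`NA` when invalid), `valid`, `label`.
#' @export
extract_fhr <- function(recording, labels = NULL, spec = window_spec(),
                        prominence_threshold = 0.3,
                        energy_threshold = 1e-4,
                        line_power_threshold = 0.5) {
  wins <- segment_windows(recording, spec)
  n <- nrow(wins)
  if (!is.null(labels) && length(labels) != n) {
    stop("extract_fhr: ", length(labels), " labels for ", n, " windows",
         call. = FALSE)
  }
  rate <- recording$rate
  # envelope of the whole recording, decimated once for the lag search
  env <- envelope_signal(recording$samples, rate)
  dec <- max(1, floor(rate / 200))
  env_dec <- env[seq(1, length(env), by = dec)]
  r2 <- rate / dec
  # decimation for the 50/60-Hz line check (keeps those bands un-aliased)
  dec_line <- max(1, floor(rate / 400))
  r_line <- rate / dec_line
  bpm <- rep(NA_real_, n)
  lab <- character(n)
  for (k in seq_len(n)) {
    i0 <- wins$start_sample[k]; i1 <- wins$end_sample[k]
    e <- env_dec[ceiling(i0 / dec):floor(i1 / dec)]
    e <- e - mean(e)
    pk <- if (all(abs(e) < 1e-12)) {
      list(lag_s = NA_real_, strength = NA_real_)
    } else autocorr_peak(e, r2)
    if (is.null(labels)) {
      x <- recording$samples[i0:i1]
      if (sqrt(mean(x^2)) < energy_threshold) {
        lab[k] <- "silence"
        next
      }
      xl <- x[seq(1, length(x), by = dec_line)]
      xl <- xl - mean(xl)
      sp <- Mod(fft(xl))^2
      freq <- (seq_along(xl) - 1) * r_line / length(xl)
      halfb <- freq <= r_line / 2
      line <- halfb & ((freq >= 49 & freq <= 51) | (freq >= 59 & freq <= 61))
      if (sum(sp[line]) / sum(sp[halfb]) > line_power_threshold) {
        lab[k] <- "interference"
        next
      }
      if (is.na(pk$strength) || pk$strength < prominence_threshold) {
        lab[k] <- "low_snr"
        next
      }
      lab[k] <- "good"
    } else {
      lab[k] <- labels[k]
      if (lab[k] != "good") next
    }
    if (!is.na(pk$strength) && pk$strength >= prominence_threshold) {
      bpm[k] <- 60 / pk$lag_s
    }
  }
  tibble(t_s = wins$onset_s, bpm = bpm,
         valid = !is.na(bpm) & lab == "good", label = lab)
}

#' Clean a raw FHR series into a gap-free 4-Hz trace
#'
#' Applies the study's two reliability rules and interpolates the gaps:
#' (a) an estimate whose ratio to the mean of the previous two retained
#' estimates falls outside the (inclusive) 65-175% range is removed; the
#' first two estimates have no history and are accepted unconditionally;
#' (b) estimates from non-good windows are removed. Each removed run —
#' extended through any isolated surviving estimates up to the next stable
#' segment (five adjacent retained points spanning at most 10 BPM) — is
#' replaced by linear interpolation between its retained neighbours;
#' leading/trailing runs are back-/forward-filled from the nearest stable
#' segment.
#'
#' @param raw Tibble from [extract_fhr()] (`t_s`, `bpm`, `valid`, `label`).
#' @param ratio_low,ratio_high Inclusive bounds of the ratio rule.
#' @param stable_len,stable_range_bpm Stable-segment definition.
#' @return Tibble `t_s`, `bpm`, `provenance` (`"measured"`/`"interpolated"`)
#'   with no missing values.
#' @export
clean_fhr_series <- function(raw, ratio_low = 0.65, ratio_high = 1.75,
                             stable_len = 5, stable_range_bpm = 10) {
  stopifnot(all(c("t_s", "bpm") %in% names(raw)))
  n <- nrow(raw)
  valid <- if ("valid" %in% names(raw)) raw$valid else !is.na(raw$bpm)
  valid <- valid & !is.na(raw$bpm)
  if (sum(valid) < stable_len) {
    stop("clean_fhr_series: fewer than ", stable_len, " valid estimates",
         call. = FALSE)
  }
  v <- raw$bpm
  # sequential ratio rule over retained (measured) history
  accepted <- logical(n)
  hist2 <- numeric(0)
  for (i in seq_len(n)) {
    if (!valid[i]) next
    if (length(hist2) < 2) {
      accepted[i] <- TRUE
      hist2 <- c(hist2, v[i])
      if (length(hist2) > 2) hist2 <- hist2[-1]
      next
    }
    ratio <- v[i] / mean(hist2)
    if (ratio >= ratio_low && ratio <= ratio_high) {
      accepted[i] <- TRUE
      hist2 <- c(hist2[-1], v[i])
    }
  }
  acc_idx <- which(accepted)
  # stable segments: stable_len adjacent accepted samples, range <= 10 BPM
  in_stable <- logical(n)
  runs <- split(acc_idx, cumsum(c(1, diff(acc_idx) != 1)))
  for (r in runs) {
    if (length(r) < stable_len) next
    for (s in seq_len(length(r) - stable_len + 1)) {
      idx <- r[s:(s + stable_len - 1)]
      if (max(v[idx]) - min(v[idx]) <= stable_range_bpm) {
        in_stable[idx] <- TRUE
      }
    }
  }
  stable_idx <- which(accepted & in_stable)
  if (length(stable_idx) == 0) {
    stop("clean_fhr_series: no stable segment found; trace unusable",
         call. = FALSE)
  }
  # a removed run extends through isolated accepted points until the next
  # stable segment; retained = accepted points not swallowed by a run
  retained <- accepted
  bad <- which(!accepted)
  for (i in bad) {
    j <- stable_idx[stable_idx > i]
    if (length(j) > 0) {
      retained[i:(min(j) - 1)] <- FALSE
    } else {
      retained[i:n] <- FALSE
      retained[stable_idx] <- TRUE
      break
    }
  }
  retained[stable_idx] <- TRUE
  ridx <- which(retained)
  out <- approx(x = ridx, y = v[ridx], xout = seq_len(n), rule = 2)$y
  tibble(t_s = raw$t_s, bpm = out,
         provenance = ifelse(retained, "measured", "interpolated"))
}

#' Inclusion screen for a Doppler recording
#'
#' A recording is included when it lasts more than 10 min (strictly
#' > 600 s) and at least 50% of its 3.75-s windows are labelled good.
#'
#' @param duration_s Recording duration in seconds.
#' @param labels Character vector of window-quality labels.
#' @return Tibble `included` (logical), `reason` (`NA` when included),
#'   `good_fraction`.
#' @export
screen_recording <- function(duration_s, labels) {
  gf <- mean(labels == "good")
  if (duration_s <= 600) {
    tibble(included = FALSE, reason = "duration", good_fraction = gf)
  } else if (gf < 0.5) {
    tibble(included = FALSE, reason = "quality", good_fraction = gf)
  } else {
    tibble(included = TRUE, reason = NA_character_, good_fraction = gf)
  }
}

#' Inclusion screen for a blood-pressure reading
#'
#' Excludes readings whose left/right arm difference reaches 15 mmHg for
#' systolic or diastolic pressure (spurious measurement) and possible
#' preeclampsia readings whose arm-averaged systolic pressure exceeds
#' 130 mmHg or diastolic exceeds 80 mmHg (supine-position thresholds).
#'
#' @param reading One-row data frame with `sbp_left`, `sbp_right`,
#'   `dbp_left`, `dbp_right`, `mhr_left`, `mhr_right`.
#' @param arm_diff_max Exclusive arm-difference bound (mmHg).
#' @param sbp_max,dbp_max Preeclampsia screen thresholds (mmHg).
#' @return Tibble `included`, `reason`.
#' @export
screen_bp <- function(reading, arm_diff_max = 15, sbp_max = 130,
                      dbp_max = 80) {
  r <- as.list(reading)
  if (abs(r$sbp_left - r$sbp_right) >= arm_diff_max ||
      abs(r$dbp_left - r$dbp_right) >= arm_diff_max) {
    return(tibble(included = FALSE, reason = "arm difference"))
  }
  if (mean(c(r$sbp_left, r$sbp_right)) > sbp_max ||
      mean(c(r$dbp_left, r$dbp_right)) > dbp_max) {
    return(tibble(included = FALSE, reason = "possible preeclampsia"))
  }
  tibble(included = TRUE, reason = NA_character_)
}
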