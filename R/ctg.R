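#' Estimate the slowly varying FHR baseline
#'
#' A filter-bank scheme that attenuates accelerations/decelerations (>= 15
#' BPM excursions shorter than about a minute) while tracking slow drift:
#' a cascade of running median filters (16- to 128-s widths) followed
#' by a 60-s centred moving average, run twice — the second pass recomputes
#' the baseline after clipping samples deviating more than
#' `clip_bpm` from the first-pass estimate.
#'
#' @param fhr_bpm Numeric gap-free 4-Hz FHR vector, at least 3 minutes.
#' @param fs Sampling rate (Hz).
#' @param clip_bpm Clipping half-width for the second pass (BPM).
#' @return Numeric baseline vector, same length as `fhr_bpm`.
#' @export
compute_baseline <- function(fhr_bpm, fs = 4, clip_bpm = 10) {
  n <- length(fhr_bpm)
  if (n < 3 * 60 * fs) {
    stop("compute_baseline: need at least 3 min of data", call. = FALSE)
  }
  one_pass <- function(x) {
    for (w_s in c(16, 32, 64, 128)) {
      k <- round(w_s * fs)
      if (k %% 2 == 0) k <- k + 1
      x <- stats::runmed(x, k, endrule = "median")
    }
    w <- round(60 * fs)
    xp <- c(rep(x[1], w), x, rep(x[n], w))
    ma <- stats::filter(xp, rep(1 / w, w), sides = 2)
    as.numeric(ma[(w + 1):(w + n)])
  }
  b1 <- one_pass(fhr_bpm)
  clipped <- pmax(b1 - clip_bpm, pmin(b1 + clip_bpm, fhr_bpm))
  one_pass(clipped)
}

#' Flag valid minutes of an FHR (or baseline) series
#'
#' A minute is valid when the modal bin of its histogram (10-BPM bins
#' anchored at 0 BPM) holds more than `threshold` of the samples — i.e.
#' the series is concentrated enough for baseline-relative event detection
#' to be meaningful. Event detection validates the *baseline* segments, so
#' the usual input is the output of [compute_baseline()]; a minute is then
#' invalid only where the baseline itself is unstable.
#'
#' @param fhr_bpm Gap-free 4-Hz series (typically the baseline).
#' @param fs Sampling rate (Hz).
#' @param binwidth Histogram bin width (BPM).
#' @param threshold Modal-bin mass required (fraction).
#' @return Logical vector, one flag per whole minute.
#' @export
flag_valid_minutes <- function(fhr_bpm, fs = 4, binwidth = 10,
                               threshold = 0.40) {
  spm <- 60 * fs
  n_min <- floor(length(fhr_bpm) / spm)
  vapply(seq_len(n_min), function(j) {
    x <- fhr_bpm[((j - 1) * spm + 1):(j * spm)]
    bins <- floor(x / binwidth)
    max(table(bins)) / length(x) > threshold
  }, logical(1))
}

#' Detect Dawes accelerations and decelerations
#'
#' An acceleration is a maximal run where the FHR stays above the baseline
#' for at least 15 s with at least one sample 15 BPM or more above it;
#' decelerations are the mirror image. Events overlapping no valid minute
#' are dropped.
#'
#' @param fhr_bpm Gap-free 4-Hz FHR vector.
#' @param baseline Baseline vector from [compute_baseline()].
#' @param valid_minutes Logical flags from [flag_valid_minutes()]; `NULL`
#'   treats all minutes as valid.
#' @param fs Sampling rate (Hz).
#' @param min_duration_s Minimum run duration (s).
#' @param min_peak_bpm Minimum absolute peak deviation (BPM).
#' @return Tibble `type`, `onset_s`, `end_s`, `peak_dev_bpm`.
#' @export
detect_events <- function(fhr_bpm, baseline, valid_minutes = NULL, fs = 4,
                          min_duration_s = 15, min_peak_bpm = 15) {
  stopifnot(length(fhr_bpm) == length(baseline))
  dev <- fhr_bpm - baseline
  if (is.null(valid_minutes)) {
    valid_minutes <- rep(TRUE, floor(length(fhr_bpm) / (60 * fs)))
  }
  find_runs <- function(above) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    tibble(start = starts[r$values], end = ends[r$values])
  }
  min_len <- min_duration_s * fs
  collect <- function(runs, sign) {
    if (nrow(runs) == 0) return(NULL)
    out <- list()
    for (i in seq_len(nrow(runs))) {
      idx <- runs$start[i]:runs$end[i]
      if (length(idx) < min_len) next
      peak <- max(sign * dev[idx])
      if (peak < min_peak_bpm) next
      mins <- unique(floor((idx - 1) / (60 * fs))) + 1
      mins <- mins[mins <= length(valid_minutes)]
      if (length(mins) == 0 || !any(valid_minutes[mins])) next
      pk_idx <- idx[which.max(sign * dev[idx])]
      out[[length(out) + 1]] <- tibble(
        type = if (sign > 0) "acceleration" else "deceleration",
        onset_s = (idx[1] - 1) / fs,
        end_s = (idx[length(idx)] - 1) / fs,
        peak_dev_bpm = dev[pk_idx]
      )
    }
    if (length(out) > 0) dplyr::bind_rows(out) else NULL
  }
  res <- dplyr::bind_rows(collect(find_runs(dev > 0), 1),
                          collect(find_runs(dev < 0), -1))
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(type = character(0), onset_s = numeric(0),
                  end_s = numeric(0), peak_dev_bpm = numeric(0)))
  }
  dplyr::arrange(res, .data$onset_s)
}

#' Phase-rectified signal averaging capacity (M = L = 1)
#'
#' With averaging window and wavelet scale both one, the acceleration
#' (deceleration) capacity reduces to the mean half-increment over anchor
#' points: anchors are samples larger (smaller) than their predecessor and
#' the capacity is `mean((x(i) - x(i-1)) / 2)` over anchors, sign-folded so
#' both capacities are non-negative. A series with no anchors (e.g. a
#' constant trace) has capacity 0.
#'
#' @param x Numeric series (FHR in BPM).
#' @param direction `"accel"` or `"decel"`.
#' @return Capacity in the units of `x`, >= 0.
#' @export
prsa_capacity <- function(x, direction = c("accel", "decel")) {
  direction <- match.arg(direction)
  stopifnot(length(x) >= 3)
  d <- diff(x)
  inc <- if (direction == "accel") d[d > 0] else -d[d < 0]
  if (length(inc) == 0) return(0)
  mean(inc) / 2
}
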