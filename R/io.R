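#' Canonical names of the 37-feature panel
#'
#' The panel combines four groups: linear time-domain indexes of the
#' interbeat sequence, non-linear/complexity indexes, spectral band powers of
#' the fetal heart-rate trace, and maternal hemodynamic quantities derived
#' from the blood-pressure reading. Within each group names are ordered
#' alphabetically so that feature tables always have deterministic columns.
#'
#' @param group Optional group filter, one of `"linear"`, `"nonlinear"`,
#'   `"spectral"`, `"hemodynamic"`.
#' @return Character vector of feature names (37 when `group` is `NULL`).
#' @export
#' @examples
#' length(feature_names())
feature_names <- function(group = NULL) {
  groups <- list(
    linear = c("aac", "acc_per_min", "basal_fhr", "dac", "ii", "kurtosis_is",
               "lti", "ltv", "m_is", "pnn5", "rmssd_is", "skewness_is",
               "std_is", "std_rmssd_ratio", "stv", "stv_ltv", "var_is"),
    nonlinear = c("apen", "entropy", "fractal_dim", "gmi", "lyapunov", "tone"),
    spectral = c("hf", "lf", "lf_mf_hf_ratio", "mf"),
    hemodynamic = c("co", "dbp", "map", "mhr", "msi", "pp", "rpp", "sbp",
                    "si", "sv")
  )
  if (is.null(group)) return(unname(unlist(groups)))
  if (!group %in% names(groups)) {
    stop("unknown feature group: ", group, call. = FALSE)
  }
  groups[[group]]
}

#' Construct a Doppler recording object
#'
#' A thin container for a mono Doppler audio trace: the (dimensionless)
#' amplitude samples and the sampling rate in Hz.
#'
#' @param samples Numeric vector of finite amplitudes, nominally in -1..1.
#' @param rate Sampling rate in Hz (canonical field value 44100).
#' @return An object of class `doppler_recording` with elements `samples`,
#'   `rate` and `duration_s`.
#' @export
doppler_recording <- function(samples, rate = 44100) {
  stopifnot(is.numeric(samples), length(samples) > 0, rate > 0)
  if (!all(is.finite(samples))) {
    stop("doppler_recording: samples must all be finite", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), rate = rate,
         duration_s = length(samples) / rate),
    class = "doppler_recording"
  )
}

#' @export
print.doppler_recording <- function(x, ...) {
  cat(sprintf("<doppler_recording: %.2f s at %g Hz (%d samples)>\n",
              x$duration_s, x$rate, length(x$samples)))
  invisible(x)
}

#' Read a mono PCM WAV file as a Doppler recording
#'
#' Parses a RIFF/WAVE file containing a single channel of 8-, 16- or 32-bit
#' integer PCM (or 32-bit IEEE float) audio. Samples are rescaled to -1..1;
#' the rate is taken from the header. Multichannel files are rejected.
#'
#' @param path Path to a WAV file.
#' @return A [doppler_recording()].
#' @export
read_doppler_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little") # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) {
      stop("malformed WAV: no data chunk in ", path, call. = FALSE)
    }
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        rate = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$channels != 1) {
        stop("read_doppler_wav: expected mono audio, got ", fmt$channels,
             " channels", call. = FALSE)
      }
      n <- sz %/% (fmt$bits %/% 8)
      if (fmt$audio_format == 3 && fmt$bits == 32) {
        x <- readBin(con, "numeric", n, 4, endian = "little")
      } else if (fmt$audio_format == 1 && fmt$bits == 16) {
        x <- readBin(con, "integer", n, 2, signed = TRUE,
                     endian = "little") / 32767
      } else if (fmt$audio_format == 1 && fmt$bits == 32) {
        x <- readBin(con, "integer", n, 4, endian = "little") / 2147483648
      } else if (fmt$audio_format == 1 && fmt$bits == 8) {
        x <- (readBin(con, "integer", n, 1, signed = FALSE) - 128) / 128
      } else {
        stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
             fmt$bits, " bits)", call. = FALSE)
      }
      return(doppler_recording(x, fmt$rate))
    } else {
      readBin(con, "raw", sz + (sz %% 2)) # skip unknown chunk (word aligned)
    }
  }
}

#' Write a Doppler recording to a mono PCM16 WAV file
#'
#' @param recording A [doppler_recording()]; samples are clipped to -1..1 and
#'   quantized to 16-bit PCM.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_doppler_wav <- function(recording, path) {
  stopifnot(inherits(recording, "doppler_recording"))
  x <- pmax(-1, pmin(1, recording$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(1), con, 2, endian = "little")  # PCM
  writeBin(as.integer(1), con, 2, endian = "little")  # mono
  writeBin(as.integer(recording$rate), con, 4, endian = "little")
  writeBin(as.integer(recording$rate * 2), con, 4, endian = "little")
  writeBin(as.integer(2), con, 2, endian = "little")  # block align
  writeBin(as.integer(16), con, 2, endian = "little") # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Read a per-visit metadata table
#'
#' Expects a CSV with columns `patient_id`, `visit_id`, `ga_months`,
#' `wav_path`, `sbp_left`, `sbp_right`, `dbp_left`, `dbp_right`, `mhr_left`,
#' `mhr_right`. Rows violating the visit invariants (gestational month
#' outside 6..9, non-positive pressures, systolic not above diastolic on
#' either arm, missing arm) are dropped and reported.
#'
#' @param path CSV path.
#' @return A tibble of valid visits with attribute `"rejected"`: a tibble of
#'   (row, reason) for rows that failed validation.
#' @export
read_visits_table <- function(path) {
  cols <- c("patient_id", "visit_id", "ga_months", "wav_path",
            "sbp_left", "sbp_right", "dbp_left", "dbp_right",
            "mhr_left", "mhr_right")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty visits table: ", path, call. = FALSE)
    out <- as_tibble(setNames(rep(list(logical(0)), length(cols)), cols))
    attr(out, "rejected") <- tibble(row = integer(0), reason = character(0))
    return(out)
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("visits table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as_tibble(df[cols])
  reasons <- rep(NA_character_, nrow(df))
  bp_cols <- c("sbp_left", "sbp_right", "dbp_left", "dbp_right",
               "mhr_left", "mhr_right")
  bp <- as.matrix(df[bp_cols])
  bad_arm <- !complete.cases(bp) | apply(bp <= 0, 1, any)
  reasons[bad_arm] <- "invalid or missing blood-pressure values"
  bad_sd <- !bad_arm &
    (df$sbp_left <= df$dbp_left | df$sbp_right <= df$dbp_right)
  reasons[bad_sd] <- "systolic not above diastolic"
  bad_ga <- is.na(df$ga_months) | !df$ga_months %in% 6:9
  reasons[bad_ga] <- "ga_months outside 6..9"
  keep <- is.na(reasons)
  rejected <- tibble(row = which(!keep), reason = reasons[!keep])
  out <- df[keep, ]
  attr(out, "rejected") <- rejected
  out
}

#' Read a newborn-outcomes table
#'
#' Expects a CSV with columns `patient_id`, `sex` (`male`/`female`) and
#' `birth_weight_kg`. A `lbw` flag is added using the sex-specific
#' low-birth-weight thresholds (defaults 2.64 kg for males, 2.57 kg for
#' females, the field thresholds mapped from national-survey percentiles).
#'
#' @param path CSV path.
#' @param threshold_male,threshold_female LBW weight thresholds in kg.
#' @return Tibble with columns `patient_id`, `sex`, `birth_weight_kg`, `lbw`.
#' @export
read_newborns_table <- function(path, threshold_male = 2.64,
                                threshold_female = 2.57) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "sex", "birth_weight_kg")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("newborns table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as_tibble(df[need])
  if (any(df$birth_weight_kg <= 0, na.rm = TRUE)) {
    stop("newborns table: birth_weight_kg must be positive", call. = FALSE)
  }
  thr <- ifelse(df$sex == "male", threshold_male, threshold_female)
  df$lbw <- df$birth_weight_kg < thr
  df
}

#' Write a feature table to CSV
#'
#' @param features Tibble with id columns (`patient_id`, `visit_id`,
#'   `ga_months` when present) and exactly the canonical 37 feature columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  fn <- feature_names()
  missing <- setdiff(fn, names(features))
  if (length(missing) > 0) {
    stop("feature table is missing feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ids <- intersect(c("patient_id", "visit_id", "ga_months", "group"),
                   names(features))
  out <- features[c(ids, fn)]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Tibble with id columns and the canonical 37 feature columns.
#' @export
read_feature_table <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(feature_names(), names(df))
  if (length(missing) > 0) {
    stop("feature table is missing feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
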