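#' Gestational-age error records for the screening stage
#'
#' The screening statistic is `delta = LMP-based GA - median estimated GA`
#' over the testing repetitions: positive delta (underestimation of the
#' fetus' apparent maturity) is the direction suggestive of growth
#' restriction.
#'
#' @param test_result A `fetal_test` object from [train_final_and_test()].
#' @param newborns Tibble with `patient_id`, `birth_weight_kg` and
#'   optionally `group`.
#' @return Tibble `visit_id`, `patient_id`, `lmp_ga_months`,
#'   `estimated_ga_months`, `delta_months`, `birth_weight_kg`, `group`.
#' @export
ga_error_records <- function(test_result, newborns) {
  stopifnot(inherits(test_result, "fetal_test"))
  pv <- test_result$per_visit
  out <- dplyr::left_join(
    tibble(visit_id = pv$visit_id, patient_id = pv$patient_id,
           lmp_ga_months = pv$ga_months,
           estimated_ga_months = pv$estimate,
           delta_months = pv$ga_months - pv$estimate,
           group = pv$group),
    newborns[intersect(c("patient_id", "birth_weight_kg"), names(newborns))],
    by = "patient_id"
  )
  class(out) <- c("ga_error_records", class(out))
  out
}

#' Screening statistic for one visit
#'
#' @param lmp_ga LMP-based gestational age (months).
#' @param estimates Vector of per-repetition GA estimates for the visit.
#' @return `lmp_ga - median(estimates)` (months).
#' @export
ga_error <- function(lmp_ga, estimates) {
  stopifnot(length(estimates) >= 1)
  lmp_ga - median(estimates)
}

#' Robust linear fit of the GA error against birth weight
#'
#' Iteratively reweighted least squares with the Tukey bisquare loss
#' (tuning constant 4.685), regressing `delta` on birth weight; the
#' Pearson correlation between weight and delta is reported alongside.
#'
#' @param records Tibble with `delta_months` and `birth_weight_kg` (e.g.
#'   from [ga_error_records()]).
#' @param max_iter,tol IRLS controls.
#' @return A `proxy_fit` object: `slope` (months/kg), `intercept`
#'   (months), `pearson_r`, `p_value`, `n`, and the underlying `rlm` fit.
#' @export
robust_fit_delta_weight <- function(records, max_iter = 50, tol = 1e-8) {
  w <- records$birth_weight_kg
  d <- records$delta_months
  ok <- is.finite(w) & is.finite(d)
  w <- w[ok]; d <- d[ok]
  if (length(unique(w)) < 3) {
    stop("robust_fit_delta_weight: need >= 3 records with distinct weights",
         call. = FALSE)
  }
  fit <- MASS::rlm(d ~ w, psi = MASS::psi.bisquare, c = 4.685,
                   maxit = max_iter, acc = tol)
  ct <- cor.test(w, d)
  out <- list(slope = unname(coef(fit)[2]),
              intercept = unname(coef(fit)[1]),
              pearson_r = unname(ct$estimate), p_value = ct$p.value,
              n = length(w), fit = fit)
  class(out) <- "proxy_fit"
  out
}

#' @export
print.proxy_fit <- function(x, ...) {
  cat(sprintf(
    "<proxy_fit: delta = %.3f %+.3f w  (r = %.3f, p = %.3g, n = %d)>\n",
    x$intercept, x$slope, x$pearson_r, x$p_value, x$n))
  invisible(x)
}

#' @rdname robust_fit_delta_weight
#' @param x A `proxy_fit` object.
#' @param ... Unused.
#' @export
tidy.proxy_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "birth_weight_kg"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname robust_fit_delta_weight
#' @export
glance.proxy_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         pearson_r = x$pearson_r, p_value = x$p_value, n = x$n)
}

#' AUROC of the screening statistic for low birth weight
#'
#' Sweeps a threshold over all distinct values of `delta` (a visit is
#' called LBW when its delta exceeds the threshold), computing sensitivity
#' and specificity at each operating point, and integrates the ROC curve
#' trapezoidally. Ties between the groups receive half credit, making the
#' area insensitive to the strict/non-strict threshold convention.
#'
#' @param records Tibble with `delta_months` and `group` (must contain
#'   `"LBW"` and at least one other level).
#' @param positive Positive-class label.
#' @return A `roc_result` object: `auroc` and `points` (tibble
#'   `threshold`, `sensitivity`, `specificity`).
#' @export
auroc_lbw <- function(records, positive = "LBW") {
  delta <- records$delta_months
  pos <- records$group == positive
  if (all(pos) || !any(pos)) {
    stop("auroc_lbw: both groups must be represented", call. = FALSE)
  }
  d_pos <- delta[pos]; d_neg <- delta[!pos]
  # rank (Mann-Whitney) formulation == trapezoidal area with half-credit ties
  cmp <- outer(d_pos, d_neg, `>`) + 0.5 * outer(d_pos, d_neg, `==`)
  auroc <- mean(cmp)
  thr <- sort(unique(delta), decreasing = TRUE)
  points <- tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(d_pos > t), numeric(1)),
    specificity = vapply(thr, function(t) mean(d_neg <= t), numeric(1))
  )
  out <- list(auroc = auroc, points = points, positive = positive,
              n_pos = sum(pos), n_neg = sum(!pos))
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUROC = %.3f (%d %s vs %d others)>\n",
              x$auroc, x$n_pos, x$positive, x$n_neg))
  invisible(x)
}

#' Map a reference low-birth-weight percentile onto a local cohort
#'
#' The LBW threshold is defined by locating the reference percentile of
#' newborns at or below 2.5 kg (14.3% for males and 16.33% for females in
#' the national survey the study drew on) in the local birth-weight
#' distribution.
#'
#' @param local_weights Numeric vector of local birth weights (kg),
#'   >= 20 values.
#' @param sex `"male"` or `"female"`.
#' @param percentile Override percentile (fraction); defaults to the
#'   sex-specific reference value.
#' @return Threshold weight in kg.
#' @export
derive_lbw_threshold <- function(local_weights, sex = c("male", "female"),
                                 percentile = NULL) {
  sex <- match.arg(sex)
  if (length(local_weights) < 20) {
    stop("derive_lbw_threshold: need >= 20 local weights", call. = FALSE)
  }
  p <- percentile %||% if (sex == "male") 0.143 else 0.1633
  unname(quantile(local_weights, probs = p))
}

#' Convert gestational months to weeks
#'
#' Uses the 40-weeks-per-9-months pregnancy conversion, reported to one
#' decimal.
#'
#' @param m Months (>= 0).
#' @param digits Decimals to report.
#' @return Weeks.
#' @export
#' @examples
#' months_to_weeks(9)    # 40.0
#' months_to_weeks(0.72) # 3.2
months_to_weeks <- function(m, digits = 1) {
  stopifnot(all(m >= 0))
  round(m * 40 / 9, digits)
}
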