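#' Plot per-month cross-validation errors
#'
#' Boxplots of the per-trial mean absolute error by gestational month.
#'
#' @param object A `fetal_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fetal_cv <- function(object, ...) {
  df <- object$per_trial
  df$month <- factor(df$month, levels = c("6", "7", "8", "9", "all"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$mae)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "Gestational month", y = "MAE (months)",
                  title = sprintf("%s: %d-trial %d-fold cross-validation",
                                  toupper(object$model), object$trials,
                                  object$folds)) +
    ggplot2::theme_minimal()
}

#' Plot held-out test errors by group and month
#'
#' @param object A `fetal_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fetal_test <- function(object, ...) {
  df <- object$per_rep
  df$month <- factor(df$month, levels = c("6", "7", "8", "9", "all"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$mae,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(position = "dodge") +
    ggplot2::labs(x = "Gestational month", y = "MAE (months)",
                  fill = "Group",
                  title = sprintf("Held-out test, %d repetitions",
                                  object$repetitions)) +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of the screening statistic
#'
#' @param object A `roc_result` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUROC = %.2f", object$auroc)) +
    ggplot2::theme_minimal()
}

#' Plot GA error against birth weight with the robust fit
#'
#' @param records Tibble from [ga_error_records()].
#' @param fit Optional `proxy_fit` from [robust_fit_delta_weight()].
#' @return A ggplot object.
#' @export
plot_delta_weight <- function(records, fit = NULL) {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$birth_weight_kg,
                                    y = .data$delta_months,
                                    colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Birth weight (kg)",
                  y = expression(delta ~ "(months)"), colour = "Group") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(slope = fit$slope,
                                  intercept = fit$intercept)
  }
  p
}

#' Plot an FHR trace with baseline and detected events
#'
#' @param fhr_bpm Gap-free 4-Hz FHR vector.
#' @param baseline Optional baseline vector.
#' @param events Optional event tibble from [detect_events()].
#' @param fs Sampling rate (Hz).
#' @return A ggplot object.
#' @export
plot_fhr_trace <- function(fhr_bpm, baseline = NULL, events = NULL, fs = 4) {
  df <- tibble(t_min = (seq_along(fhr_bpm) - 1) / fs / 60, bpm = fhr_bpm)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$bpm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (min)", y = "FHR (BPM)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = events, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$onset_s / 60, xmax = .data$end_s / 60,
                   ymin = -Inf, ymax = Inf, fill = .data$type),
      alpha = 0.2)
  }
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_line(
      data = tibble(t_min = df$t_min, bpm = baseline),
      colour = "firebrick", linewidth = 0.5)
  }
  p
}
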