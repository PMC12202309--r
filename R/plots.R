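# Plotting helpers (ggplot2).

#' Mean concentration-time curves by group
#'
#' Mean (and SEM error bars) of the observed concentrations per time point,
#' faceted by compound and matrix, on a log concentration scale. Below-limit
#' records are dropped.
#'
#' @param data Long-format concentration records.
#' @param arm_filter Optional arm label to restrict to.
#' @return A ggplot object.
#' @export
plot_concentrations <- function(data, arm_filter = NULL) {
  if (!is.null(arm_filter)) {
    data <- dplyr::filter(data, .data$arm == arm_filter)
  }
  df <- data |>
    dplyr::filter(!.data$blq_flag, .data$conc > 0) |>
    dplyr::group_by(.data$group, .data$arm, .data$compound, .data$matrix,
                    .data$time_h) |>
    dplyr::summarise(mean_conc = mean(.data$conc),
                     sem = stats::sd(.data$conc) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$mean_conc,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_conc - .data$sem,
                                        ymax = .data$mean_conc + .data$sem),
                           width = 0.05) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(.data$matrix ~ .data$compound + .data$arm,
                        scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (ng/mL or ng/g)",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' @method autoplot pk_fit
#' @export
autoplot.pk_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted,
                  ggplot2::aes(x = .data$pred, y = .data$conc,
                               colour = .data$arm,
                               shape = .data$compound)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "predicted (ng/mL)", y = "observed (ng/mL)",
                  title = "pooled fit: observed vs predicted") +
    ggplot2::theme_bw()
}

#' @method autoplot batch_auc
#' @export
autoplot.batch_auc <- function(object, ...) {
  df <- tibble::tibble(estimate = object$auc,
                       lower = object$lower, upper = object$upper)
  ggplot2::ggplot(df, ggplot2::aes(x = "AUC_t", y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.1) +
    ggplot2::labs(x = NULL, y = "AUC_t (h*ng/mL)",
                  title = sprintf("AUC_t with %g%% bootstrap-t interval",
                                  100 * object$conf_level)) +
    ggplot2::theme_bw()
}
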