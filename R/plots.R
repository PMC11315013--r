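#' Bland-Altman plot for one session
#'
#' Differences (reference minus estimate) against pair means, with the bias
#' and 95% limits of agreement drawn as horizontal lines.
#'
#' @param s,y Series as in [bland_altman()].
#' @param smooth Smooth the estimate before plotting (matching the
#'   statistics).
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(s, y, smooth = TRUE) {
  paired <- pair_series(s, y)
  if (smooth) paired$y <- smooth_minute_series(paired$n, paired$y)
  stats <- bland_altman(s, y, smooth = smooth)
  df <- tibble::tibble(mean = (paired$s + paired$y) / 2,
                       diff = paired$s - paired$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = stats$bias, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(stats$lower_loa, stats$upper_loa),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Mean of reference and estimate (°C)",
                  y = "Reference − estimate (°C)",
                  title = sprintf("Bias %.3f °C, LoA [%.2f, %.2f] °C",
                                  stats$bias, stats$lower_loa,
                                  stats$upper_loa))
}

#' Fold-level agreement plot for a cross-validation result
#'
#' @param object A `dst_cv`.
#' @param ... Unused.
#' @return A ggplot object showing per-fold bias and limits of agreement.
#' @method autoplot dst_cv
#' @export
autoplot.dst_cv <- function(object, ...) {
  ggplot2::ggplot(object$fold_means,
                  ggplot2::aes(x = factor(.data$fold), y = .data$bias)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower_loa,
                                        ymax = .data$upper_loa),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "CV fold", y = "Bias and 95% LoA (°C)")
}

#' Grand-average change-curve plot
#'
#' @param object A `curve_comparison` (e.g. from [verify_in_lab()]).
#' @param ... Unused.
#' @return A ggplot object with both mean change curves.
#' @method autoplot curve_comparison
#' @export
autoplot.curve_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$mean_a, series = "estimated DST"),
    dplyr::mutate(object$mean_b, series = "foot temperature")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$minute, y = .data$delta,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Minutes from lights-off",
                  y = "Temperature change (°C)",
                  colour = NULL,
                  title = sprintf("Pearson r = %.2f", object$r))
}

#' Learning-curve plot
#'
#' @param object A `dst_learning_curve`.
#' @param ... Unused.
#' @return A ggplot object of train/validation mean R-squared versus the
#'   fraction of training subjects.
#' @method autoplot dst_learning_curve
#' @export
autoplot.dst_learning_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("fraction", "train_r2", "val_r2")],
    cols = c("train_r2", "val_r2"),
    names_to = "set", values_to = "r2"
  )
  df$set <- ifelse(df$set == "train_r2", "training", "validation")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$r2,
                                   colour = .data$set)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Fraction of training subjects",
                  y = expression(R^2), colour = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
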