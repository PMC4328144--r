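#' Manhattan-style plot of a regional scan
#'
#' Position (Mb) against -log10 p, colored by imputation retention
#' type (A = genotyped on all arrays, B = well imputed, C = moderately
#' imputed), with optional horizontal guides at the gate and core
#' thresholds.
#'
#' @param records Scan tibble from [single_snp_scan()].
#' @param p_gate,p_core Guide lines (set `NULL` to omit).
#' @return A ggplot object.
#' @export
plot_scan <- function(records, p_gate = 1e-5, p_core = 1e-6) {
  df <- dplyr::filter(records, !is.na(.data$p))
  df$retention <- factor(df$retention,
                         levels = c("A", "B", "C", "unset"))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6,
                                         y = -log10(.data$p),
                                         color = .data$retention)) +
    ggplot2::geom_point(size = 1.2, alpha = 0.8) +
    ggplot2::scale_color_manual(
      values = c(A = "black", B = "red", C = "green4", unset = "grey60"),
      drop = FALSE, name = "retention"
    ) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
  if (!is.null(p_gate)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(p_gate),
                                   linetype = "dashed", color = "grey40")
  }
  if (!is.null(p_core)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(p_core),
                                   linetype = "dotted", color = "grey40")
  }
  gg
}

#' Frequency of collapsed model classes
#'
#' Bar chart of how often each LD-equivalence class was selected over
#' the stochastic iterations, annotated with class size.
#'
#' @param classes Tibble from [collapse_models()].
#' @return A ggplot object.
#' @export
plot_model_classes <- function(classes) {
  df <- dplyr::mutate(classes,
                      label = paste0("#", .data$class_id, " (",
                                     .data$size, " SNP)"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label,
                                                      -.data$frequency),
                                   y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "model class", y = "iterations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Cross-validation curve of an elastic-net fit
#'
#' @param fit An `enet_fit` object.
#' @return A ggplot object.
#' @export
plot_cv_curve <- function(fit) {
  stopifnot(inherits(fit, "enet_fit"))
  ggplot2::ggplot(fit$cv, ggplot2::aes(x = log(.data$lambda),
                                       y = .data$cv_deviance)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cv_deviance - .data$cv_se,
                                      ymax = .data$cv_deviance + .data$cv_se),
                         fill = "grey85") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(xintercept = log(fit$lambda_sel),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(log(lambda)),
                  y = "mean CV deviance / observation") +
    ggplot2::theme_minimal()
}

#' @rdname plot_scan
#' @param object A `pipeline_result`.
#' @param ... Passed to [plot_scan()].
#' @export
autoplot.pipeline_result <- function(object, ...) {
  plot_scan(object$scan, ...)
}
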