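#' Plot age norms as mean +/- 2 SD bands
#'
#' @param object An `age_norms` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.age_norms <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age_year, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                                      ymax = .data$mean + 2 * .data$sd),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "TICV-corrected volume",
                  title = "Age norms (mean ± 2 SD)")
}

#' Plot a fitted age curve over its data
#'
#' @param object An `age_curve` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.age_curve <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$age_years, y = .data$corrected)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "age (years)", y = "TICV-corrected volume",
                  title = paste0(object$region, ": APR ",
                                 sprintf("%+.2f", object$apr), " %/yr"))
}

#' Plot one subject's regional deviation profile
#'
#' Bar chart of per-region Z-scores with flagged (low-volume) regions
#' highlighted; the dashed line marks Z = -2 for visual reference.
#'
#' @param classification A `classification` tibble (one subject).
#' @return A ggplot.
#' @export
plot_subject_profile <- function(classification) {
  df <- dplyr::filter(classification, is.na(.data$excluded_reason))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$z,
                                   fill = .data$flag)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -2, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               name = "flagged low") +
    ggplot2::labs(x = NULL, y = "Z vs age-matched norms") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of battery factor loadings
#'
#' @param object A `battery_reduction` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.battery_reduction <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$factor, y = .data$measure,
                                 fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(title = "Factor loadings",
                  subtitle = paste0("|loading| ≥ ", object$cutoff,
                                    " retained"))
}
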