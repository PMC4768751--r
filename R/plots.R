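#' Plot per-environment heritability estimates
#'
#' Heritability with +/- 1 SE bars by environment, one panel per trait.
#'
#' @param object A [genetic_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genetic_summary <- function(object, ...) {
  df <- dplyr::mutate(object,
                      environment = factor(.data$environment,
                                           levels = unique(.data$environment)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$environment, y = .data$h2)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$h2 - .data$SE_h2, 0),
                                        ymax = .data$h2 + .data$SE_h2),
                           width = 0.15) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = "developmental environment",
                  y = expression(h^2 %+-% SE)) +
    ggplot2::theme_minimal()
}

#' Plot an allometric scaling relationship by environment
#'
#' Log-log scatter of the ANCOVA's response against its covariate, with the
#' fitted per-environment (or common-slope) lines.
#'
#' @param object An [ancova_scaling()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ancova_scaling <- function(object, ...) {
  d <- object$model$model
  names(d)[names(d) == "y"] <- "response"
  pred <- d
  pred$response <- stats::predict(object$model)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$response,
                                  colour = .data$g)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = pred, linewidth = 0.8) +
    ggplot2::labs(x = paste0("log ", object$covariate),
                  y = paste0("log ", object$response),
                  colour = object$group) +
    ggplot2::theme_minimal()
}

#' Trait distributions by developmental environment
#'
#' @param data Phenotype data frame.
#' @param traits Trait column names.
#' @param env_col Environment column.
#' @return A ggplot object (boxplots, one panel per trait, free y scales).
#' @export
plot_trait_distributions <- function(data,
                                     traits = c("body_mass_mg",
                                                "femur_area_mm2",
                                                "testis_mass_mg"),
                                     env_col = "environment") {
  long <- tidyr::pivot_longer(data, dplyr::all_of(traits),
                              names_to = "trait", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[env_col]], y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "developmental environment", y = NULL) +
    ggplot2::theme_minimal()
}
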