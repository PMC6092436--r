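# ggplot2 views of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.rs_ncm <- function(object, ...) {
  dat <- dplyr::arrange(object$otus, .data$p)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$freq_obs),
                        alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$freq_pred), colour = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_low), colour = "blue",
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_high), colour = "blue",
                       linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Regional mean relative abundance (log scale)",
      y = "Occurrence frequency",
      title = sprintf("Sloan neutral model: Nm = %.0f, R2 = %.2f",
                      object$Nm, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rs_nmds <- function(object, groups = NULL, ...) {
  dat <- object$coordinates
  p <- if (is.null(groups)) {
    ggplot2::ggplot(dat, ggplot2::aes(.data$NMDS1, .data$NMDS2))
  } else {
    dat$group <- groups
    ggplot2::ggplot(dat, ggplot2::aes(.data$NMDS1, .data$NMDS2,
                                      colour = .data$group))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = sprintf("NMDS (stress = %.3f)", object$stress)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rs_decay <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$geo_km, .data$dissimilarity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(
      x = "Geographic distance (km)", y = "Bray-Curtis dissimilarity",
      title = sprintf("Distance-decay: Mantel r = %.2f (p = %.3g)",
                      object$mantel$r, object$mantel$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rs_varpart <- function(object, ...) {
  dat <- tidy(object)
  dat$fraction <- factor(dat$fraction,
                         levels = c("pure_env", "shared", "pure_spatial",
                                    "residual"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$fraction, 100 * .data$adj_r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Adjusted R2 (%)",
                  title = "Variation partitioning") +
    ggplot2::theme_minimal()
}
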