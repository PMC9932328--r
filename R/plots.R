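#' Forest plot of mixed-model fixed effects
#'
#' @param object a `qct_fit`.
#' @param drop_intercept omit the intercept row (default `TRUE`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.qct_fit <- function(object, drop_intercept = TRUE, ...) {
  df <- object$coefs
  if (drop_intercept) df <- df[df$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo,
                                          xmax = .data$ci_hi)) +
    ggplot2::labs(
      x = paste0("estimate (", object$scale, ")"), y = NULL,
      title = object$spec$endpoint,
      subtitle = object$formula
    ) +
    ggplot2::theme_minimal()
}

#' Plot an airway tree in frontal projection
#'
#' Centerlines projected on the x-z plane, coloured by lobe; linewidth
#' scales with the lumen diameter (measured if available, otherwise ground
#' truth).
#'
#' @param object an [airway_tree()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.airway_tree <- function(object, ...) {
  ld <- if ("lumen_diameter_mm" %in% names(object)) object$lumen_diameter_mm
  else if ("lumen_diameter_true_mm" %in% names(object)) object$lumen_diameter_true_mm
  else rep(1, nrow(object))
  segs <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    cl <- object$centerline[[i]]
    tibble::tibble(
      x = cl[-nrow(cl), 1], z = cl[-nrow(cl), 3],
      xend = cl[-1, 1], zend = cl[-1, 3],
      lobe = if (!"lobe" %in% names(object)) NA_character_ else object$lobe[i],
      lumen = ld[i]
    )
  }))
  ggplot2::ggplot(segs, ggplot2::aes(x = .data$x, y = .data$z,
                                     xend = .data$xend, yend = .data$zend,
                                     colour = .data$lobe,
                                     linewidth = .data$lumen)) +
    ggplot2::geom_segment(lineend = "round") +
    ggplot2::scale_linewidth(range = c(0.3, 3), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)", colour = "lobe") +
    ggplot2::theme_minimal()
}

#' Bar chart of nested air-trapping percentages per region
#'
#' @param at_table output of [air_trapping_table()].
#' @return a ggplot object.
#' @export
plot_air_trapping <- function(at_table) {
  long <- tidyr::pivot_longer(
    at_table[, c("region", "A1", "A2", "A3")],
    cols = c("A1", "A2", "A3"),
    names_to = "severity", values_to = "percent"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region, y = .data$percent,
                                     fill = .data$severity)) +
    ggplot2::geom_col(position = "identity", alpha = 0.85) +
    ggplot2::labs(x = NULL, y = "% of analysed expiratory parenchyma",
                  fill = NULL,
                  title = "Air trapping under nested thresholds") +
    ggplot2::theme_minimal()
}
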