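#' Plot the fitted normative Gaussians
#'
#' One Gaussian density curve per area over the thickness axis, the
#' visual analogue of the normative table.
#'
#' @param object A `normative_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.normative_table <- function(object, ...) {
  grid <- tidyr::crossing(
    tibble::as_tibble(object)[, c("area", "mean_mm", "sd_mm")],
    x = seq(min(object$mean_mm - 4 * object$sd_mm),
            max(object$mean_mm + 4 * object$sd_mm), length.out = 200)
  ) |>
    dplyr::mutate(density = stats::dnorm(.data$x, .data$mean_mm, .data$sd_mm))
  ggplot2::ggplot(grid, ggplot2::aes(.data$x, .data$density,
                                     colour = .data$area)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "cortical thickness (mm)", y = "density",
                  title = "Normative Gaussian model per visual area") +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of area thickness against the Gaussian fit
#'
#' @param normative A `normative_table` (its `"qq"` attribute is used).
#' @param areas Optional subset of areas to show.
#' @return A ggplot with one facet per area and the identity line.
#' @export
plot_qq <- function(normative, areas = NULL) {
  qq <- attr(normative, "qq")
  if (is.null(qq)) stop("no QQ data attached to this table", call. = FALSE)
  if (!is.null(areas)) qq <- qq[qq$area %in% areas, ]
  ggplot2::ggplot(qq, ggplot2::aes(.data$theoretical, .data$sample)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~area, scales = "free") +
    ggplot2::labs(x = "theoretical quantile (mm)", y = "sample quantile (mm)") +
    ggplot2::theme_minimal()
}

#' Heatmap of the inter-areal correlation matrix
#'
#' @param object An `area_corr`.
#' @param ... Unused.
#' @return A ggplot tile map in the canonical area order.
#' @export
autoplot.area_corr <- function(object, ...) {
  long <- tidy.area_corr(object) |>
    dplyr::mutate(
      area1 = factor(.data$area1, levels = rownames(object)),
      area2 = factor(.data$area2, levels = rownames(object))
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$area1, .data$area2,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Dendrogram of the area cluster tree
#'
#' @param x An `area_clusters`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.area_clusters <- function(x, ...) {
  graphics::plot(x$hclust, hang = -1,
                 xlab = "", sub = "", main = "Inter-areal cluster tree", ...)
  graphics::abline(h = x$cut_height, lty = 2, col = "grey50")
}

#' Hemispheric bias per area with significance annotation
#'
#' @param object A `bias_table`.
#' @param ... Unused.
#' @return A ggplot of left-minus-right bias per area, effect-size
#'   categories as colour.
#' @export
autoplot.bias_table <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(area = factor(.data$area, levels = .data$area))
  ggplot2::ggplot(dat, ggplot2::aes(.data$area, .data$bias_mm,
                                    fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "bias, left - right (mm)",
                  fill = "effect size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
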