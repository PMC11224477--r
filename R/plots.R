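#' Plot an observed filling series with its fitted curve
#'
#' @param object A [fit_logistic()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grainfill_fit
#' @export
autoplot.grainfill_fit <- function(object, ...) {
  if (is.null(object$fit)) rlang::abort("cannot plot a failed fit")
  grid <- tibble::tibble(
    dap = seq(0, max(object$data$dap) * 1.1, length.out = 200)
  )
  grid$weight <- predict(object, grid$dap)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dap,
                                            y = .data$weight)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Days after pollination",
                  y = "100-grain dry weight (g)") +
    ggplot2::theme_minimal()
}

#' Plot fitted filling curves across treatments
#'
#' One panel per variety (and year, if present), curves coloured by
#' tillage; observed means optionally overlaid.
#'
#' @param fits Tibble from [fit_filling()].
#' @param t_max Right edge of the time axis (d).
#' @return A ggplot.
#' @export
plot_filling_curves <- function(fits, t_max = 60) {
  fits <- fits[!is.na(fits$A), ]
  grid <- tidyr::expand_grid(fits, dap = seq(0, t_max, length.out = 150))
  grid$weight <- logistic_weight(grid$dap, grid$A, grid$B, grid$C)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$dap, y = .data$weight,
                                          colour = .data$tillage,
                                          group = interaction(
                                            .data$tillage,
                                            grid[["replicate"]] %||% 1
                                          ))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Days after pollination",
                  y = "100-grain dry weight (g)", colour = "Tillage") +
    ggplot2::theme_minimal()
  facets <- intersect(c("year", "variety"), names(fits))
  if (length(facets)) {
    p <- p + ggplot2::facet_wrap(facets)
  }
  p
}

#' Biplot of a correlation PCA
#'
#' Scores on the first two components with variable loadings drawn as
#' arrows (scaled for legibility).
#'
#' @param object A [pca_correlation()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grainfill_pca
#' @export
autoplot.grainfill_pca <- function(object, ...) {
  sc <- tibble::as_tibble(object$scores[, 1:2, drop = FALSE],
                          .name_repair = "minimal")
  names(sc) <- c("PC1", "PC2")
  ld <- tibble::as_tibble(object$loadings[, 1:2, drop = FALSE],
                          rownames = "variable", .name_repair = "minimal")
  names(ld)[2:3] <- c("PC1", "PC2")
  scale_f <- max(abs(sc$PC1), abs(sc$PC2)) * 0.8
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * scale_f,
                   yend = .data$PC2 * scale_f),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick"
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * scale_f * 1.08,
                   y = .data$PC2 * scale_f * 1.08,
                   label = .data$variable),
      colour = "firebrick", size = 3
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
}
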