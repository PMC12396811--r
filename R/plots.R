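#' Plot a fitted Gamma mixture over the windowed count distribution
#'
#' @param object a `gamma_mixture_fit`.
#' @param ... unused.
#' @return A ggplot: empirical probabilities (bars) with the fitted mixture
#'   density overlaid.
#' @export
autoplot.gamma_mixture_fit <- function(object, ...) {
  emp <- tibble::as_tibble(object$data)
  grid <- seq(min(emp$value) - 1, max(emp$value) + 1, length.out = 400)
  dens <- tibble::tibble(x = grid, y = mixture_pdf(grid, object))
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$value, y = .data$prob)) +
    ggplot2::geom_col(fill = "grey70", width = 0.9) +
    ggplot2::geom_line(data = dens, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "mRNA count", y = "probability",
                  title = sprintf("Gamma mixture (m = %d), KL = %.4g",
                                  object$m, object$kl)) +
    ggplot2::theme_minimal()
}

#' Plot burst size and frequency along the trajectory
#'
#' @param object a [burst_trajectory()] result.
#' @param ... unused.
#' @return A ggplot of BS and BF against pseudotime, coloured by branch.
#' @export
autoplot.burst_trajectory <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("BS", "BF"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_mid, y = .data$value,
                                     colour = .data$branch)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "pseudotime", y = NULL,
                  title = paste0("Burst kinetics: ", attr(object, "gene"))) +
    ggplot2::theme_minimal()
}

#' Plot a regulation-strength series
#'
#' @param object a [regulation_strength_series()] result.
#' @param ... unused.
#' @return A ggplot of per-window importance against pseudotime.
#' @export
autoplot.regulation_trend <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$t_mid, y = .data$importance,
                               colour = .data$branch)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "pseudotime", y = "regulation strength",
                  title = sprintf("%s → %s", attr(object, "regulator"),
                                  attr(object, "target"))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a Wasserstein distance matrix
#'
#' @param object a [wasserstein_matrix()].
#' @param ... unused.
#' @return A ggplot tile heatmap.
#' @export
autoplot.wasserstein_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::as_tibble(m, rownames = "item_a") |>
    tidyr::pivot_longer(-"item_a", names_to = "item_b",
                        values_to = "distance")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item_a, y = .data$item_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "W1") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Filled-contour plot of a joint density
#'
#' @param object a [joint_density()].
#' @param ... unused.
#' @return A ggplot raster of the 2D density.
#' @export
autoplot.joint_density <- function(object, ...) {
  df <- expand.grid(x = object$x, y = object$y)
  df$z <- as.vector(object$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "density") +
    ggplot2::theme_minimal()
}
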