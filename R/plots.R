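# ggplot2 quick-look graphics.

# Points on the boundary of the standard ellipse (Mahalanobis^2 = r2).
ellipse_path <- function(center, cov_matrix, radius2 = 1, n = 181) {
  eig <- eigen(cov_matrix, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(cos(theta), sin(theta)) * sqrt(radius2)
  pts <- t(eig$vectors %*% (sqrt(pmax(eig$values, 0)) * circ))
  tibble::tibble(d13c_mean = pts[, 1] + center[1],
                 d15n_mean = pts[, 2] + center[2])
}

#' Isotope bi-plot with standard ellipses per population-year
#'
#' Plots territory-year observations in d13C-d15N space, one standard
#' ellipse (Mahalanobis distance 1, the ~40% core area) per
#' population-year, and optionally the TDF-shifted source means.
#'
#' @param observations Tibble from [aggregate_siblings()].
#' @param sources Optional source tibble; shifted means are overlaid.
#' @return A ggplot object.
#' @export
plot_isotope_biplot <- function(observations, sources = NULL) {
  assert_columns(observations,
                 c("population", "year", "d13c_mean", "d15n_mean"),
                 what = "`observations`")
  obs <- dplyr::mutate(observations,
                       group = paste(.data$population, .data$year,
                                     sep = "-"))
  ell <- obs |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(g, key) {
      X <- cbind(g$d13c_mean, g$d15n_mean)
      if (nrow(X) < 3) return(tibble::tibble())
      ellipse_path(colMeans(X), stats::cov(X))
    }) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$d13c_mean,
                                         y = .data$d15n_mean,
                                         colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_path(data = ell, linewidth = 0.4) +
    ggplot2::labs(x = expression(delta^13 * C ~ ("‰")),
                  y = expression(delta^15 * N ~ ("‰")),
                  colour = "Population-year") +
    ggplot2::theme_minimal()
  if (!is.null(sources)) {
    src <- apply_tdf(sources)
    p <- p + ggplot2::geom_point(
      data = src,
      ggplot2::aes(x = .data$mu_adj_d13c, y = .data$mu_adj_d15n),
      inherit.aes = FALSE, shape = 4, size = 2.5) +
      ggplot2::geom_text(
        data = src,
        ggplot2::aes(x = .data$mu_adj_d13c, y = .data$mu_adj_d15n,
                     label = .data$category),
        inherit.aes = FALSE, vjust = -0.8, size = 3)
  }
  p
}

#' @describeIn plot_isotope_biplot Posterior diet proportions with 95%
#'   credible intervals for a single mixing fit.
#' @param object A `mixing_fit`.
#' @param ... Unused.
#' @export
autoplot.mixing_fit <- function(object, ...) {
  est <- dplyr::mutate(object$estimates,
                       category = factor(.data$category,
                                         levels = rev(object$estimates$category)))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$mean, y = .data$category)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$q025,
                                          xmax = .data$q975)) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "Posterior diet proportion", y = NULL) +
    ggplot2::theme_minimal()
}

#' Akaike-weight profile of a model ranking
#'
#' @param object A `model_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_ranking <- function(object, ...) {
  tbl <- dplyr::mutate(object$table,
                       definition = factor(.data$definition,
                                           levels = rev(object$table$definition)))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$aiccw,
                                    y = .data$definition,
                                    fill = .data$supported)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::theme_minimal()
}
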