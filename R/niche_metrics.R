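as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    return(unname(points))
  }
  assert_columns(points, c("d13c_mean", "d15n_mean"), what = "`points`")
  unname(cbind(points$d13c_mean, points$d15n_mean))
}

#' Layman metrics of an isotopic point cloud
#'
#' Summarises the structure of a set of territory-year observations in
#' d13C-d15N space: `cr` = d13C range (max - min), `nr` = d15N range,
#' `cd` = mean Euclidean distance to the centroid (trophic diversity),
#' `sdnnd` = standard deviation of each point's distance to its nearest
#' other point (trophic evenness).  SDNND uses the population SD
#' (denominator n), a convention fixed here and applied consistently.
#'
#' @param points A two-column matrix of (d13C, d15N) or a tibble with
#'   `d13c_mean`, `d15n_mean` (as from [aggregate_siblings()]).
#' @return A tibble with one row: `cr`, `nr`, `cd`, `sdnnd`.
#' @export
#' @examples
#' layman_metrics(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)))
layman_metrics <- function(points) {
  X <- as_point_matrix(points)
  n <- nrow(X)
  if (n < 2) stop_invalid("Need at least 2 points.")
  cr <- diff(range(X[, 1]))
  nr <- diff(range(X[, 2]))
  centroid <- colMeans(X)
  cd <- mean(sqrt((X[, 1] - centroid[1])^2 + (X[, 2] - centroid[2])^2))
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nnd <- apply(D, 1, min)
  sdnnd <- sqrt(mean((nnd - mean(nnd))^2))  # population SD
  tibble::tibble(cr = cr, nr = nr, cd = cd, sdnnd = sdnnd)
}

#' Bootstrapped Layman metrics at a fixed resample size
#'
#' Repeatedly resamples `m` points with replacement, computes the four
#' Layman metrics on each resample (one shared resample per replicate for
#' all four), and returns the mean over replicates.  Resampling at the
#' minimum territory count shared across population-years makes the
#' metrics comparable despite unequal sample sizes.
#'
#' @param points Point matrix or tibble (see [layman_metrics()]).
#' @param m Resample size (<= number of points).
#' @param B Number of bootstrap replicates (the reference protocol uses
#'   10000).
#' @param seed Integer seed.
#' @param replace Resample with replacement (default `TRUE`); `FALSE`
#'   gives the subsampling-without-replacement convention.
#' @return A tibble with one row: bootstrapped means `cr_b`, `nr_b`,
#'   `cd_b`, `sdnnd_b`, plus `m` and `B`.
#' @export
bootstrap_metrics <- function(points, m, B = 10000L, seed = NULL,
                              replace = TRUE) {
  X <- as_point_matrix(points)
  n <- nrow(X)
  if (m > n) stop_invalid("`m` must not exceed the number of points.")
  if (m < 2) stop_invalid("`m` must be at least 2.")
  if (B < 1) stop_invalid("`B` must be >= 1.")
  with_rng(seed, {
    acc <- matrix(NA_real_, B, 4)
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = replace)
      acc[b, ] <- as.numeric(layman_metrics(X[idx, , drop = FALSE]))
    }
    tibble::tibble(
      cr_b = mean(acc[, 1]), nr_b = mean(acc[, 2]),
      cd_b = mean(acc[, 3]), sdnnd_b = mean(acc[, 4]),
      m = m, B = B
    )
  })
}

#' Standard ellipse area of a bivariate isotopic sample
#'
#' \eqn{SEA = \pi \sqrt{\det \hat\Sigma}} with \eqn{\hat\Sigma} the
#' sample covariance (denominator n - 1).  The small-sample corrected
#' version multiplies by \eqn{(n-1)/(n-2)}.  The standard ellipse
#' (Mahalanobis distance^2 <= 2) covers the "core" niche, about 40% of
#' the data for bivariate normal samples.
#'
#' @param points Point matrix or tibble.
#' @param corrected Return SEAc (default `TRUE`) or uncorrected SEA.
#' @return Area in per-mil squared.
#' @export
standard_ellipse_area <- function(points, corrected = TRUE) {
  X <- as_point_matrix(points)
  n <- nrow(X)
  if (n < 3) stop_invalid("Need at least 3 points for an ellipse.")
  S <- stats::cov(X)
  d <- det(S)
  if (!is.finite(d) || d <= 0) {
    rlang::abort("Degenerate (singular) covariance: points are collinear.",
                 class = "isoniche_degenerate_geometry")
  }
  sea <- pi * sqrt(d)
  if (corrected) sea * (n - 1) / (n - 2) else sea
}

#' Fraction of points inside the standard ellipse
#'
#' The standard ellipse has semi-axes equal to the principal standard
#' deviations, i.e. its boundary is the set of points at squared
#' Mahalanobis distance 1 from the centroid.  For bivariate normal data
#' the squared Mahalanobis distance follows a chi-squared(2) law, so the
#' expected fraction inside is \eqn{1 - e^{-1/2} \approx 0.3935} — the
#' "core" roughly-40%-of-the-data niche area.
#'
#' @param points Point matrix or tibble.
#' @param center,cov_matrix Optional ellipse parameters; default: sample
#'   mean and covariance of `points`.
#' @param radius2 Squared Mahalanobis radius of the ellipse boundary
#'   (default 1, the standard ellipse whose semi-axes are the principal
#'   SDs).
#' @return Fraction of points with Mahalanobis distance^2 <= `radius2`.
#' @export
ellipse_containment <- function(points, center = NULL, cov_matrix = NULL,
                                radius2 = 1) {
  X <- as_point_matrix(points)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(cov_matrix)) cov_matrix <- stats::cov(X)
  if (!is.finite(det(cov_matrix)) || det(cov_matrix) <= 0) {
    rlang::abort("Degenerate ellipse covariance.",
                 class = "isoniche_degenerate_geometry")
  }
  d2 <- stats::mahalanobis(X, center, cov_matrix)
  mean(d2 <= radius2)
}

#' Per population-year isotopic niche metrics table
#'
#' Computes, for each population-year, the mean isotope values, the four
#' bootstrapped Layman metrics (resample size `m` = the minimum
#' territory count across population-years, by default) and the
#' corrected standard ellipse area, mirroring the standard report layout.
#'
#' @param observations Territory-year tibble from [aggregate_siblings()].
#' @param B Bootstrap replicates (default 10000).
#' @param m Resample size; default `NULL` uses the minimum group size.
#' @param seed Integer seed for the bootstrap.
#' @return A tibble with one row per population-year: `population`,
#'   `year`, `mean_d13c`, `mean_d15n`, `cr_b`, `nr_b`, `cd_b`, `sdnnd_b`,
#'   `sea`, `sea_c`, `n`.
#' @export
niche_metrics <- function(observations, B = 10000L, m = NULL, seed = NULL) {
  assert_columns(observations,
                 c("population", "year", "d13c_mean", "d15n_mean"),
                 what = "`observations`")
  groups <- observations |>
    dplyr::group_by(.data$population, .data$year) |>
    dplyr::group_split()
  sizes <- vapply(groups, nrow, integer(1))
  if (is.null(m)) m <- min(sizes)
  purrr::map2_dfr(groups, seq_along(groups), function(g, i) {
    X <- as_point_matrix(g)
    boot <- bootstrap_metrics(X, m = m, B = B,
                              seed = if (is.null(seed)) NULL else seed + i)
    tibble::tibble(
      population = g$population[1], year = g$year[1],
      mean_d13c = mean(X[, 1]), mean_d15n = mean(X[, 2]),
      cr_b = boot$cr_b, nr_b = boot$nr_b, cd_b = boot$cd_b,
      sdnnd_b = boot$sdnnd_b,
      sea = standard_ellipse_area(X, corrected = FALSE),
      sea_c = standard_ellipse_area(X, corrected = TRUE),
      n = nrow(X)
    )
  })
}
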