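#' Shannon-Weaver diet diversity
#'
#' \eqn{H' = -\sum_k p_k \ln p_k} (natural log, nats), with
#' \eqn{0 \ln 0 := 0}.  For K categories H' ranges from 0 (complete
#' specialisation) to \eqn{\ln K} (uniform diet); with K = 8, the ceiling
#' is \eqn{\ln 8 \approx 2.079}.
#'
#' @param p Nonnegative numeric vector summing to 1 (a diet vector).
#' @return H' in nats.
#' @export
#' @examples
#' shannon_diversity(rep(1 / 8, 8))   # ln 8
shannon_diversity <- function(p) {
  if (any(p < 0)) stop_invalid("Diet proportions must be nonnegative.")
  assert_simplex(p, what = "p")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Proportional similarity between a diet and the population mean
#'
#' \eqn{PS_i = 1 - \frac{1}{2}\sum_k |p_{ik} - q_k|}: 1 when the
#' territory's diet equals the population mean diet, approaching 0 as the
#' two diets become disjoint.  Equals 1 minus the total-variation
#' distance between the two diet distributions.
#'
#' @param p_i Territory diet vector (simplex).
#' @param q Population mean diet vector (simplex, same length).
#' @return PS in [0, 1].
#' @export
proportional_similarity <- function(p_i, q) {
  if (length(p_i) != length(q)) {
    stop_invalid("`p_i` and `q` must have the same length.")
  }
  assert_simplex(p_i, what = "p_i")
  assert_simplex(q, what = "q")
  1 - 0.5 * sum(abs(p_i - q))
}

#' Population mean diet
#'
#' Unweighted componentwise mean of a set of territory diet vectors,
#' renormalised onto the simplex.
#'
#' @param diets A tibble with `p_OC` .. `p_TL` columns (one row per
#'   territory-year) or a numeric matrix with one diet per row.
#' @return Named numeric simplex vector q.
#' @export
population_mean_diet <- function(diets) {
  P <- if (is.matrix(diets)) diets else diet_matrix(diets)
  if (nrow(P) == 0) stop_invalid("Need at least one diet vector.")
  renormalize(colMeans(P))
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks
#' (average ranks for ties).  The two-sided p-value is exact by full
#' permutation enumeration for n <= `exact_max` (default 9), and uses the
#' t approximation with n - 2 degrees of freedom otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact_max Largest n for which the p-value is computed by full
#'   n! enumeration.
#' @return A tibble with `rho`, `p_value`, `n`, `method`.  `rho` is `NA`
#'   (with a warning) when either variable has zero rank variance.
#' @export
spearman_test <- function(x, y, exact_max = 9L) {
  n <- length(x)
  if (length(y) != n) stop_invalid("`x` and `y` must have equal length.")
  if (n < 3) stop_invalid("Need at least 3 observations.")
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop_invalid("`x` and `y` must be finite.")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    rlang::warn("Zero rank variance: Spearman's rho is undefined.")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          n = n, method = "undefined"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perm <- all_permutations(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    # rho for every permutation of y against fixed x
    num <- matrix(ryc[perm], nrow = nrow(perm)) %*% rxc
    rho_perm <- as.vector(num) / (sqrt(sum(rxc^2)) * sqrt(sum(ryc^2)))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = min(p, 1), n = n, method = method)
}

# All permutations of 1:n as an n! x n integer matrix.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, p + (p >= i))
  }))
}

#' Per-territory diet diversity and specificity indices
#'
#' Appends Shannon diversity `h_prime` and proportional similarity `ps_i`
#' (overlap with the population mean diet q) to a table of territory-year
#' diet vectors.  Diet vectors are renormalised onto the simplex first
#' (posterior means are normalised up to rounding).
#'
#' @param diets Tibble with key columns and `p_OC` .. `p_TL`.
#' @param leave_one_out If `TRUE`, each territory's q excludes itself;
#'   default `FALSE` (q is the full-population mean, as when an
#'   individual's overlap with the whole study area is wanted).
#' @return The input tibble with `h_prime` and `ps_i` columns.
#' @export
compute_diet_indices <- function(diets, leave_one_out = FALSE) {
  P <- diet_matrix(diets)
  P <- t(apply(P, 1, renormalize))
  q <- renormalize(colMeans(P))
  n <- nrow(P)
  h <- apply(P, 1, shannon_diversity)
  ps <- vapply(seq_len(n), function(i) {
    qi <- if (leave_one_out && n > 1) renormalize(colMeans(P[-i, , drop = FALSE])) else q
    proportional_similarity(P[i, ], qi)
  }, numeric(1))
  dplyr::mutate(diets, h_prime = h, ps_i = ps)
}

#' Screen prey categories for "preferred prey" signal
#'
#' Correlates each category's consumption share against territory diet
#' diversity H' across territory-years (Spearman).  Preferred prey are
#' expected to show significantly negative rho: the more a territory
#' relies on them, the narrower its diet.
#'
#' @param diets Tibble with `p_OC` .. `p_TL` (territory-year rows).
#' @param alpha Two-sided significance level for the preferred flag
#'   (default 0.05).
#' @return A tibble with one row per category: `category`, `rho`,
#'   `p_value`, `preferred` (significantly negative rho).
#' @export
preferred_prey_screen <- function(diets, alpha = 0.05) {
  P <- diet_matrix(diets)
  if (nrow(P) < 5) stop_invalid("Need at least 5 territory-years.")
  h <- apply(t(apply(P, 1, renormalize)), 1, shannon_diversity)
  purrr::map_dfr(seq_along(PREY_CATEGORIES), function(k) {
    share <- P[, k]
    if (stats::sd(share) == 0) {
      rlang::warn(sprintf(
        "Category %s has constant share: rho undefined.",
        PREY_CATEGORIES[k]))
      return(tibble::tibble(category = PREY_CATEGORIES[k],
                            rho = NA_real_, p_value = NA_real_,
                            preferred = NA))
    }
    st <- spearman_test(share, h)
    tibble::tibble(
      category = PREY_CATEGORIES[k],
      rho = st$rho, p_value = st$p_value,
      preferred = !is.na(st$rho) && st$rho < 0 && st$p_value < alpha
    )
  })
}
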