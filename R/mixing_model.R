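# SIAR-class Bayesian stable-isotope mixing model.
#
# Consumer isotope values X_ij (consumer i, isotope j) are modelled as
#   X_ij ~ Normal( sum_k p_k (mu_jk + lambda_j),
#                  sum_k p_k^2 (omega_jk^2 + tau_j^2) + sigma_j^2 )
# with diet proportions p on the simplex under a Dirichlet prior and a
# Uniform(0, sigma_upper) prior on each residual SD sigma_j.  TDF
# uncertainty (tau) enters the variance term rather than being resampled
# per draw, matching the cited model's mean/variance composition.

#' Specify a mixing model problem
#'
#' Bundles consumers, TDF-shifted sources, priors and MCMC settings.
#' Sources may be given as a standard two-isotope source tibble (from
#' [pool_sources()] or [generate_sources()]) or, for reduced problems,
#' as a list with matrices `mu` (K x J source means), `omega` (K x J
#' source SDs) and vectors `tdf`, `tdf_sd` (length J); consumers
#' correspondingly as a tibble with `d13c`/`d15n` or an n x J matrix.
#'
#' @param consumers Consumer isotope values (tibble or matrix; >= 1 row).
#' @param sources Source distributions (tibble or list, see above).
#' @param prior_alpha Dirichlet prior concentration, scalar or length-K
#'   (default 1: flat over the simplex).
#' @param sigma_upper Upper bound of the uniform residual-SD prior, in
#'   per-mil (default 20, far beyond observed isotopic spreads).
#' @param sigma_fixed Optional length-J vector fixing the residual SDs
#'   (no sigma sampling); used mainly for reduced-problem checks.
#' @param chains Number of MCMC chains (>= 2 so split-Rhat is defined).
#' @param burn_in Adaptation/warm-up iterations per chain.
#' @param n_samples Post-warm-up iterations per chain.
#' @param thin Keep every `thin`-th draw.
#' @return An object of class `mixing_spec`.
#' @export
mixing_spec <- function(consumers, sources, prior_alpha = 1,
                        sigma_upper = 20, sigma_fixed = NULL,
                        chains = 2L, burn_in = 10000L,
                        n_samples = 40000L, thin = 10L) {
  if (is.data.frame(sources)) {
    src <- apply_tdf(sources)
    src <- src[match(PREY_CATEGORIES[PREY_CATEGORIES %in% src$category],
                     src$category), ]
    mu <- cbind(src$mu_d13c, src$mu_d15n)
    omega <- cbind(src$omega_d13c, src$omega_d15n)
    tdf <- c(src$tdf_d13c[1], src$tdf_d15n[1])
    tdf_sd <- c(src$tdf_sd_d13c[1], src$tdf_sd_d15n[1])
    categories <- src$category
  } else {
    mu <- as.matrix(sources$mu)
    omega <- as.matrix(sources$omega)
    tdf <- sources$tdf
    tdf_sd <- sources$tdf_sd
    categories <- sources$categories %||%
      paste0("S", seq_len(nrow(mu)))
  }
  K <- nrow(mu); J <- ncol(mu)
  if (K < 1) stop_invalid("Need at least one source.")
  if (is.data.frame(consumers)) {
    assert_columns(consumers, c("d13c", "d15n"), what = "`consumers`")
    X <- unname(cbind(consumers$d13c, consumers$d15n))
  } else {
    X <- as.matrix(consumers)
  }
  if (ncol(X) != J) stop_invalid("Consumer/source isotope dimensions differ.")
  if (nrow(X) < 1) stop_invalid("Need at least one consumer.")
  if (any(!is.finite(X))) stop_invalid("Consumer values must be finite.")
  alpha <- rep_len(prior_alpha, K)
  if (any(alpha <= 0)) stop_invalid("`prior_alpha` must be > 0.")
  if (!is.null(sigma_fixed)) {
    sigma_fixed <- rep_len(sigma_fixed, J)
    if (any(sigma_fixed < 0)) stop_invalid("`sigma_fixed` must be >= 0.")
  }
  if (chains < 2) stop_invalid("Need >= 2 chains for split-Rhat.")
  structure(list(
    X = X,
    mu_shift = sweep(mu, 2, tdf, `+`),      # K x J, mu + lambda
    w2 = sweep(omega^2, 2, tdf_sd^2, `+`),  # K x J, omega^2 + tau^2
    categories = categories, K = K, J = J,
    alpha = alpha, sigma_upper = sigma_upper, sigma_fixed = sigma_fixed,
    chains = as.integer(chains), burn_in = as.integer(burn_in),
    n_samples = as.integer(n_samples), thin = as.integer(thin)
  ), class = "mixing_spec")
}

#' Mixing model log likelihood
#'
#' Sum over consumers and isotopes of the Normal log density with mixture
#' mean \eqn{\sum_k p_k(\mu_{jk}+\lambda_j)} and variance
#' \eqn{\sum_k p_k^2(\omega_{jk}^2+\tau_j^2) + \sigma_j^2}.  Returns
#' `-Inf` (not an error) when an isotope's total variance is zero and
#' any consumer sits off the mixture mean.
#'
#' @param p Diet proportion vector on the simplex (length K).
#' @param sigma Residual SD per isotope (length J, >= 0).
#' @param spec A `mixing_spec`.
#' @return Log density (scalar).
#' @export
log_likelihood <- function(p, sigma, spec) {
  assert_simplex(p, what = "p")
  if (any(sigma < 0)) stop_invalid("`sigma` must be >= 0.")
  ll_core(p, sigma^2, spec$X, spec$mu_shift, spec$w2,
          nrow(spec$X), colSums(spec$X), colSums(spec$X^2))
}

# Core likelihood evaluation using precomputed sufficient statistics.
ll_core <- function(p, sig2, X, muL, w2, n, sx, ssx) {
  m <- as.vector(p %*% muL)           # length J
  v <- as.vector((p * p) %*% w2) + sig2
  if (any(v <= 0)) {
    dev_ok <- vapply(which(v <= 0), function(j) {
      all(abs(X[, j] - m[j]) < 1e-12)
    }, logical(1))
    return(if (all(dev_ok)) Inf else -Inf)
  }
  sum(-0.5 * n * log(2 * pi * v) -
        0.5 * (ssx - 2 * m * sx + n * m^2) / v)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# One MCMC chain.  Returns list(p = draws x K, sigma = draws x J).
run_chain <- function(spec, seed, init_jitter) {
  X <- spec$X; muL <- spec$mu_shift; w2 <- spec$w2
  K <- spec$K; J <- spec$J
  n <- nrow(X); sx <- colSums(X); ssx <- colSums(X^2)
  alpha <- spec$alpha
  upper <- spec$sigma_upper
  fixed <- !is.null(spec$sigma_fixed)
  set.seed(seed)
  z <- log(alpha / sum(alpha)) + rnorm(K, 0, init_jitter)
  z <- z - mean(z)
  sigma <- if (fixed) spec$sigma_fixed else
    pmin(upper * 0.9, exp(rnorm(J, 0, 0.5)))
  p <- softmax(z)
  # target on z: loglik + sum(alpha * log p)  (Dirichlet prior + softmax
  # Jacobian); uniform sigma prior contributes only its support.
  lt <- ll_core(p, sigma^2, X, muL, w2, n, sx, ssx) + sum(alpha * log(p))
  step_z <- 0.5; step_s <- 0.25
  acc_z <- 0L; acc_s <- 0L; adapt_block <- 50L
  n_iter <- spec$burn_in + spec$n_samples
  keep <- seq(spec$burn_in + spec$thin, n_iter, by = spec$thin)
  out_p <- matrix(NA_real_, length(keep), K)
  out_s <- matrix(NA_real_, length(keep), J)
  ki <- 1L
  for (it in seq_len(n_iter)) {
    # update p via centered log-ratio random walk
    z_new <- z + rnorm(K, 0, step_z)
    z_new <- z_new - mean(z_new)
    p_new <- softmax(z_new)
    lt_new <- ll_core(p_new, sigma^2, X, muL, w2, n, sx, ssx) +
      sum(alpha * log(p_new))
    if (is.finite(lt_new) && log(runif(1)) < lt_new - lt) {
      z <- z_new; p <- p_new; lt <- lt_new; acc_z <- acc_z + 1L
    }
    # update sigma via reflected random walk inside (0, upper)
    if (!fixed) {
      s_new <- sigma + rnorm(J, 0, step_s)
      s_new <- abs(s_new)
      s_new <- ifelse(s_new > upper, 2 * upper - s_new, s_new)
      if (all(s_new >= 0 & s_new <= upper)) {
        lt_new <- ll_core(p, s_new^2, X, muL, w2, n, sx, ssx) +
          sum(alpha * log(p))
        if (is.finite(lt_new) && log(runif(1)) < lt_new - lt) {
          sigma <- s_new; lt <- lt_new; acc_s <- acc_s + 1L
        }
      }
    }
    # adapt step sizes toward ~30% acceptance during burn-in
    if (it <= spec$burn_in && it %% adapt_block == 0L) {
      step_z <- max(1e-3, step_z * exp((acc_z / adapt_block - 0.3)))
      acc_z <- 0L
      if (!fixed) {
        step_s <- max(1e-3, step_s * exp((acc_s / adapt_block - 0.3)))
        acc_s <- 0L
      }
    }
    if (ki <= length(keep) && it == keep[ki]) {
      out_p[ki, ] <- p
      out_s[ki, ] <- sigma
      ki <- ki + 1L
    }
  }
  list(p = out_p, sigma = out_s)
}

# Split-Rhat over a list of per-chain draw matrices (draws x params).
split_rhat <- function(chains) {
  n <- nrow(chains[[1]])
  half <- floor(n / 2)
  seqs <- list()
  for (ch in chains) {
    seqs <- c(seqs, list(ch[seq_len(half), , drop = FALSE],
                         ch[(n - half + 1):n, , drop = FALSE]))
  }
  m <- length(seqs)
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    x <- vapply(seqs, function(s) mean(s[, j]), numeric(1))
    w <- vapply(seqs, function(s) stats::var(s[, j]), numeric(1))
    W <- mean(w)
    B <- half * stats::var(x)
    if (W < 1e-300) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
}

ess_basic <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  if (requireNamespace("coda", quietly = TRUE)) {
    return(as.numeric(coda::effectiveSize(x)))
  }
  rho <- stats::acf(x, plot = FALSE, lag.max = min(100, n - 1))$acf[-1]
  pos <- which(rho < 0.05)[1]
  if (!is.na(pos)) rho <- rho[seq_len(pos)]
  n / (1 + 2 * sum(rho))
}

#' Fit the Bayesian mixing model
#'
#' Samples diet proportions (and residual SDs) by random-walk Metropolis
#' on centered-log-ratio transformed proportions with adaptive step
#' scaling during burn-in.  Convergence is gated on split-Rhat: if any
#' parameter exceeds `rhat_max` the chains are re-run with doubled
#' lengths up to `max_extensions` times, after which a diagnostic error
#' carrying the Rhat table is raised.
#'
#' @param spec A `mixing_spec`.
#' @param seed Integer seed (chain c uses `seed + c`).
#' @param rhat_max Convergence gate on split-Rhat (default 1.05).
#' @param max_extensions Times the chain lengths may be doubled on a
#'   failed gate (default 2).
#' @return An object of class `mixing_fit` with elements `estimates`
#'   (per-source posterior mean, sd, 2.5/97.5 percentiles, Rhat, ESS),
#'   `sigma_estimates`, `draws` (retained p draws, all chains, with the
#'   chain id), `rhat`, and the spec/seed used.
#' @export
fit_mixing_model <- function(spec, seed = 1L, rhat_max = 1.05,
                             max_extensions = 2L) {
  stopifnot(inherits(spec, "mixing_spec"))
  attempt <- 0L
  repeat {
    chains <- lapply(seq_len(spec$chains), function(c) {
      run_chain(spec, seed = seed + c + 7919L * attempt,
                init_jitter = 0.5 + 0.5 * (c - 1))
    })
    fixed <- !is.null(spec$sigma_fixed)
    par_chains <- lapply(chains, function(ch) {
      if (fixed) ch$p else cbind(ch$p, ch$sigma)
    })
    rh <- split_rhat(par_chains)
    par_names <- c(spec$categories,
                   if (!fixed) paste0("sigma_", seq_len(spec$J)))
    rhat_tbl <- tibble::tibble(parameter = par_names, rhat = rh)
    if (all(rh <= rhat_max)) break
    if (attempt >= max_extensions) {
      rlang::abort(
        c("Mixing model did not converge (split-Rhat above gate).",
          sprintf("%s: Rhat = %.3f",
                  rhat_tbl$parameter[rh > rhat_max],
                  rh[rh > rhat_max])),
        class = "isoniche_convergence_error",
        rhat = rhat_tbl
      )
    }
    attempt <- attempt + 1L
    spec$burn_in <- spec$burn_in * 2L
    spec$n_samples <- spec$n_samples * 2L
  }
  P <- do.call(rbind, lapply(chains, `[[`, "p"))
  S <- do.call(rbind, lapply(chains, `[[`, "sigma"))
  chain_id <- rep(seq_len(spec$chains),
                  each = nrow(chains[[1]]$p))
  estimates <- tibble::tibble(
    category = spec$categories,
    mean = colMeans(P),
    sd = apply(P, 2, stats::sd),
    q025 = apply(P, 2, stats::quantile, probs = 0.025),
    q975 = apply(P, 2, stats::quantile, probs = 0.975),
    rhat = rh[seq_len(spec$K)],
    n_eff = apply(P, 2, ess_basic)
  )
  sigma_estimates <- tibble::tibble(
    isotope = paste0("sigma_", seq_len(spec$J)),
    mean = colMeans(S),
    sd = apply(S, 2, stats::sd),
    q025 = apply(S, 2, stats::quantile, probs = 0.025),
    q975 = apply(S, 2, stats::quantile, probs = 0.975)
  )
  structure(list(
    estimates = estimates,
    sigma_estimates = sigma_estimates,
    draws = P, sigma_draws = S, chain_id = chain_id,
    rhat = rhat_tbl, spec = spec, seed = seed,
    extensions_used = attempt
  ), class = "mixing_fit")
}

#' @export
print.mixing_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian mixing model fit: K = %d sources, %d consumers, %d chains\n",
    x$spec$K, nrow(x$spec$X), x$spec$chains))
  print(x$estimates)
  invisible(x)
}

#' Fit diet proportions for every territory-year
#'
#' Runs one independent mixing-model fit per territory-year (no
#' hierarchical pooling), on the chicks sampled in that territory.
#'
#' @param consumers Consumer tibble (`population`, `year`, `territory`,
#'   `d13c`, `d15n`).
#' @param sources Source tibble (K = 8).
#' @param seed Integer base seed; each territory-year uses a distinct
#'   derived seed.
#' @param ... Passed to [mixing_spec()] (prior, chain settings).
#' @return A list with `estimates` (long tibble: key columns, `category`,
#'   `mean`, `sd`, `q025`, `q975`, `rhat`, `n_eff`) and `diets` (wide
#'   tibble of posterior-mean diet vectors, `p_OC` .. `p_TL`).
#' @export
fit_territory_diets <- function(consumers, sources, seed = 1L, ...) {
  assert_columns(consumers,
                 c("population", "year", "territory", "d13c", "d15n"),
                 what = "`consumers`")
  groups <- consumers |>
    dplyr::group_by(.data$population, .data$year, .data$territory) |>
    dplyr::group_split()
  est <- purrr::map_dfr(seq_along(groups), function(i) {
    g <- groups[[i]]
    spec <- mixing_spec(g, sources, ...)
    fit <- fit_mixing_model(spec, seed = seed + 13L * i)
    dplyr::bind_cols(
      tibble::tibble(population = g$population[1], year = g$year[1],
                     territory = g$territory[1], n_chicks = nrow(g)),
      fit$estimates
    )
  })
  diets <- est |>
    dplyr::select("population", "year", "territory", "category", "mean") |>
    tidyr::pivot_wider(names_from = "category", values_from = "mean",
                       names_prefix = "p_")
  list(estimates = est, diets = diets)
}

#' Sensitivity of diet estimates to the trophic discrimination factors
#'
#' Refits the mixing model with the TDF means moved one isotope at a time
#' to each value of `c_values` (d13C) and `n_values` (d15N), holding the
#' TDF SDs fixed, and reports the per-source absolute change in posterior
#' mean contribution against the baseline fit (same seed), in percentage
#' points.
#'
#' @param consumers Consumer tibble with territory keys.
#' @param sources Source tibble; its `tdf_*` columns are the baseline.
#' @param c_values d13C TDF grid (default `c(1.6, 2.6)`, the +/-0.5
#'   endpoints around 2.1 of the published sensitivity protocol; the
#'   published variation spans 1.6-2.6).
#' @param n_values d15N TDF grid (default `c(2.2, 3.2)`).
#' @param seed Integer seed shared across refits.
#' @param ... Passed to [mixing_spec()].
#' @return A list with `changes` (long tibble: grid point, territory,
#'   category, baseline and refit means, `abs_change_pp`), `by_grid`
#'   (mean absolute change per grid point) and `grand_mean_abs_change_pp`
#'   (scalar, percentage points).
#' @export
tdf_sensitivity <- function(consumers, sources,
                            c_values = c(1.6, 2.6),
                            n_values = c(2.2, 3.2),
                            seed = 1L, ...) {
  base_tdf <- c(sources$tdf_d13c[1], sources$tdf_d15n[1])
  grid <- dplyr::bind_rows(
    tibble::tibble(tdf_c = c_values, tdf_n = base_tdf[2],
                   varied = "d13c"),
    tibble::tibble(tdf_c = base_tdf[1], tdf_n = n_values,
                   varied = "d15n")
  )
  grid <- dplyr::filter(grid, !(.data$tdf_c == base_tdf[1] &
                                  .data$tdf_n == base_tdf[2]))
  baseline <- fit_territory_diets(consumers, sources, seed = seed, ...)
  base_est <- dplyr::select(baseline$estimates, "population", "year",
                            "territory", "category",
                            base_mean = "mean")
  changes <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    src_i <- dplyr::mutate(sources,
                           tdf_d13c = grid$tdf_c[i],
                           tdf_d15n = grid$tdf_n[i])
    res <- tryCatch(
      fit_territory_diets(consumers, src_i, seed = seed, ...),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      rlang::warn(sprintf("Grid point (%.1f, %.1f) failed: %s",
                          grid$tdf_c[i], grid$tdf_n[i],
                          conditionMessage(res)))
      return(tibble::tibble())
    }
    res$estimates |>
      dplyr::select("population", "year", "territory", "category",
                    refit_mean = "mean") |>
      dplyr::left_join(base_est,
                       by = c("population", "year", "territory",
                              "category")) |>
      dplyr::mutate(
        tdf_c = grid$tdf_c[i], tdf_n = grid$tdf_n[i],
        varied = grid$varied[i],
        abs_change_pp = 100 * abs(.data$refit_mean - .data$base_mean)
      )
  })
  by_grid <- changes |>
    dplyr::group_by(.data$tdf_c, .data$tdf_n, .data$varied) |>
    dplyr::summarise(
      mean_abs_change_pp = mean(.data$abs_change_pp), .groups = "drop")
  list(
    changes = changes,
    by_grid = by_grid,
    grand_mean_abs_change_pp = mean(changes$abs_change_pp),
    baseline = baseline
  )
}
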