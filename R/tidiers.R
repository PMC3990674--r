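# broom-style tidiers.

#' Tidy a mixing model fit
#'
#' @param x A `mixing_fit`.
#' @param ... Unused.
#' @return Tibble of per-source posterior summaries.
#' @export
tidy.mixing_fit <- function(x, ...) {
  x$estimates
}

#' One-row diagnostics summary of a mixing model fit
#'
#' @param x A `mixing_fit`.
#' @param ... Unused.
#' @return Tibble with chain/draw counts, worst Rhat, smallest ESS.
#' @export
glance.mixing_fit <- function(x, ...) {
  tibble::tibble(
    n_sources = x$spec$K,
    n_consumers = nrow(x$spec$X),
    chains = x$spec$chains,
    draws = nrow(x$draws),
    max_rhat = max(x$rhat$rhat),
    min_n_eff = min(x$estimates$n_eff),
    extensions_used = x$extensions_used
  )
}

#' Tidy a fitted candidate GLMM
#'
#' @param x A `fitness_fit`.
#' @param ... Unused.
#' @return Tibble of fixed-effect estimates with SEs and Wald CIs.
#' @export
tidy.fitness_fit <- function(x, ...) {
  x$beta
}

#' One-row summary of a fitted candidate GLMM
#'
#' @param x A `fitness_fit`.
#' @param ... Unused.
#' @return Tibble with loglik, k, n, AICc, variance components, R2m/R2c.
#' @export
glance.fitness_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, k = x$k, n = x$n, aicc = x$aicc,
    var_territory = unname(x$varcomp["territory"]),
    var_year_population = unname(x$varcomp["year_population"]),
    r2m = x$r2m, r2c = x$r2c
  )
}

#' Tidy a candidate model ranking
#'
#' @param x A `model_ranking`.
#' @param ... Unused.
#' @return The ranked model table.
#' @export
tidy.model_ranking <- function(x, ...) {
  x$table
}

#' One-row summary of a candidate model ranking
#'
#' @param x A `model_ranking`.
#' @param ... Unused.
#' @return Tibble with model counts and the best model's statistics.
#' @export
glance.model_ranking <- function(x, ...) {
  best <- x$table[1, ]
  tibble::tibble(
    n_models = nrow(x$table),
    n_failed = length(x$failures),
    best_model = best$definition,
    best_aicc = best$aicc,
    best_aiccw = best$aiccw,
    n_supported = sum(x$table$supported)
  )
}
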