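# Territory-scale diet-fitness inference: binomial-logit GLMMs over a
# fixed candidate set, ranked by AICc with Akaike weights and
# marginal/conditional R2; plus population-scale rank correlations.

#' The fixed candidate model set
#'
#' Fifteen binomial-logit mixed models for the probability that a
#' successful pair fledges two chicks instead of one.  Pair age and mate
#' replacement appear in every model; diet terms vary: rabbit consumption
#' (OC), partridge consumption (AR), their sum (OC+AR as one covariate),
#' diet diversity H', specificity PS, quadratic effects, and the H' x PS
#' interaction.  All models carry territory and year-within-population
#' random intercepts.
#'
#' @return A tibble with `model_id`, `definition` (display label) and
#'   `terms` (list column of fixed-effect term strings beyond
#'   age/replacement).
#' @export
candidate_models <- function() {
  tibble::tibble(
    model_id = 1:15,
    definition = c(
      "Age+Replacement",
      "Age+Replacement+PSi+PSi^2",
      "Age+Replacement+H'",
      "Age+Replacement+(OC+AR)",
      "Age+Replacement+OC",
      "Age+Replacement+PSi",
      "Age+Replacement+AR",
      "Age+Replacement+H'+H'^2",
      "Age+Replacement+(OC+AR)+H'",
      "Age+Replacement+OC+H'",
      "Age+Replacement+AR+H'",
      "Age+Replacement+(OC+AR)+PSi",
      "Age+Replacement+OC+PSi",
      "Age+Replacement+AR+PSi",
      "Age+Replacement+H'+PSi+(H'*PSi)"
    ),
    terms = list(
      character(0),
      c("ps_z", "ps_z2"),
      "h_z",
      "ocar_z",
      "oc_z",
      "ps_z",
      "ar_z",
      c("h_z", "h_z2"),
      c("ocar_z", "h_z"),
      c("oc_z", "h_z"),
      c("ar_z", "h_z"),
      c("ocar_z", "ps_z"),
      c("oc_z", "ps_z"),
      c("ar_z", "ps_z"),
      c("h_z", "ps_z", "h_z:ps_z")
    )
  )
}

# Standardize continuous diet predictors; quadratics are built from the
# standardized values (stabilizes quadratic/interaction fits).
prepare_fitness_data <- function(data) {
  assert_columns(data,
                 c("population", "year", "territory", "pair_age",
                   "replacement", "fledglings", "p_OC", "p_AR",
                   "h_prime", "ps_i"),
                 what = "`data`")
  if (!all(data$fledglings %in% 1:2)) {
    stop_invalid("`fledglings` must be 1 or 2 (successful pairs only).")
  }
  zs <- function(x) if (stats::sd(x) == 0) x - mean(x) else
    (x - mean(x)) / stats::sd(x)
  data |>
    dplyr::mutate(
      two_chicks = as.integer(.data$fledglings == 2L),
      age_adult = as.integer(.data$pair_age == "adult"),
      oc_z = zs(.data$p_OC),
      ar_z = zs(.data$p_AR),
      ocar_z = zs(.data$p_OC + .data$p_AR),
      h_z = zs(.data$h_prime),
      ps_z = zs(.data$ps_i),
      h_z2 = zs(.data$h_prime)^2,
      ps_z2 = zs(.data$ps_i)^2,
      territory_f = interaction(.data$population, .data$territory,
                                drop = TRUE),
      popyear_f = interaction(.data$population, .data$year, drop = TRUE)
    )
}

#' Fit one candidate binomial GLMM
#'
#' Fits P(two chicks) ~ age + replacement + diet terms with territory and
#' population:year random intercepts by Laplace-approximate maximum
#' likelihood (lme4::glmer, logit link).
#'
#' @param terms Character vector of extra fixed-effect terms (on the
#'   standardized scale; see [candidate_models()]), or a 1-row slice of
#'   the candidate tibble.
#' @param data Territory-year table with breeding outcome and diet
#'   indices (columns of [prepare_fitness_data()] input).
#' @return A list of class `fitness_fit`: `fit` (the merMod), `beta`
#'   tibble (estimate, SE, Wald CI), `varcomp` (territory and
#'   year-within-population variances), `loglik`, `k` (fixed
#'   coefficients + 2 variance components), `n`, `aicc`, `r2m`, `r2c`.
#' @export
fit_binomial_glmm <- function(terms, data) {
  if (is.data.frame(terms)) terms <- terms$terms[[1]]
  d <- prepare_fitness_data(data)
  rhs <- paste(c("age_adult", "replacement", terms,
                 "(1 | territory_f)", "(1 | popyear_f)"),
               collapse = " + ")
  form <- stats::as.formula(paste("two_chicks ~", rhs))
  fit <- lme4::glmer(form, data = d, family = stats::binomial("logit"),
                     control = lme4::glmerControl(calc.derivs = FALSE))
  beta_hat <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- lme4::VarCorr(fit)
  var_terr <- as.numeric(vc$territory_f)
  var_py <- as.numeric(vc$popyear_f)
  ll <- as.numeric(stats::logLik(fit))
  k <- length(beta_hat) + 2L
  n <- nrow(d)
  r2 <- nakagawa_r2_components(fit, var_terr, var_py)
  structure(list(
    fit = fit,
    beta = tibble::tibble(
      term = names(beta_hat), estimate = unname(beta_hat),
      std_error = unname(se),
      conf_low = unname(beta_hat - 1.96 * se),
      conf_high = unname(beta_hat + 1.96 * se)
    ),
    varcomp = c(territory = var_terr, year_population = var_py),
    loglik = ll, k = k, n = n,
    aicc = aicc(ll, k, n),
    r2m = r2[1], r2c = r2[2]
  ), class = "fitness_fit")
}

#' Small-sample corrected AIC
#'
#' \eqn{AICc = -2 \log L + 2k + 2k(k+1)/(n-k-1)}.  Undefined when
#' \eqn{n \le k + 1}.
#'
#' @param loglik Maximized log likelihood.
#' @param k Parameter count (fixed coefficients + variance components).
#' @param n Number of observations.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    stop_invalid(sprintf(
      "AICc correction undefined for n = %d, k = %d (need n > k + 1).",
      n, k))
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from a set of AICc values
#'
#' \eqn{w_i = \exp(-\Delta_i / 2) / \sum_j \exp(-\Delta_j / 2)} with
#' \eqn{\Delta_i = AICc_i - \min AICc}: the relative likelihood that
#' model i is the best of the candidate set.  Invariant to adding a
#' constant to all AICc values; weights sum to 1.
#'
#' @param aicc_values Numeric vector of AICc (or already-differenced
#'   Delta-AICc) values.
#' @return Numeric vector of weights.
#' @export
akaike_weights <- function(aicc_values) {
  if (any(!is.finite(aicc_values))) {
    stop_invalid("AICc values must be finite.")
  }
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

nakagawa_r2_components <- function(fit, var_terr, var_py) {
  X <- stats::model.matrix(fit)
  eta_fixed <- as.vector(X %*% lme4::fixef(fit))
  # population variance of the fixed linear predictor
  var_f <- mean((eta_fixed - mean(eta_fixed))^2)
  var_d <- pi^2 / 3   # logit-link distribution-specific variance
  denom <- var_f + var_terr + var_py + var_d
  c(var_f / denom, (var_f + var_terr + var_py) / denom)
}

#' Marginal and conditional R2 for a binomial-logit mixed model
#'
#' Latent-scale variance partition: \eqn{R^2_m = \sigma^2_f / (\sigma^2_f
#' + \sigma^2_{terr} + \sigma^2_{year:pop} + \pi^2/3)} where
#' \eqn{\sigma^2_f} is the (population) variance of the fixed-effect
#' linear predictor across observations; \eqn{R^2_c} adds the random
#' intercept variances to the numerator.
#'
#' @param fit A `fitness_fit` from [fit_binomial_glmm()].
#' @return Named numeric vector `c(r2m, r2c)`.
#' @export
nakagawa_r2 <- function(fit) {
  stopifnot(inherits(fit, "fitness_fit"))
  r2 <- nakagawa_r2_components(fit$fit, fit$varcomp["territory"],
                               fit$varcomp["year_population"])
  c(r2m = unname(r2[1]), r2c = unname(r2[2]))
}

#' Fit and rank the whole candidate model set
#'
#' Fits all candidate GLMMs, sorts by AICc and reports Delta-AICc,
#' Akaike weights and marginal/conditional R2 in the standard report
#' column order.  Models whose fit fails are recorded and dropped from
#' the ranking with a warning.
#'
#' @param data Territory-year table (see [fit_binomial_glmm()]).
#' @param models Candidate tibble (default [candidate_models()]); subset
#'   it to restrict the set.
#' @return A list of class `model_ranking`: `table` (ranked tibble with
#'   `model_id`, `definition`, `aicc`, `delta_aicc`, `aiccw`, `r2m`,
#'   `r2c`, `supported` flagging Delta < 2), `fits` (list of
#'   `fitness_fit`), `failures`.
#' @export
rank_model_set <- function(data, models = candidate_models()) {
  fits <- purrr::map(seq_len(nrow(models)), function(i) {
    tryCatch(fit_binomial_glmm(models$terms[[i]], data),
             error = function(e) e)
  })
  failed <- vapply(fits, inherits, logical(1), what = "error")
  if (any(failed)) {
    rlang::warn(sprintf(
      "%d model(s) failed to fit and were dropped: %s",
      sum(failed),
      paste(models$definition[failed], collapse = "; ")))
  }
  ok <- which(!failed)
  if (length(ok) == 0) stop_invalid("Every candidate model failed.")
  tbl <- tibble::tibble(
    model_id = models$model_id[ok],
    definition = models$definition[ok],
    aicc = vapply(fits[ok], `[[`, numeric(1), "aicc"),
    r2m = vapply(fits[ok], `[[`, numeric(1), "r2m"),
    r2c = vapply(fits[ok], `[[`, numeric(1), "r2c")
  ) |>
    dplyr::mutate(
      delta_aicc = .data$aicc - min(.data$aicc),
      aiccw = akaike_weights(.data$aicc),
      supported = .data$delta_aicc < 2
    ) |>
    dplyr::arrange(.data$aicc) |>
    dplyr::select("model_id", "definition", "aicc", "delta_aicc",
                  "aiccw", "r2m", "r2c", "supported")
  structure(list(table = tbl, fits = fits[ok],
                 failures = models$definition[failed]),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("Candidate model ranking (binomial-logit GLMMs):\n")
  print(x$table)
  invisible(x)
}

#' Population-scale productivity vs niche-structure correlations
#'
#' Spearman rank correlations between per population-year mean
#' productivity and each of the niche metrics SEAc and bootstrapped
#' SDNND, for every productivity measure supplied (e.g. successful pairs
#' only, and the whole monitored population where available).
#'
#' @param productivity Tibble with `population`, `year` and one or more
#'   productivity columns named in `measures`.
#' @param metrics Niche metric tibble from [niche_metrics()].
#' @param measures Character vector of productivity column names; default
#'   every column matching `"productivity"`.
#' @return A tibble with `measure`, `metric`, `rho`, `p_value`, `n`.
#' @export
population_level_tests <- function(productivity, metrics,
                                   measures = grep("productivity",
                                                   names(productivity),
                                                   value = TRUE)) {
  assert_columns(productivity, c("population", "year"),
                 what = "`productivity`")
  assert_columns(metrics, c("population", "year", "sea_c", "sdnnd_b"),
                 what = "`metrics`")
  if (length(measures) == 0) stop_invalid("No productivity measures found.")
  d <- dplyr::inner_join(productivity, metrics,
                         by = c("population", "year"))
  if (nrow(d) < 5) stop_invalid("Need at least 5 population-years.")
  purrr::map_dfr(measures, function(ms) {
    purrr::map_dfr(c("sea_c", "sdnnd_b"), function(mt) {
      st <- spearman_test(d[[ms]], d[[mt]])
      tibble::tibble(measure = ms, metric = mt,
                     rho = st$rho, p_value = st$p_value, n = st$n)
    })
  })
}
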