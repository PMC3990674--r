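# Synthetic study generator: forward-simulates a complete raptor
# diet-fitness study (prey sources, territory diets, nestling feathers,
# breeding outcomes) with known ground truth.

# Run `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.  `seed = NULL` uses the current stream.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

default_source_geometry <- function() {
  # Invented geometry (per-category tissue means, pre-TDF), placed so the
  # TDF-shifted mixing polygon is non-degenerate, encloses the observed
  # consumer envelope (d13C -24.85..-19.26, d15N 2.34..11.03) and puts
  # the corn-fed dovecote pigeons (CLd) at the d13C-rich extreme.
  tibble::tibble(
    category   = PREY_CATEGORIES,
    mu_d13c    = c(-27.1, -21.6, -28.1, -27.1, -19.1, -23.6, -28.6, -20.1),
    mu_d15n    = c(-0.9, -1.5, 3.3, 9.1, 3.8, 9.8, 5.8, 8.5),
    omega_d13c = rep(0.40, 8),
    omega_d15n = rep(0.60, 8)
  )
}

#' Build a synthetic study scenario configuration
#'
#' Bundles every knob of the forward simulation: the seven population-year
#' sampling blocks (default territory counts 20, 12, 20, 17, 25, 24, 12 for
#' France 2010-2011, Catalonia 2008-2011 and Andalusia 2011), the 8-source
#' isotope geometry, Dirichlet diet-variation regimes, trophic
#' discrimination factors, residual isotope noise, and the binomial
#' productivity model coefficients.
#'
#' Diet regimes: each territory's true diet is a Dirichlet draw around a
#' regime mean.  The `"tight"` regime (the Andalusia-like population-year)
#' uses a large concentration around a rabbit/partridge-rich mean; the
#' `"spread"` regime uses a smaller concentration, giving the substantial
#' among-territory diet variation seen in the northern populations.  A
#' fraction `specialist_fraction` of spread-regime territories instead draw
#' around a specialist mean concentrated on preferred prey (OC + AR).
#'
#' Productivity: P(two fledglings) = plogis(b0 + b_age adult +
#' b_repl replacement + b_ps (PS-ps0) + b_ps2 (PS-ps0)^2 + b_h (H'-h0) +
#' u_territory + u_population:year), with centering constants `ps0`, `h0`.
#'
#' @param population_years Tibble with `population`, `year`,
#'   `n_territories`, `regime` ("tight"/"spread").
#' @param source_geometry Tibble of per-category tissue means/SDs
#'   (columns as [default_source_geometry()] produces).
#' @param tdf,tdf_sd Length-2 TDF means and SDs (d13C, d15N); defaults
#'   2.1 +/- 0.08 and 2.7 +/- 0.5 per-mil.
#' @param mean_diet_spread,mean_diet_tight,mean_diet_specialist Named
#'   length-8 simplex vectors (regime mean diets).
#' @param conc_spread,conc_tight Dirichlet concentration totals (> 0).
#' @param specialist_fraction Fraction of spread-regime territories drawn
#'   around the specialist mean.
#' @param residual_sd Length-2 per-isotope residual SD of consumer values
#'   around the mixture mean (per-mil).
#' @param beta Named list of productivity coefficients: `intercept`,
#'   `age`, `replacement`, `ps`, `ps2`, `h`.
#' @param ps_center,h_center Centering constants for PS and H' in the
#'   productivity linear predictor.
#' @param sd_territory,sd_popyear Random-intercept SDs (logit scale).
#' @param p_adult,p_replacement Prevalence of adult pairs and of mate
#'   replacements.
#' @param n_source_samples Raw prey samples drawn per category by
#'   [generate_source_samples()].
#' @param seed Default seed used by the generators when none is passed.
#' @return A list of class `isoniche_scenario`.
#' @export
scenario_config <- function(
    population_years = tibble::tibble(
      population = c("France", "France", "Catalonia", "Catalonia",
                     "Catalonia", "Catalonia", "Andalusia"),
      year = c(2010L, 2011L, 2008L, 2009L, 2010L, 2011L, 2011L),
      n_territories = c(20L, 12L, 20L, 17L, 25L, 24L, 12L),
      regime = c("spread", "spread", "spread", "spread", "spread",
                 "spread", "tight")
    ),
    source_geometry = default_source_geometry(),
    tdf = c(2.1, 2.7),
    tdf_sd = c(0.08, 0.5),
    mean_diet_spread = c(OC = 0.25, AR = 0.18, CP = 0.11, CLw = 0.12,
                         CLd = 0.05, PAS = 0.09, SV = 0.07, TL = 0.13),
    mean_diet_tight = c(OC = 0.30, AR = 0.25, CP = 0.09, CLw = 0.12,
                        CLd = 0.03, PAS = 0.07, SV = 0.04, TL = 0.10),
    mean_diet_specialist = c(OC = 0.45, AR = 0.28, CP = 0.05, CLw = 0.06,
                             CLd = 0.02, PAS = 0.05, SV = 0.03, TL = 0.06),
    conc_spread = 12,
    conc_tight = 60,
    specialist_fraction = 0.15,
    residual_sd = c(0.3, 0.4),
    beta = list(intercept = 0.2, age = 0.8, replacement = -0.9,
                ps = 0, ps2 = 10, h = -1.2),
    ps_center = 0.85,
    h_center = 1.8,
    sd_territory = 0.3,
    sd_popyear = 0.3,
    p_adult = 0.9,
    p_replacement = 0.15,
    n_source_samples = 15L,
    seed = 1L) {
  cfg <- list(
    population_years = population_years,
    source_geometry = source_geometry,
    tdf = tdf, tdf_sd = tdf_sd,
    mean_diet_spread = renormalize(mean_diet_spread),
    mean_diet_tight = renormalize(mean_diet_tight),
    mean_diet_specialist = renormalize(mean_diet_specialist),
    conc_spread = conc_spread, conc_tight = conc_tight,
    specialist_fraction = specialist_fraction,
    residual_sd = residual_sd,
    beta = beta, ps_center = ps_center, h_center = h_center,
    sd_territory = sd_territory, sd_popyear = sd_popyear,
    p_adult = p_adult, p_replacement = p_replacement,
    n_source_samples = as.integer(n_source_samples),
    seed = seed
  )
  validate_scenario(cfg)
  structure(cfg, class = "isoniche_scenario")
}

validate_scenario <- function(cfg) {
  assert_columns(cfg$population_years,
                 c("population", "year", "n_territories", "regime"),
                 what = "`population_years`")
  if (!all(cfg$population_years$regime %in% c("tight", "spread"))) {
    stop_invalid("regime must be 'tight' or 'spread'.")
  }
  if (any(c(cfg$tdf_sd, cfg$residual_sd, cfg$sd_territory,
            cfg$sd_popyear, cfg$source_geometry$omega_d13c,
            cfg$source_geometry$omega_d15n) < 0)) {
    stop_invalid("All SDs must be >= 0.")
  }
  if (cfg$conc_spread <= 0 || cfg$conc_tight <= 0) {
    stop_invalid("Dirichlet concentrations must be > 0.")
  }
  if (cfg$specialist_fraction < 0 || cfg$specialist_fraction > 1) {
    stop_invalid("`specialist_fraction` must be in [0, 1].")
  }
  for (m in list(cfg$mean_diet_spread, cfg$mean_diet_tight,
                 cfg$mean_diet_specialist)) {
    assert_simplex(m, what = "mean diet")
  }
  if (!identical(sort(cfg$source_geometry$category),
                 sort(PREY_CATEGORIES))) {
    stop_invalid("`source_geometry` must cover exactly the 8 categories.")
  }
  invisible(cfg)
}

#' Generate the eight synthetic source distributions
#'
#' Returns the scenario's per-category source table (tissue mean/SD per
#' isotope plus TDF mean/SD), in the same shape [pool_sources()] produces.
#' By construction the corn-fed dovecote pigeon category (CLd) carries
#' the highest d13C mean.
#'
#' @param config An `isoniche_scenario` from [scenario_config()].
#' @return A source tibble (8 rows, canonical category order).
#' @export
generate_sources <- function(config) {
  validate_scenario(config)
  config$source_geometry |>
    dplyr::mutate(
      tdf_d13c = config$tdf[1], tdf_d15n = config$tdf[2],
      tdf_sd_d13c = config$tdf_sd[1], tdf_sd_d15n = config$tdf_sd[2],
      n_samples = config$n_source_samples
    ) |>
    dplyr::arrange(match(.data$category, PREY_CATEGORIES)) |>
    dplyr::select("category", "mu_d13c", "mu_d15n", "omega_d13c",
                  "omega_d15n", "tdf_d13c", "tdf_d15n", "tdf_sd_d13c",
                  "tdf_sd_d15n", "n_samples")
}

#' Generate raw prey tissue samples
#'
#' Draws `n_source_samples` normal samples per category from the
#' scenario's source geometry, with the two domestic pigeon clusters
#' merged back into a single `CL` category so that the pigeon split in
#' [pool_sources()] is exercised end to end.
#'
#' @param config An `isoniche_scenario`.
#' @param seed Integer seed (default from config).
#' @return Tibble with `category` (7 levels, `CL` merged), `d13c`, `d15n`.
#' @export
generate_source_samples <- function(config, seed = config$seed) {
  validate_scenario(config)
  geom <- config$source_geometry
  with_rng(seed, {
    samples <- purrr::pmap_dfr(geom, function(category, mu_d13c, mu_d15n,
                                              omega_d13c, omega_d15n, ...) {
      n <- config$n_source_samples
      tibble::tibble(
        category = category,
        d13c = stats::rnorm(n, mu_d13c, omega_d13c),
        d15n = stats::rnorm(n, mu_d15n, omega_d15n)
      )
    })
    dplyr::mutate(samples, category = ifelse(
      .data$category %in% c("CLw", "CLd"), "CL", .data$category))
  })
}

#' Generate true territory diet proportions for one population-year
#'
#' Draws one simplex diet vector per territory from the regime's
#' Dirichlet distribution (see [scenario_config()]).
#'
#' @param config An `isoniche_scenario`.
#' @param population,year Identify the population-year row of the config.
#' @param seed Integer seed.
#' @return A tibble with `population`, `year`, `territory` and columns
#'   `p_OC` .. `p_TL` (each row on the simplex).
#' @export
generate_territory_diets <- function(config, population, year,
                                     seed = config$seed) {
  validate_scenario(config)
  py <- dplyr::filter(config$population_years,
                      .data$population == .env$population,
                      .data$year == .env$year)
  if (nrow(py) != 1) {
    stop_invalid(sprintf("Population-year %s %s not in the scenario.",
                         population, year))
  }
  n <- py$n_territories
  with_rng(seed, {
    tight <- py$regime == "tight"
    conc <- if (tight) config$conc_tight else config$conc_spread
    m <- if (tight) config$mean_diet_tight else config$mean_diet_spread
    specialist <- if (tight) rep(FALSE, n) else
      stats::runif(n) < config$specialist_fraction
    p <- matrix(NA_real_, n, 8)
    if (any(!specialist)) {
      p[!specialist, ] <- rdirichlet(sum(!specialist), conc * m)
    }
    if (any(specialist)) {
      p[specialist, ] <- rdirichlet(sum(specialist),
                                    conc * config$mean_diet_specialist)
    }
    colnames(p) <- paste0("p_", PREY_CATEGORIES)
    dplyr::bind_cols(
      tibble::tibble(
        population = population, year = as.integer(year),
        territory = sprintf("T%02d", seq_len(n)),
        specialist = specialist
      ),
      tibble::as_tibble(p)
    )
  })
}

diet_matrix <- function(diets) {
  cols <- paste0("p_", PREY_CATEGORIES)
  assert_columns(diets, cols, what = "`diets`")
  as.matrix(diets[, cols])
}

#' Generate nestling feather isotope values from true diets
#'
#' Forward model of the mixing process: each chick's isotope pair is
#' drawn independently (given the territory's true diet p) with mean
#' \eqn{\sum_k p_k (\mu_{jk} + \lambda_j)} and variance
#' \eqn{\sum_k p_k^2 (\omega_{jk}^2 + \tau_j^2) + \sigma_j^2} per
#' isotope j — exactly the likelihood the mixing model inverts.
#'
#' @param diets Diet tibble from [generate_territory_diets()] (or any
#'   tibble with `population`, `year`, `territory` and `p_*` columns).
#' @param sources Source tibble ([generate_sources()] / [pool_sources()]).
#' @param config An `isoniche_scenario` (supplies residual SDs).
#' @param n_chicks Integer vector (1 or 2) per territory; default 2.
#' @param seed Integer seed.
#' @return A consumer tibble (`population`, `year`, `territory`,
#'   `chick_id`, `d13c`, `d15n`).
#' @export
generate_feathers <- function(diets, sources, config,
                              n_chicks = rep(2L, nrow(diets)),
                              seed = config$seed) {
  stopifnot(length(n_chicks) == nrow(diets), all(n_chicks %in% 1:2))
  shifted <- apply_tdf(sources)
  shifted <- shifted[match(PREY_CATEGORIES, shifted$category), ]
  P <- diet_matrix(diets)
  for (i in seq_len(nrow(P))) assert_simplex(P[i, ], what = "diet row")
  mu <- cbind(shifted$mu_adj_d13c, shifted$mu_adj_d15n)   # K x 2
  w2 <- cbind(shifted$sd_adj_d13c^2, shifted$sd_adj_d15n^2)
  mean_iso <- P %*% mu                                    # n x 2
  var_iso <- (P^2) %*% w2                                 # n x 2
  var_iso[, 1] <- var_iso[, 1] + config$residual_sd[1]^2
  var_iso[, 2] <- var_iso[, 2] + config$residual_sd[2]^2
  with_rng(seed, {
    idx <- rep(seq_len(nrow(P)), n_chicks)
    chick <- unlist(lapply(n_chicks, seq_len))
    tibble::tibble(
      population = diets$population[idx],
      year = diets$year[idx],
      territory = diets$territory[idx],
      chick_id = sprintf("c%d", chick),
      d13c = stats::rnorm(length(idx), mean_iso[idx, 1],
                          sqrt(var_iso[idx, 1])),
      d15n = stats::rnorm(length(idx), mean_iso[idx, 2],
                          sqrt(var_iso[idx, 2]))
    )
  })
}

#' Generate breeding outcomes from true diet indices
#'
#' Draws pair age and replacement flags at configured prevalences and the
#' number of fledglings (1 or 2) from the binomial-logit productivity
#' model with territory and population:year random intercepts.
#'
#' @param territory_truth Tibble with `population`, `year`, `territory`,
#'   `ps_true`, `h_true` (true proportional similarity and Shannon
#'   diversity per territory-year).
#' @param config An `isoniche_scenario`.
#' @param seed Integer seed.
#' @return A breeding tibble (`population`, `year`, `territory`,
#'   `pair_age`, `replacement`, `fledglings`) plus the latent
#'   `prob_two` column.
#' @export
generate_breeding <- function(territory_truth, config, seed = config$seed) {
  assert_columns(territory_truth,
                 c("population", "year", "territory", "ps_true", "h_true"),
                 what = "`territory_truth`")
  b <- config$beta
  stopifnot(all(vapply(b, is.finite, logical(1))))
  with_rng(seed, {
    n <- nrow(territory_truth)
    terr_key <- paste(territory_truth$population,
                      territory_truth$territory)
    py_key <- paste(territory_truth$population, territory_truth$year)
    u_t <- stats::rnorm(length(unique(terr_key)), 0, config$sd_territory)
    u_p <- stats::rnorm(length(unique(py_key)), 0, config$sd_popyear)
    names(u_t) <- unique(terr_key)
    names(u_p) <- unique(py_key)
    adult <- stats::rbinom(n, 1, config$p_adult)
    repl <- stats::rbinom(n, 1, config$p_replacement)
    ps_c <- territory_truth$ps_true - config$ps_center
    h_c <- territory_truth$h_true - config$h_center
    eta <- b$intercept + b$age * adult + b$replacement * repl +
      b$ps * ps_c + b$ps2 * ps_c^2 + b$h * h_c +
      u_t[terr_key] + u_p[py_key]
    prob <- stats::plogis(eta)
    two <- stats::rbinom(n, 1, prob)
    tibble::tibble(
      population = territory_truth$population,
      year = as.integer(territory_truth$year),
      territory = territory_truth$territory,
      pair_age = ifelse(adult == 1, "adult", "nonadult"),
      replacement = as.integer(repl),
      fledglings = as.integer(1L + two),
      prob_two = prob
    )
  })
}

#' Simulate a complete study with known ground truth
#'
#' Runs the full forward model over every population-year in the
#' scenario: true territory diets, true diet indices (H', PS against the
#' study-wide true mean diet), breeding outcomes, nestling feathers for
#' each fledged chick, and raw prey samples.
#'
#' @param config An `isoniche_scenario`.
#' @param seed Integer seed; sub-seeds for each stage are derived from it.
#' @return A list with `consumers`, `source_samples`, `sources`,
#'   `breeding`, `truth` (per territory-year true diet and indices) and
#'   the `config`/`seed` used.
#' @export
simulate_study <- function(config = scenario_config(), seed = config$seed) {
  validate_scenario(config)
  sources <- generate_sources(config)
  py <- config$population_years
  diets <- purrr::pmap_dfr(
    py, function(population, year, n_territories, regime) {
      generate_territory_diets(
        config, population, year,
        seed = seed + 1000L +
          match(paste(population, year),
                paste(py$population, py$year)))
    })
  P <- diet_matrix(diets)
  q_true <- colMeans(P)
  truth <- diets |>
    dplyr::mutate(
      h_true = apply(P, 1, shannon_diversity),
      ps_true = apply(P, 1, proportional_similarity, q = q_true)
    )
  breeding <- generate_breeding(truth, config, seed = seed + 2000L)
  consumers <- generate_feathers(
    truth, sources, config,
    n_chicks = breeding$fledglings, seed = seed + 3000L)
  source_samples <- generate_source_samples(config, seed = seed + 4000L)
  list(
    consumers = consumers,
    source_samples = source_samples,
    sources = sources,
    breeding = dplyr::select(breeding, -"prob_two"),
    truth = truth,
    config = config,
    seed = seed
  )
}
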