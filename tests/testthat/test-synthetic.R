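test_that("generated sources cover the 8 categories with CLd carbon-extreme", {
  cfg <- scenario_config()
  src <- generate_sources(cfg)
  expect_identical(src$category, prey_categories())
  expect_equal(src$category[which.max(src$mu_d13c)], "CLd")
  # degenerate config: all SDs zero gives point sources
  geom0 <- dplyr::mutate(default_source_geometry(),
                         omega_d13c = 0, omega_d15n = 0)
  cfg0 <- scenario_config(source_geometry = geom0, tdf_sd = c(0, 0),
                          residual_sd = c(0, 0))
  src0 <- generate_sources(cfg0)
  expect_true(all(src0$omega_d13c == 0))
  shifted <- apply_tdf(src0)
  expect_true(all(shifted$sd_adj_d13c == 0))
})

test_that("TDF-shifted source hull contains nearly all generated consumers", {
  cfg <- scenario_config()
  sim <- simulate_study(cfg, seed = 11)
  shifted <- apply_tdf(sim$sources)
  verts <- cbind(shifted$mu_adj_d13c, shifted$mu_adj_d15n)
  inside <- points_in_hull(cbind(sim$consumers$d13c, sim$consumers$d15n),
                           verts)
  expect_gte(mean(inside), 0.99)
})

test_that("territory diets are simplex draws with the configured regimes", {
  cfg <- scenario_config()
  d <- generate_territory_diets(cfg, "Catalonia", 2010, seed = 3)
  P <- as.matrix(d[, paste0("p_", prey_categories())])
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  expect_true(all(P >= 0))

  # alpha -> infinity limit: all territories share the mean diet, PS -> 1
  cfg_inf <- scenario_config(conc_spread = 1e8, specialist_fraction = 0)
  d_inf <- generate_territory_diets(cfg_inf, "Catalonia", 2010, seed = 3)
  Pi <- as.matrix(d_inf[, paste0("p_", prey_categories())])
  q <- colMeans(Pi)
  ps <- apply(Pi, 1, proportional_similarity, q = renormalize(q))
  expect_true(all(ps > 0.999))

  # specialist regime concentrates on rabbits
  cfg_spec <- scenario_config(specialist_fraction = 1)
  d_spec <- generate_territory_diets(cfg_spec, "Catalonia", 2010, seed = 3)
  Ps <- as.matrix(d_spec[, paste0("p_", prey_categories())])
  m <- colMeans(Ps)
  expect_equal(names(which.max(m)), "p_OC")
})

test_that("simulated diet means match the Dirichlet closed form", {
  cfg <- scenario_config(
    population_years = tibble::tibble(
      population = "X", year = 2010L, n_territories = 2000L,
      regime = "spread"),
    specialist_fraction = 0
  )
  d <- generate_territory_diets(cfg, "X", 2010, seed = 5)
  P <- as.matrix(d[, paste0("p_", prey_categories())])
  m <- cfg$mean_diet_spread              # Dirichlet mean
  a0 <- cfg$conc_spread
  v <- m * (1 - m) / (a0 + 1)            # Dirichlet variance
  se <- sqrt(v / nrow(P))
  expect_true(all(abs(colMeans(P) - m) < 3 * se))
})

test_that("feather values follow the mixture mean/variance model", {
  cfg0 <- scenario_config(
    source_geometry = dplyr::mutate(default_source_geometry(),
                                    omega_d13c = 0, omega_d15n = 0),
    tdf_sd = c(0, 0), residual_sd = c(0, 0))
  src0 <- generate_sources(cfg0)
  diets <- tibble::tibble(population = "X", year = 2010L,
                          territory = "T01")
  P <- matrix(c(1, rep(0, 7)), nrow = 1,
              dimnames = list(NULL, paste0("p_", prey_categories())))
  diets <- dplyr::bind_cols(diets, tibble::as_tibble(P))
  f <- generate_feathers(diets, src0, cfg0, n_chicks = 1L, seed = 2)
  expect_equal(f$d13c, src0$mu_d13c[1] + 2.1)
  expect_equal(f$d15n, src0$mu_d15n[1] + 2.7)

  # uniform diet, zero spread: arithmetic mean of shifted source means
  Pu <- matrix(rep(1 / 8, 8), nrow = 1,
               dimnames = list(NULL, paste0("p_", prey_categories())))
  diets_u <- dplyr::bind_cols(
    tibble::tibble(population = "X", year = 2010L, territory = "T01"),
    tibble::as_tibble(Pu))
  fu <- generate_feathers(diets_u, src0, cfg0, n_chicks = 1L, seed = 2)
  expect_equal(fu$d13c, mean(src0$mu_d13c + 2.1), tolerance = 1e-12)
  expect_equal(fu$d15n, mean(src0$mu_d15n + 2.7), tolerance = 1e-12)

  # CLT check: sample mean of many chicks matches the mixture mean
  cfg <- scenario_config()
  src <- generate_sources(cfg)
  n_rep <- 5000L
  diets_many <- dplyr::bind_cols(
    tibble::tibble(population = "X", year = 2010L,
                   territory = sprintf("T%04d", seq_len(n_rep))),
    tibble::as_tibble(Pu[rep(1, n_rep), , drop = FALSE]))
  fm <- generate_feathers(diets_many, src, cfg,
                          n_chicks = rep(1L, n_rep), seed = 9)
  shifted <- apply_tdf(src)
  mu_mix <- mean(shifted$mu_adj_d13c)
  var_mix <- sum((1 / 8)^2 * shifted$sd_adj_d13c^2) + cfg$residual_sd[1]^2
  expect_lt(abs(mean(fm$d13c) - mu_mix), 4 * sqrt(var_mix / n_rep))
})

test_that("breeding outcomes follow the logistic productivity model", {
  set.seed(1)
  base_truth <- tibble::tibble(
    population = "X", year = 2010L,
    territory = sprintf("T%04d", 1:4000),
    ps_true = runif(4000, 0.6, 1), h_true = runif(4000, 1.2, 2.1))

  # all coefficients zero: half the pairs fledge two chicks
  cfg0 <- scenario_config(
    beta = list(intercept = 0, age = 0, replacement = 0, ps = 0,
                ps2 = 0, h = 0),
    sd_territory = 0, sd_popyear = 0)
  b <- generate_breeding(base_truth, cfg0, seed = 4)
  frac <- mean(b$fledglings == 2)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(b)))

  # saturating intercept: every pair fledges two
  cfg_inf <- scenario_config(
    beta = list(intercept = 50, age = 0, replacement = 0, ps = 0,
                ps2 = 0, h = 0),
    sd_territory = 0, sd_popyear = 0)
  b2 <- generate_breeding(base_truth[1:200, ], cfg_inf, seed = 4)
  expect_true(all(b2$fledglings == 2L))

  # estimation oracle: plain logistic refit recovers the coefficients
  cfg_est <- scenario_config(
    beta = list(intercept = 0.3, age = 0.8, replacement = -0.9,
                ps = 0, ps2 = 0, h = -1.2),
    sd_territory = 0, sd_popyear = 0)
  truth5 <- base_truth[1:4000, ]
  b3 <- generate_breeding(truth5, cfg_est, seed = 8)
  d <- dplyr::mutate(
    dplyr::inner_join(b3, truth5, by = c("population", "year",
                                         "territory")),
    two = as.integer(fledglings == 2L),
    adult = as.integer(pair_age == "adult"),
    h_c = h_true - cfg_est$h_center)
  fit <- glm(two ~ adult + replacement + h_c, data = d,
             family = binomial())
  ci <- suppressMessages(confint.default(fit))
  gen <- c(0.3, 0.8, -0.9, -1.2)
  expect_true(all(gen >= ci[, 1] & gen <= ci[, 2]))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_scenario()
  a <- simulate_study(cfg, seed = 99)
  b <- simulate_study(cfg, seed = 99)
  expect_identical(readr::format_csv(a$consumers),
                   readr::format_csv(b$consumers))
  expect_identical(readr::format_csv(a$breeding),
                   readr::format_csv(b$breeding))
  expect_identical(readr::format_csv(a$source_samples),
                   readr::format_csv(b$source_samples))
  c2 <- simulate_study(cfg, seed = 100)
  expect_false(identical(a$consumers$d13c, c2$consumers$d13c))
})

test_that("default scenario overlaps the observed index ranges", {
  sim <- simulate_study(scenario_config(), seed = 21)
  h <- sim$truth$h_true
  ps <- sim$truth$ps_true
  # overlap (not equality) with the observed territory-level ranges
  expect_true(min(h) < 2.08 && max(h) > 1.23)
  expect_true(min(ps) < 0.97 && max(ps) > 0.62)
})
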