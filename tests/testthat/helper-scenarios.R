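# Shared fixtures: reduced-size scenarios and MCMC settings so the suite
# stays fast while exercising every stage.

small_scenario <- function(...) {
  scenario_config(
    population_years = tibble::tibble(
      population = c("France", "France", "Catalonia", "Catalonia",
                     "Andalusia"),
      year = c(2010L, 2011L, 2008L, 2009L, 2011L),
      n_territories = c(5L, 4L, 4L, 4L, 4L),
      regime = c("spread", "spread", "spread", "spread", "tight")
    ),
    ...
  )
}

fast_mcmc <- list(chains = 2L, burn_in = 1000L, n_samples = 4000L,
                  thin = 5L)

fit_fast <- function(consumers, sources, seed = 1L, ...) {
  spec <- mixing_spec(consumers, sources,
                      chains = fast_mcmc$chains,
                      burn_in = fast_mcmc$burn_in,
                      n_samples = fast_mcmc$n_samples,
                      thin = fast_mcmc$thin, ...)
  fit_mixing_model(spec, seed = seed)
}

# Convex-hull membership test: TRUE when a point lies inside (or on) the
# convex hull of `vertices` (two-column matrix).
points_in_hull <- function(points, vertices) {
  h <- grDevices::chull(vertices)          # counter-clockwise order
  hx <- vertices[h, 1]; hy <- vertices[h, 2]
  nh <- length(h)
  apply(points, 1, function(pt) {
    cross <- vapply(seq_len(nh), function(i) {
      j <- if (i == nh) 1L else i + 1L
      (hx[j] - hx[i]) * (pt[2] - hy[i]) - (hy[j] - hy[i]) * (pt[1] - hx[i])
    }, numeric(1))
    all(cross >= -1e-9) || all(cross <= 1e-9)
  })
}

# Breeding + diet truth table from the generator, sized for quick GLMM
# fits.  Spans 2 populations x 2 years so both random factors have
# several levels.
fitness_fixture <- function(n = 160, seed = 31,
                            beta = list(intercept = 0.3, age = 0.8,
                                        replacement = -0.9, ps = 0,
                                        ps2 = 0, h = -1.2),
                            sd_territory = 0, sd_popyear = 0) {
  k <- as.integer(ceiling(n / 4))
  cfg <- scenario_config(
    population_years = tibble::tibble(
      population = c("X", "X", "Y", "Y"),
      year = c(2010L, 2011L, 2010L, 2011L),
      n_territories = rep(k, 4), regime = "spread"),
    beta = beta, sd_territory = sd_territory, sd_popyear = sd_popyear)
  sim <- simulate_study(cfg, seed = seed)
  dplyr::inner_join(
    sim$breeding,
    dplyr::mutate(sim$truth, h_prime = h_true, ps_i = ps_true),
    by = c("population", "year", "territory"))
}

renormalize_for_test <- function(x) {
  x <- pmax(x, 0)
  x / sum(x)
}

# Write a data frame to a temp CSV and return the path.
csv_fixture <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

well_formed_consumers <- function() {
  tibble::tibble(
    population = c("A", "A", "B"),
    year = c(2010L, 2010L, 2011L),
    territory = c("t1", "t1", "t2"),
    chick_id = c("c1", "c2", "c1"),
    d13c = c(-22.0, -23.0, -21.4),
    d15n = c(6.0, 7.0, 5.1)
  )
}
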