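test_that("delta notation arithmetic matches its closed form and round-trips", {
  expect_equal(delta_from_ratio(0.0112, 0.0112), 0)
  expect_equal(delta_from_ratio(1.001 * 0.0112, 0.0112), 1.0)
  expect_equal(delta_from_ratio(0.999 * 0.0112, 0.0112), -1.0)
  expect_error(delta_from_ratio(0.01, 0), class = "isoniche_invalid_input")
  expect_error(delta_from_ratio(0.01, -1), class = "isoniche_invalid_input")
  # round trip to machine precision over a spread of deltas
  set.seed(10)
  d <- runif(50, -30, 15)
  expect_equal(delta_from_ratio(ratio_from_delta(d, 0.011180), 0.011180),
               d, tolerance = 1e-12)
})

test_that("consumer reader enforces schema, types and completeness", {
  path <- csv_fixture(well_formed_consumers())
  got <- read_consumers(path)
  expect_equal(nrow(got), 3)
  expect_type(got$year, "integer")

  broken <- dplyr::select(well_formed_consumers(), -d15n)
  expect_error(read_consumers(csv_fixture(broken)),
               regexp = "d15n", class = "isoniche_schema_error")

  header_only <- well_formed_consumers()[0, ]
  expect_warning(empty <- read_consumers(csv_fixture(header_only)),
                 regexp = "no rows")
  expect_equal(nrow(empty), 0)

  bad <- well_formed_consumers()
  bad$d13c <- as.character(bad$d13c)
  bad$d13c[2] <- "oops"
  expect_error(read_consumers(csv_fixture(bad)),
               class = "isoniche_row_error")

  dup <- well_formed_consumers()
  dup$chick_id <- "c1"
  dup$territory <- "t1"
  dup$population <- "A"
  dup$year <- 2010L
  expect_error(read_consumers(csv_fixture(dup)),
               class = "isoniche_row_error")
})

test_that("breeding reader validates factor levels and outcomes", {
  ok <- tibble::tibble(
    population = "A", year = 2011L, territory = c("t1", "t2"),
    pair_age = c("adult", "nonadult"), replacement = c(0L, 1L),
    fledglings = c(1L, 2L)
  )
  expect_equal(nrow(read_breeding(csv_fixture(ok))), 2)
  bad <- dplyr::mutate(ok, fledglings = c(0L, 3L))
  expect_error(read_breeding(csv_fixture(bad)),
               class = "isoniche_invalid_input")
})

test_that("sibling aggregation averages pairs, passes singletons, is idempotent", {
  x <- well_formed_consumers()
  out <- aggregate_siblings(x)
  two <- out[out$territory == "t1", ]
  expect_equal(two$d13c_mean, -22.5)
  expect_equal(two$d15n_mean, 6.5)
  expect_equal(two$n_chicks, 2L)
  one <- out[out$territory == "t2", ]
  expect_equal(one$d13c_mean, -21.4)
  expect_equal(one$d15n_mean, 5.1)
  expect_equal(one$n_chicks, 1L)

  # idempotence on already-aggregated data
  again <- aggregate_siblings(
    dplyr::transmute(out, population, year, territory,
                     chick_id = "m", d13c = d13c_mean, d15n = d15n_mean))
  expect_equal(again$d13c_mean, out$d13c_mean)
  expect_equal(again$d15n_mean, out$d15n_mean)

  triple <- dplyr::mutate(x, territory = "t1", population = "A",
                          year = 2010L, chick_id = c("a", "b", "c"))
  expect_error(aggregate_siblings(triple),
               class = "isoniche_invalid_input")
})

test_that("aggregation yields one row per distinct territory-year key", {
  sim <- simulate_study(small_scenario(), seed = 7)
  out <- aggregate_siblings(sim$consumers)
  # direct enumeration oracle
  keys <- unique(paste(sim$consumers$population, sim$consumers$year,
                       sim$consumers$territory))
  expect_equal(nrow(out), length(keys))
  # means equal a by-hand split-apply oracle
  oracle <- tapply(sim$consumers$d13c,
                   paste(sim$consumers$population, sim$consumers$year,
                         sim$consumers$territory), mean)
  got <- setNames(out$d13c_mean,
                  paste(out$population, out$year, out$territory))
  expect_equal(unname(got[names(oracle)]), as.numeric(oracle),
               tolerance = 1e-12)
})

test_that("pigeon split sends the low-d13C cluster to CLw", {
  pigeons <- tibble::tibble(
    d13c = c(-22.1, -21.9, -22.0, -13.2, -12.8, -13.0),
    d15n = rep(5, 6)
  )
  out <- split_pigeons(pigeons)
  expect_equal(out$category[out$d13c < -20], rep("CLw", 3))
  expect_equal(out$category[out$d13c > -15], rep("CLd", 3))
  # fixed-threshold override
  out2 <- split_pigeons(pigeons, threshold = -18)
  expect_identical(out$category, out2$category)
})

test_that("source pooling reproduces group statistics and the 8 categories", {
  simple <- tibble::tibble(
    category = rep(c("OC", "AR", "CP", "PAS", "SV", "TL"), each = 2),
    d13c = rep(c(-25, -24), 6),
    d15n = c(5, 7, rep(c(3, 4), 5))
  )
  pigeons <- tibble::tibble(
    category = "CL",
    d13c = c(-22, -21.8, -13, -13.2), d15n = c(6, 6, 7, 7)
  )
  pooled <- pool_sources(dplyr::bind_rows(simple, pigeons))
  expect_identical(pooled$category, prey_categories())
  oc <- pooled[pooled$category == "OC", ]
  expect_equal(oc$mu_d15n, 6)
  expect_equal(oc$omega_d15n, sqrt(2))

  # independent group-by oracle on a 40-row random prey table
  set.seed(42)
  raw <- tibble::tibble(
    category = sample(prey_categories(), 40, replace = TRUE),
    d13c = rnorm(40, -22, 2), d15n = rnorm(40, 6, 1.5)
  )
  # ensure >= 2 samples per category
  raw <- dplyr::bind_rows(
    raw,
    tibble::tibble(category = rep(prey_categories(), 2),
                   d13c = rnorm(16, -22, 2), d15n = rnorm(16, 6, 1.5)))
  pooled <- pool_sources(raw)
  for (cat in prey_categories()) {
    sub <- raw[raw$category == cat, ]
    row <- pooled[pooled$category == cat, ]
    expect_equal(row$mu_d13c, mean(sub$d13c), tolerance = 1e-12)
    expect_equal(row$omega_d13c, sd(sub$d13c), tolerance = 1e-12)
    expect_equal(row$n_samples, nrow(sub))
  }
  # row-order invariance
  shuffled <- pool_sources(raw[sample(nrow(raw)), ])
  expect_equal(pooled, shuffled)

  thin <- raw[raw$category != "SV", ]
  thin <- dplyr::bind_rows(thin, tibble::tibble(category = "SV",
                                                d13c = -23, d15n = 5))
  expect_error(pool_sources(thin), regexp = "SV",
               class = "isoniche_invalid_input")
})

test_that("TDF shift adds means and combines spreads in quadrature", {
  src <- tibble::tibble(
    category = "OC", mu_d13c = -24.0, mu_d15n = 4.0,
    omega_d13c = 0.3, omega_d15n = 0.3,
    tdf_d13c = 2.1, tdf_d15n = 2.7,
    tdf_sd_d13c = 0.08, tdf_sd_d15n = 0.5, n_samples = 5L
  )
  out <- apply_tdf(src)
  expect_equal(out$mu_adj_d13c, -21.9)
  expect_equal(out$mu_adj_d15n, 6.7)
  expect_equal(out$sd_adj_d13c, sqrt(0.3^2 + 0.08^2))
  # identity when TDF is zero
  src0 <- dplyr::mutate(src, tdf_d13c = 0, tdf_d15n = 0,
                        tdf_sd_d13c = 0, tdf_sd_d15n = 0)
  out0 <- apply_tdf(src0)
  expect_equal(out0$mu_adj_d13c, src0$mu_d13c)
  expect_equal(out0$sd_adj_d15n, src0$omega_d15n)
  # quadrature closed form
  srcq <- dplyr::mutate(src, omega_d13c = 0.3, tdf_sd_d13c = 0.5)
  expect_equal(apply_tdf(srcq)$sd_adj_d13c, sqrt(0.34))
})
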