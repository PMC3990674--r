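# End-to-end orchestration: load or simulate -> aggregate siblings ->
# pool sources -> per-territory mixing fits -> diet indices -> niche
# metrics -> model ranking -> population-level tests -> report tables.

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Summarise territory diet estimates into a population-year report
#'
#' Per population-year and prey category: mean and range (max - min) of
#' the territory-level posterior mean consumption, in percent.  Within
#' each group the category means sum to ~100 (up to the per-territory
#' simplex normalisation).
#'
#' @param diets Wide diet tibble (`population`, `year`, `territory`,
#'   `p_OC` .. `p_TL`), e.g. `fit_territory_diets()$diets`.
#' @return Long tibble: `population`, `year`, `category`, `mean_pct`,
#'   `range_pct`, `n_territories`.
#' @export
summarize_consumption <- function(diets) {
  assert_columns(diets, c("population", "year"), what = "`diets`")
  long <- diets |>
    tidyr::pivot_longer(dplyr::all_of(paste0("p_", PREY_CATEGORIES)),
                        names_to = "category", values_to = "p",
                        names_prefix = "p_") |>
    dplyr::group_by(.data$population, .data$year, .data$category) |>
    dplyr::summarise(
      mean_pct = 100 * mean(.data$p),
      range_pct = 100 * (max(.data$p) - min(.data$p)),
      n_territories = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = PREY_CATEGORIES)) |>
    dplyr::arrange(.data$population, .data$year, .data$category) |>
    dplyr::mutate(category = as.character(.data$category))
  long
}

#' Read back a pipeline report table
#'
#' Thin reader for the raw-precision CSV tables the pipeline writes, so
#' every output round-trips through the package.
#'
#' @param path Path to a `*_raw.csv` (or any pipeline CSV).
#' @return A tibble.
#' @export
read_pipeline_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

write_report <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
}

#' Run the full diet-fitness pipeline
#'
#' Executes every stage on either user-supplied tables or a synthetic
#' scenario, and writes the report bundle to `out_dir`:
#' `table1[_raw].csv` (niche metrics per population-year),
#' `table2[_raw].csv` (mean and range of prey consumption, "Mean
#' (range) %"), `table3[_raw].csv` (model ranking), `sensitivity.csv`
#' (TDF sensitivity, when enabled), `diet_indices.csv`,
#' `population_tests.csv` and a `manifest.json` recording configuration,
#' seed and versions.
#'
#' @param out_dir Output directory (created if missing).
#' @param scenario An `isoniche_scenario` used when no real tables are
#'   given.
#' @param consumers,source_samples,breeding Optional real input tibbles
#'   (or CSV paths) replacing the synthetic stage.
#' @param seed Global seed; every stochastic stage derives its own seed
#'   from it.
#' @param mcmc List of mixing-model settings (`chains`, `burn_in`,
#'   `n_samples`, `thin`).
#' @param boot_B,boot_m Niche-metric bootstrap replicates and resample
#'   size (`NULL` m = minimum group size).
#' @param sensitivity Run the TDF sensitivity grid (default `TRUE`).
#' @param models Candidate model tibble (default the full set of 15).
#' @return (Invisibly) a list with every intermediate and final object.
#' @export
run_pipeline <- function(out_dir,
                         scenario = scenario_config(),
                         consumers = NULL, source_samples = NULL,
                         breeding = NULL,
                         seed = 1L,
                         mcmc = list(chains = 2L, burn_in = 10000L,
                                     n_samples = 40000L, thin = 10L),
                         boot_B = 10000L, boot_m = NULL,
                         sensitivity = TRUE,
                         models = candidate_models()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (is.null(consumers)) {
    sim <- simulate_study(scenario, seed = seed)
    consumers <- sim$consumers
    source_samples <- sim$source_samples
    breeding <- sim$breeding
    truth <- sim$truth
    stage_log("simulate", "generated %d chicks, %d prey samples, %d breeding records",
              nrow(consumers), nrow(source_samples), nrow(breeding))
  } else {
    if (is.character(consumers)) consumers <- read_consumers(consumers)
    if (is.character(source_samples)) {
      source_samples <- read_sources(source_samples)
    }
    if (is.character(breeding)) breeding <- read_breeding(breeding)
    stage_log("load", "read %d chicks, %d prey samples, %d breeding records",
              nrow(consumers), nrow(source_samples), nrow(breeding))
  }

  obs <- aggregate_siblings(consumers)
  stage_log("aggregate", "%d chicks -> %d territory-year observations",
            nrow(consumers), nrow(obs))

  sources <- pool_sources(source_samples,
                          tdf = scenario$tdf, tdf_sd = scenario$tdf_sd)
  stage_log("sources", "pooled %d samples into %d categories",
            nrow(source_samples), nrow(sources))

  fits <- fit_territory_diets(
    consumers, sources, seed = seed + 100L,
    chains = mcmc$chains, burn_in = mcmc$burn_in,
    n_samples = mcmc$n_samples, thin = mcmc$thin)
  stage_log("mixing", "fitted %d territory-year diets",
            nrow(fits$diets))

  indices <- compute_diet_indices(fits$diets)
  stage_log("indices", "computed H' and PS for %d territory-years",
            nrow(indices))

  metrics <- niche_metrics(obs, B = boot_B, m = boot_m,
                           seed = seed + 200L)
  stage_log("niche", "metrics for %d population-years", nrow(metrics))

  fitness_data <- dplyr::inner_join(
    breeding, indices,
    by = c("population", "year", "territory"))
  stage_log("fitness", "model set on %d successful territory-years",
            nrow(fitness_data))
  ranking <- rank_model_set(fitness_data, models = models)

  productivity <- breeding |>
    dplyr::group_by(.data$population, .data$year) |>
    dplyr::summarise(
      productivity_successful = mean(.data$fledglings),
      .groups = "drop")
  pop_tests <- population_level_tests(productivity, metrics)
  stage_log("population", "rank correlations over %d population-years",
            nrow(productivity))

  sens <- NULL
  if (isTRUE(sensitivity)) {
    sens <- tdf_sensitivity(
      consumers, sources, seed = seed + 300L,
      chains = mcmc$chains, burn_in = mcmc$burn_in,
      n_samples = mcmc$n_samples, thin = mcmc$thin)
    stage_log("sensitivity",
              "grand mean absolute change %.2f percentage points",
              sens$grand_mean_abs_change_pp)
  }

  # --- report tables -------------------------------------------------
  table1_raw <- metrics
  table1 <- metrics |>
    dplyr::mutate(dplyr::across(
      c("mean_d13c", "mean_d15n", "cr_b", "nr_b", "cd_b", "sdnnd_b",
        "sea", "sea_c"), ~ round(.x, 2)))
  write_report(table1_raw, file.path(out_dir, "table1_raw.csv"))
  write_report(table1, file.path(out_dir, "table1.csv"))

  table2_raw <- summarize_consumption(fits$diets)
  table2 <- table2_raw |>
    dplyr::mutate(cell = sprintf("%.1f (%.1f)", .data$mean_pct,
                                 .data$range_pct),
                  group = paste(.data$population, .data$year,
                                sep = "-")) |>
    dplyr::select("category", "group", "cell") |>
    tidyr::pivot_wider(names_from = "group", values_from = "cell")
  write_report(table2_raw, file.path(out_dir, "table2_raw.csv"))
  write_report(table2, file.path(out_dir, "table2.csv"))

  table3_raw <- ranking$table
  table3 <- ranking$table |>
    dplyr::transmute(
      .data$model_id, .data$definition,
      delta_aicc = round(.data$delta_aicc, 3),
      aiccw = round(.data$aiccw, 3),
      r2m = round(.data$r2m, 3), r2c = round(.data$r2c, 3),
      .data$supported)
  write_report(table3_raw, file.path(out_dir, "table3_raw.csv"))
  write_report(table3, file.path(out_dir, "table3.csv"))

  write_report(indices, file.path(out_dir, "diet_indices.csv"))
  write_report(fits$estimates, file.path(out_dir, "diet_estimates.csv"))
  write_report(pop_tests, file.path(out_dir, "population_tests.csv"))
  if (!is.null(sens)) {
    write_report(sens$by_grid, file.path(out_dir, "sensitivity.csv"))
  }

  manifest <- list(
    package = "isoniche",
    version = as.character(utils::packageVersion("isoniche")),
    r_version = R.version.string,
    seed = seed,
    mcmc = mcmc,
    bootstrap = list(B = boot_B, m = boot_m),
    n_consumers = nrow(consumers),
    n_territory_years = nrow(obs),
    n_population_years = nrow(metrics),
    synthetic = !is.null(truth),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    consumers = consumers, observations = obs, sources = sources,
    diet_fits = fits, indices = indices, metrics = metrics,
    ranking = ranking, population_tests = pop_tests,
    sensitivity = sens, truth = truth, breeding = breeding,
    out_dir = out_dir
  ))
}
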