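#' Convert an isotope ratio to delta notation
#'
#' Expresses a measured isotope ratio relative to an international
#' standard in per-mil units: \eqn{\delta = (R_{sample}/R_{standard} - 1)
#' \times 1000}.  For carbon the standard is Pee Dee Belemnite (PDB); for
#' nitrogen it is atmospheric N2 (AIR).
#'
#' @param r_sample Numeric vector of sample isotope ratios (e.g. 13C:12C).
#' @param r_standard Numeric vector (or scalar) of standard ratios; must
#'   be strictly positive.
#' @return Numeric vector of delta values in per-mil.
#' @export
#' @examples
#' delta_from_ratio(0.011238, 0.011180)
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop_invalid("`r_standard` must be finite and strictly positive.")
  }
  if (any(!is.finite(r_sample))) {
    stop_invalid("`r_sample` must be finite.")
  }
  (r_sample / r_standard - 1) * 1000
}

#' Invert delta notation back to a raw ratio
#'
#' @param delta Delta value in per-mil.
#' @param r_standard Standard ratio (> 0).
#' @return The sample ratio implied by `delta`.
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop_invalid("`r_standard` must be finite and strictly positive.")
  }
  (delta / 1000 + 1) * r_standard
}

read_checked_csv <- function(path, col_types, required, what) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path),
                 class = "isoniche_io_error")
  }
  # parse issues surface through readr::problems() below; vroom's
  # spec-mismatch warning duplicates our own schema error
  df <- suppressWarnings(
    readr::read_csv(path, col_types = col_types,
                    show_col_types = FALSE, progress = FALSE))
  assert_columns(df, required, what = sprintf("%s file '%s'", what, path))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    bad <- utils::head(probs, 5)
    rlang::abort(
      c(sprintf("%s file '%s' has %d malformed cell(s):", what, path,
                nrow(probs)),
        sprintf("row %d, column %d: expected %s, got '%s'",
                bad$row, bad$col, bad$expected, bad$actual)),
      class = "isoniche_row_error"
    )
  }
  if (nrow(df) == 0) {
    rlang::warn(sprintf("%s file '%s' contains a header but no rows.",
                        what, path))
  }
  df
}

#' Read a consumer (nestling feather) isotope table
#'
#' Expects a comma-separated UTF-8 file with columns `population`, `year`,
#' `territory`, `chick_id`, `d13c`, `d15n` (per-mil vs PDB / AIR).  Rows
#' with missing or unparseable isotope values are rejected, not imputed:
#' the analysis uses complete isotope pairs only.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per sampled chick.
#' @export
read_consumers <- function(path) {
  df <- read_checked_csv(
    path,
    col_types = readr::cols(
      population = readr::col_character(),
      year = readr::col_integer(),
      territory = readr::col_character(),
      chick_id = readr::col_character(),
      d13c = readr::col_double(),
      d15n = readr::col_double()
    ),
    required = c("population", "year", "territory", "chick_id",
                 "d13c", "d15n"),
    what = "consumer"
  )
  bad <- which(!is.finite(df$d13c) | !is.finite(df$d15n))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("consumer file '%s': missing/non-finite isotope values at data row(s) %s",
              path, paste(bad, collapse = ", ")),
      class = "isoniche_row_error"
    )
  }
  key <- paste(df$population, df$year, df$territory, df$chick_id, sep = "\r")
  if (anyDuplicated(key)) {
    rlang::abort(
      sprintf("consumer file '%s': duplicated (population, year, territory, chick_id) keys", path),
      class = "isoniche_row_error"
    )
  }
  df
}

#' Read a prey source sample table
#'
#' Expects columns `category`, `d13c`, `d15n`, one row per sampled prey
#' individual (muscle tissue).  Domestic pigeons may appear either as a
#' single `CL` category (split later by [pool_sources()]) or pre-split as
#' `CLw` / `CLd`.
#'
#' @param path Path to the CSV file.
#' @return A tibble of raw prey samples.
#' @export
read_sources <- function(path) {
  df <- read_checked_csv(
    path,
    col_types = readr::cols(
      category = readr::col_character(),
      d13c = readr::col_double(),
      d15n = readr::col_double()
    ),
    required = c("category", "d13c", "d15n"),
    what = "source"
  )
  bad <- which(!is.finite(df$d13c) | !is.finite(df$d15n))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("source file '%s': missing/non-finite isotope values at data row(s) %s",
              path, paste(bad, collapse = ", ")),
      class = "isoniche_row_error"
    )
  }
  df
}

#' Read a breeding outcome table
#'
#' Expects columns `population`, `year`, `territory`, `pair_age`
#' (`"adult"` or `"nonadult"`), `replacement` (0/1) and `fledglings`
#' (1 or 2; successful pairs only).
#'
#' @param path Path to the CSV file.
#' @return A tibble of territory-year breeding records.
#' @export
read_breeding <- function(path) {
  df <- read_checked_csv(
    path,
    col_types = readr::cols(
      population = readr::col_character(),
      year = readr::col_integer(),
      territory = readr::col_character(),
      pair_age = readr::col_character(),
      replacement = readr::col_integer(),
      fledglings = readr::col_integer()
    ),
    required = c("population", "year", "territory", "pair_age",
                 "replacement", "fledglings"),
    what = "breeding"
  )
  if (nrow(df) > 0) {
    if (!all(df$pair_age %in% c("adult", "nonadult"))) {
      stop_invalid("`pair_age` must be 'adult' or 'nonadult'.")
    }
    if (!all(df$replacement %in% c(0L, 1L))) {
      stop_invalid("`replacement` must be 0 or 1.")
    }
    if (!all(df$fledglings %in% c(1L, 2L))) {
      stop_invalid("`fledglings` must be 1 or 2 (successful pairs only).")
    }
  }
  df
}

#' Aggregate sibling chicks to one observation per territory-year
#'
#' In territories fledging two chicks the siblings' isotope values are
#' averaged, so each territory-year contributes a single observation to
#' the population-level niche metrics.  Territories with a single chick
#' pass through unchanged.
#'
#' @param consumers A consumer tibble as returned by [read_consumers()]
#'   or [generate_feathers()].
#' @return A tibble with columns `population`, `year`, `territory`,
#'   `d13c_mean`, `d15n_mean`, `n_chicks`, one row per territory-year.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   population = "A", year = 2011L, territory = c("t1", "t1", "t2"),
#'   chick_id = c("c1", "c2", "c1"),
#'   d13c = c(-22, -23, -21.4), d15n = c(6, 7, 5.1)
#' )
#' aggregate_siblings(x)
aggregate_siblings <- function(consumers) {
  assert_columns(consumers,
                 c("population", "year", "territory", "d13c", "d15n"),
                 what = "`consumers`")
  out <- consumers |>
    dplyr::group_by(.data$population, .data$year, .data$territory) |>
    dplyr::summarise(
      d13c_mean = mean(.data$d13c),
      d15n_mean = mean(.data$d15n),
      n_chicks = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n_chicks > 2)) {
    bad <- out[out$n_chicks > 2, ]
    stop_invalid(sprintf(
      "More than 2 chicks in territory-year(s): %s",
      paste(sprintf("%s/%s/%s", bad$population, bad$year, bad$territory),
            collapse = ", ")
    ))
  }
  out
}

#' Split domestic pigeon samples by carbon source
#'
#' Domestic pigeons show a marked carbon dichotomy: birds foraging on
#' crops carry lower d13C, birds from dovecotes fed corn (a C4 plant)
#' carry higher d13C.  This splits a pigeon sample table into `CLw`
#' (lower-d13C cluster) and `CLd` (higher-d13C cluster) either by a
#' 1-dimensional 2-means clustering on d13C (default) or at a fixed
#' user-supplied threshold.
#'
#' @param pigeons Tibble of pigeon samples with `d13c`, `d15n`.
#' @param threshold Optional fixed d13C cutoff; samples below it become
#'   `CLw`, at or above it `CLd`.  When `NULL` a 2-means split is used.
#' @return The input with a `category` column set to `"CLw"` / `"CLd"`.
#' @export
split_pigeons <- function(pigeons, threshold = NULL) {
  assert_columns(pigeons, c("d13c", "d15n"), what = "`pigeons`")
  if (nrow(pigeons) < 4) {
    stop_invalid("Need at least 4 pigeon samples (2 per resulting category).")
  }
  if (is.null(threshold)) {
    # deterministic 2-means: initialize at the extremes of the d13c axis
    centers <- matrix(range(pigeons$d13c), ncol = 1)
    km <- stats::kmeans(matrix(pigeons$d13c, ncol = 1), centers = centers)
    low_cluster <- which.min(km$centers)
    cat <- ifelse(km$cluster == low_cluster, "CLw", "CLd")
  } else {
    cat <- ifelse(pigeons$d13c < threshold, "CLw", "CLd")
  }
  dplyr::mutate(pigeons, category = cat)
}

#' Pool prey samples into per-category source distributions
#'
#' Combines raw prey samples across the study area into one mean +/- SD
#' source distribution per category for both isotopes, splits domestic
#' pigeons (`CL`) into crop-foraging (`CLw`) and dovecote/corn (`CLd`)
#' groups, and attaches trophic discrimination factors (TDFs).
#'
#' @param samples Tibble with `category`, `d13c`, `d15n`.  Categories must
#'   cover OC, AR, CP, PAS, SV, TL and either `CL` or both `CLw`/`CLd`.
#' @param tdf Length-2 numeric, TDF means for (d13C, d15N) in per-mil.
#'   Default `c(2.1, 2.7)` (feather values for a raptor fed quail muscle).
#' @param tdf_sd Length-2 numeric, TDF SDs; default `c(0.08, 0.5)`.
#' @param pigeon_threshold Optional fixed d13C cutoff passed to
#'   [split_pigeons()]; default uses 2-means.
#' @return A tibble with one row per category (K = 8) in canonical order:
#'   `category`, `mu_d13c`, `mu_d15n`, `omega_d13c`, `omega_d15n`,
#'   `tdf_d13c`, `tdf_d15n`, `tdf_sd_d13c`, `tdf_sd_d15n`, `n_samples`.
#' @export
pool_sources <- function(samples, tdf = c(2.1, 2.7), tdf_sd = c(0.08, 0.5),
                         pigeon_threshold = NULL) {
  assert_columns(samples, c("category", "d13c", "d15n"), what = "`samples`")
  if (any(tdf_sd < 0)) stop_invalid("`tdf_sd` must be >= 0.")
  if (any(samples$category == "CL")) {
    cl <- split_pigeons(dplyr::filter(samples, .data$category == "CL"),
                        threshold = pigeon_threshold)
    samples <- dplyr::bind_rows(
      dplyr::filter(samples, .data$category != "CL"), cl
    )
  }
  missing <- setdiff(PREY_CATEGORIES, unique(samples$category))
  if (length(missing) > 0) {
    stop_invalid(sprintf("No samples for category(ies): %s",
                         paste(missing, collapse = ", ")))
  }
  extra <- setdiff(unique(samples$category), PREY_CATEGORIES)
  if (length(extra) > 0) {
    stop_invalid(sprintf("Unknown prey category(ies): %s",
                         paste(extra, collapse = ", ")))
  }
  counts <- table(samples$category)
  thin <- names(counts)[counts < 2]
  if (length(thin) > 0) {
    stop_invalid(sprintf(
      "Category(ies) with fewer than 2 samples (SD undefined): %s",
      paste(thin, collapse = ", ")
    ))
  }
  out <- samples |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      mu_d13c = mean(.data$d13c), mu_d15n = mean(.data$d15n),
      omega_d13c = stats::sd(.data$d13c), omega_d15n = stats::sd(.data$d15n),
      n_samples = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(
      tdf_d13c = tdf[1], tdf_d15n = tdf[2],
      tdf_sd_d13c = tdf_sd[1], tdf_sd_d15n = tdf_sd[2]
    ) |>
    dplyr::arrange(match(.data$category, PREY_CATEGORIES)) |>
    dplyr::select("category", "mu_d13c", "mu_d15n", "omega_d13c",
                  "omega_d15n", "tdf_d13c", "tdf_d15n", "tdf_sd_d13c",
                  "tdf_sd_d15n", "n_samples")
  out
}

#' Shift source distributions by their trophic discrimination factors
#'
#' Adds the per-isotope TDF mean to each source mean and combines source
#' and TDF spread in quadrature: shifted mean \eqn{\mu + \lambda},
#' combined SD \eqn{\sqrt{\omega^2 + \tau^2}}.  The shifted table is what
#' the mixing model (and the consumer bi-plot) work in.
#'
#' @param sources A source tibble from [pool_sources()] or
#'   [generate_sources()].
#' @return The source tibble with extra columns `mu_adj_d13c`,
#'   `mu_adj_d15n`, `sd_adj_d13c`, `sd_adj_d15n`.
#' @export
apply_tdf <- function(sources) {
  assert_columns(sources,
                 c("category", "mu_d13c", "mu_d15n", "omega_d13c",
                   "omega_d15n", "tdf_d13c", "tdf_d15n",
                   "tdf_sd_d13c", "tdf_sd_d15n"),
                 what = "`sources`")
  dplyr::mutate(
    sources,
    mu_adj_d13c = .data$mu_d13c + .data$tdf_d13c,
    mu_adj_d15n = .data$mu_d15n + .data$tdf_d15n,
    sd_adj_d13c = sqrt(.data$omega_d13c^2 + .data$tdf_sd_d13c^2),
    sd_adj_d15n = sqrt(.data$omega_d15n^2 + .data$tdf_sd_d15n^2)
  )
}
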