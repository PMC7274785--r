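# CSV schemas (comma-separated, UTF-8, header row, '.' decimal, empty
# missing values) and the JSON sidecar of true generating parameters.

ANIMALS_COLS <- c("animal_id", "site", "sex", "genotype", "diet_id",
                  "age_weeks", "body_mass_g", "lean_mass_g", "fat_mass_g",
                  "ambient_temp_c", "run_start")
SERIES_COLS <- c("animal_id", "timestamp", "vo2_ml_hr", "vco2_ml_hr",
                 "ee_kj_hr", "food_g", "beam_breaks")
DIETS_COLS <- c("diet_id", "name", "energy_density_kj_g",
                "fat_energy_fraction")

format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC")

parse_ts <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (anyNA(out) & !all(is.na(x))) {
    # fall back to a space-separated form without offset (assume UTC)
    alt <- as.POSIXct(x, tz = "UTC")
    out[is.na(out)] <- alt[is.na(out)]
  }
  out
}

check_schema <- function(df, required, file) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s) %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read the animal-level table
#'
#' Expects the `animals.csv` schema: `animal_id, site, sex, genotype,
#' diet_id, age_weeks, body_mass_g, lean_mass_g, fat_mass_g,
#' ambient_temp_c, run_start` (ISO 8601 timestamps). Extra columns are kept.
#'
#' @param path Path to the CSV file.
#' @return A tibble with `run_start` parsed to `POSIXct`.
#' @export
read_animals <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, ANIMALS_COLS, basename(path))
  df$run_start <- parse_ts(df$run_start)
  if (any(df$body_mass_g <= 0, na.rm = TRUE)) {
    stop(basename(path), ": body_mass_g must be positive", call. = FALSE)
  }
  as_tibble(df)
}

#' Read the hourly time-series table
#'
#' Expects the `timeseries.csv` schema: `animal_id, timestamp, vo2_ml_hr,
#' vco2_ml_hr, ee_kj_hr, food_g, beam_breaks`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with `timestamp` parsed to `POSIXct`.
#' @export
read_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, SERIES_COLS, basename(path))
  df$timestamp <- parse_ts(df$timestamp)
  as_tibble(df)
}

#' Read the diet table
#'
#' Expects the `diets.csv` schema: `diet_id, name, energy_density_kj_g,
#' fat_energy_fraction`.
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_diets <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, DIETS_COLS, basename(path))
  if (any(df$energy_density_kj_g <= 0, na.rm = TRUE)) {
    stop(basename(path), ": energy_density_kj_g must be positive",
         call. = FALSE)
  }
  as_tibble(df)
}

#' Write a synthetic cohort to disk
#'
#' Emits `animals.csv`, `timeseries.csv` and `diets.csv` in the published
#' schemas, plus `truth.json`, a sidecar of the true generating parameters
#' (site coefficients, strain shifts, per-animal true means and the seed)
#' for parameter-recovery tests.
#'
#' @param cohort A `mc_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- cohort$animals
  a$run_start <- format_ts(a$run_start)
  write.csv(a, file.path(dir, "animals.csv"), row.names = FALSE, na = "")
  s <- cohort$series
  s$timestamp <- format_ts(s$timestamp)
  write.csv(s, file.path(dir, "timeseries.csv"), row.names = FALSE, na = "")
  write.csv(cohort$diets, file.path(dir, "diets.csv"), row.names = FALSE,
            na = "")
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE,
                       POSIXt = "ISO8601")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `animals.csv`, `timeseries.csv`,
#'   `diets.csv`.
#' @return A list with tibbles `animals`, `series`, `diets` (no truth).
#' @export
read_cohort <- function(dir) {
  list(animals = read_animals(file.path(dir, "animals.csv")),
       series = read_series(file.path(dir, "timeseries.csv")),
       diets = read_diets(file.path(dir, "diets.csv")))
}
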