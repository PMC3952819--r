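#' Read and write the tabular file formats
#'
#' All tables are UTF-8, header-first, comma-separated files with fixed,
#' documented columns:
#' * geography: `states.csv` (`state_id`, `CFR`, `DSM`, `ASD`, `Eval`) and
#'   `counties.csv` (`county_id`, `state_id`, `pop_male`, `pop_female`);
#' * covariates: `county_id` plus one numeric column per covariate;
#' * panel: `county_id`, `disease`, `gender`, `y`, `N`;
#' * patients: `patient_id`, `county_id`, `gender`, one logical
#'   `flag_*` column per phenotype plus `flag_ConGen`.
#'
#' Readers validate the schema (naming any missing or unparseable
#' columns) and the table invariants; `read_panel()` rejects rows with
#' negative counts or `y > N`, reporting the row numbers. Identifiers are
#' opaque strings and are never parsed for meaning. Round trips are
#' lossless and order-preserving.
#'
#' @param panel,geo,covars,patients Objects to write.
#' @param path,dir File path (directory for geography, which spans two
#'   files).
#' @return Writers return the path(s) invisibly; readers return the
#'   parsed object.
#' @name geopoisson-io
NULL

read_table_checked <- function(path, col_types, required) {
  df <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE))
  extra <- setdiff(names(df), required)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0 || length(extra) > 0) {
    abort(sprintf("schema mismatch in %s: missing [%s], extra [%s]",
                  basename(path), paste(missing_cols, collapse = ", "),
                  paste(extra, collapse = ", ")),
          class = "geopoisson_schema_error")
  }
  df
}

#' @rdname geopoisson-io
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  readr::write_csv(panel[, c("county_id", "disease", "gender", "y", "N")], path)
  invisible(path)
}

#' @rdname geopoisson-io
#' @export
read_panel <- function(path) {
  df <- read_table_checked(path, readr::cols(
    county_id = readr::col_character(), disease = readr::col_character(),
    gender = readr::col_character(), y = readr::col_integer(),
    N = readr::col_integer()),
    c("county_id", "disease", "gender", "y", "N"))
  if (anyNA(df$y) || anyNA(df$N)) {
    abort("panel integer columns failed to parse.",
          class = "geopoisson_schema_error")
  }
  bad <- which(df$y < 0 | df$y > df$N)
  if (length(bad) > 0) {
    abort(sprintf("invalid panel rows (y < 0 or y > N) at row(s): %s",
                  paste(head(bad, 10), collapse = ", ")),
          class = "geopoisson_validation_error")
  }
  df
}

#' @rdname geopoisson-io
#' @export
write_geography <- function(geo, dir) {
  stopifnot(inherits(geo, "gp_geography"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "states.csv"); cp <- file.path(dir, "counties.csv")
  readr::write_csv(geo$states, sp)
  readr::write_csv(geo$counties, cp)
  invisible(c(sp, cp))
}

#' @rdname geopoisson-io
#' @export
read_geography <- function(dir) {
  states <- read_table_checked(file.path(dir, "states.csv"), readr::cols(
    state_id = readr::col_character(), CFR = readr::col_integer(),
    DSM = readr::col_integer(), ASD = readr::col_integer(),
    Eval = readr::col_integer()),
    c("state_id", "CFR", "DSM", "ASD", "Eval"))
  counties <- read_table_checked(file.path(dir, "counties.csv"), readr::cols(
    county_id = readr::col_character(), state_id = readr::col_character(),
    pop_male = readr::col_integer(), pop_female = readr::col_integer()),
    c("county_id", "state_id", "pop_male", "pop_female"))
  new_geography(states, counties)
}

#' @rdname geopoisson-io
#' @export
write_covariates <- function(covars, path) {
  readr::write_csv(covars, path)
  invisible(path)
}

#' @rdname geopoisson-io
#' @export
read_covariates <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    county_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (!"county_id" %in% names(df)) {
    abort("covariates file lacks county_id.", class = "geopoisson_schema_error")
  }
  df
}

#' @rdname geopoisson-io
#' @export
write_patients <- function(patients, path) {
  readr::write_csv(patients, path)
  invisible(path)
}

#' @rdname geopoisson-io
#' @export
read_patients <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), county_id = readr::col_character(),
    gender = readr::col_character(), .default = readr::col_logical()),
    progress = FALSE)
  req <- c("patient_id", "county_id", "gender")
  if (!all(req %in% names(df))) {
    abort("patients file lacks identifier columns.",
          class = "geopoisson_schema_error")
  }
  if (anyDuplicated(df$patient_id)) {
    abort("patient_ids must be unique.", class = "geopoisson_validation_error")
  }
  df
}
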