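#' Ring-recovery dataset
#'
#' Container for a season's worth of dead-recovery records together with
#' species metadata and the recovery horizon `k`. Records are held as a
#' tibble (one row per dead-recovered bird), species metadata as a second
#' tibble; the object tracks which preparation steps (first-year exclusion,
#' migration-window filter, species inclusion, day standardization) have
#' been applied so that downstream functions can insist on the correct
#' pipeline order.
#'
#' @param records Tibble or data frame with columns `species_id`, `season`,
#'   `day_of_year`, `ringing_year`, `years_to_recovery`, `distance_class`
#'   and optionally `sex` (defaults to `"unknown"`) and `std_day`.
#' @param species Optional tibble of species metadata with columns
#'   `species_id`, `name`, `distance_class`, and window columns
#'   `window_spring_start`, `window_spring_end`, `window_autumn_start`,
#'   `window_autumn_end` (day-of-year, `NA` when the species is not analysed
#'   in that season). When `NULL`, a skeleton is assembled from the records.
#' @param season `"spring"` or `"autumn"`.
#'
#' @return A `recovery_data` object: a list with elements `records`,
#'   `species`, `season`, `k` (maximal years-to-recovery over records) and
#'   bookkeeping flags `first_year_excluded` and `standardized`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   species_id = "phoenicurus_phoenicurus", season = "spring",
#'   day_of_year = c(121L, 130L, 142L), ringing_year = c(1965L, 1970L, 1980L),
#'   years_to_recovery = c(2L, 3L, 2L), distance_class = "long",
#'   sex = "unknown"
#' )
#' recovery_data(rec, season = "spring")
recovery_data <- function(records, species = NULL, season = c("spring", "autumn")) {
  season <- match.arg(season)
  records <- tibble::as_tibble(records)
  if (!"sex" %in% names(records)) records$sex <- "unknown"
  records$sex[is.na(records$sex) | records$sex == ""] <- "unknown"
  if (!"std_day" %in% names(records)) records$std_day <- NA_real_
  required <- c(
    "species_id", "season", "day_of_year", "ringing_year",
    "years_to_recovery", "distance_class"
  )
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "recovery records are missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  records <- records[, c(required, "sex", "std_day")]
  validate_records(records)
  if (is.null(species)) {
    species <- records |>
      dplyr::distinct(.data$species_id, .data$distance_class) |>
      dplyr::mutate(
        name = .data$species_id,
        window_spring_start = NA_integer_, window_spring_end = NA_integer_,
        window_autumn_start = NA_integer_, window_autumn_end = NA_integer_,
        day_mean = NA_real_, day_sd = NA_real_
      ) |>
      dplyr::select(
        "species_id", "name", "distance_class", dplyr::starts_with("window_"),
        "day_mean", "day_sd"
      )
  } else {
    species <- tibble::as_tibble(species)
    if (!"day_mean" %in% names(species)) species$day_mean <- NA_real_
    if (!"day_sd" %in% names(species)) species$day_sd <- NA_real_
    orphans <- setdiff(records$species_id, species$species_id)
    if (length(orphans) > 0) {
      abort(paste0(
        "records refer to species absent from the species table: ",
        paste(orphans, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      records = records,
      species = species,
      season = season,
      k = if (nrow(records) > 0) max(records$years_to_recovery) else 0L,
      first_year_excluded = FALSE,
      standardized = FALSE
    ),
    class = "recovery_data"
  )
}

validate_records <- function(records) {
  check_field <- function(ok, field) {
    bad <- which(!ok)
    if (length(bad) > 0) {
      abort(paste0(
        "invalid ", field, " in record row(s) ",
        paste(head(bad, 5), collapse = ", "),
        if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else ""
      ))
    }
  }
  check_field(
    !is.na(records$day_of_year) &
      records$day_of_year >= 1 & records$day_of_year <= 366,
    "day_of_year (must be in [1, 366])"
  )
  check_field(
    !is.na(records$years_to_recovery) & records$years_to_recovery >= 1,
    "years_to_recovery (must be >= 1)"
  )
  check_field(records$season %in% c("spring", "autumn"), "season")
  check_field(records$distance_class %in% c("short", "long"), "distance_class")
  check_field(records$sex %in% c("male", "female", "unknown"), "sex")
  check_field(!is.na(records$ringing_year), "ringing_year")
  invisible(records)
}

#' @export
print.recovery_data <- function(x, ...) {
  cat(sprintf(
    "<recovery_data> %s: %d records, %d species, k = %d\n",
    x$season, nrow(x$records), nrow(x$species), x$k
  ))
  cat(sprintf(
    "  first-year excluded: %s; days standardized: %s\n",
    x$first_year_excluded, x$standardized
  ))
  invisible(x)
}

refresh_k <- function(ds) {
  ds$k <- if (nrow(ds$records) > 0) max(ds$records$years_to_recovery) else 0L
  ds
}

window_cols <- function(season) {
  paste0("window_", season, c("_start", "_end"))
}
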