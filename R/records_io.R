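#' Read a ring-recovery table
#'
#' Reads a delimited text file with one row per dead-recovered bird and
#' assembles a [recovery_data] object. Required columns: `species_id`,
#' `season`, `day_of_year` (1 January = 1), `ringing_year`,
#' `years_to_recovery` (years from ringing to dead recovery, >= 1) and
#' `distance_class` (`"short"` for European winterers, `"long"` for
#' sub-Saharan migrants). A `sex` column (`male`/`female`/`unknown`) is
#' optional. Rows for other seasons are dropped.
#'
#' @param path Path to the recovery table.
#' @param season Season to extract, `"spring"` or `"autumn"`.
#' @param species_meta Optional species metadata: a path readable by
#'   [read_species_meta()] or a tibble in the same layout.
#' @param delim Field delimiter (default comma).
#' @return A [recovery_data] object with `k` set to the maximal
#'   years-to-recovery.
#' @export
read_recovery_table <- function(path, season = c("spring", "autumn"),
                                species_meta = NULL, delim = ",") {
  season <- match.arg(season)
  if (!file.exists(path)) abort(paste0("recovery table not found: ", path))
  raw <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c(
    "species_id", "season", "day_of_year", "ringing_year",
    "years_to_recovery", "distance_class"
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "recovery table ", path, " is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  parse_int <- function(x, field) {
    out <- suppressWarnings(as.integer(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad) > 0) {
      abort(paste0(
        "unparsable ", field, " in row(s) ",
        paste(head(bad, 5), collapse = ", "), " of ", path
      ))
    }
    out
  }
  records <- tibble::tibble(
    species_id = raw$species_id,
    season = raw$season,
    day_of_year = parse_int(raw$day_of_year, "day_of_year"),
    ringing_year = parse_int(raw$ringing_year, "ringing_year"),
    years_to_recovery = parse_int(raw$years_to_recovery, "years_to_recovery"),
    distance_class = raw$distance_class,
    sex = if ("sex" %in% names(raw)) raw$sex else "unknown"
  )
  records <- records[records$season == season, , drop = FALSE]
  if (is.character(species_meta)) species_meta <- read_species_meta(species_meta)
  recovery_data(records, species = species_meta, season = season)
}

#' Read a species metadata table
#'
#' Delimited text with columns `species_id`, `name`, `distance_class`,
#' `window_spring_start`, `window_spring_end`, `window_autumn_start`,
#' `window_autumn_end`. Window bounds are day-of-year integers defining the
#' species' migration period used by [apply_migration_window()]; empty or
#' `NA` bounds mean the species is not analysed in that season.
#'
#' @param path Path to the metadata file.
#' @param delim Field delimiter.
#' @return A tibble, one row per species.
#' @export
read_species_meta <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("species metadata not found: ", path))
  meta <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      species_id = readr::col_character(),
      name = readr::col_character(),
      distance_class = readr::col_character(),
      .default = readr::col_integer()
    )
  )
  required <- c("species_id", "name", "distance_class", unlist(lapply(
    c("spring", "autumn"), window_cols
  )))
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "species metadata is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (s in c("spring", "autumn")) {
    wc <- window_cols(s)
    bad <- which(!is.na(meta[[wc[1]]]) & !is.na(meta[[wc[2]]]) &
      meta[[wc[1]]] > meta[[wc[2]]])
    if (length(bad) > 0) {
      abort(paste0(
        "species metadata has inverted ", s, " window for: ",
        paste(meta$species_id[bad], collapse = ", ")
      ))
    }
  }
  meta$day_mean <- NA_real_
  meta$day_sd <- NA_real_
  meta
}

#' Write a recovery table
#'
#' Writes the records of a [recovery_data] object back to delimited text in
#' the same layout [read_recovery_table()] reads, so that read -> write ->
#' read round-trips record content.
#'
#' @param ds A [recovery_data] object.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_recovery_table <- function(ds, path, delim = ",") {
  stopifnot(inherits(ds, "recovery_data"))
  out <- ds$records[, c(
    "species_id", "season", "day_of_year", "ringing_year",
    "years_to_recovery", "distance_class", "sex"
  )]
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Exclude first-year deaths and shift life spans
#'
#' Birds found dead within their first year after ringing are removed so
#' that only adult survival is compared (juvenile survival is typically
#' lower and age is unknown in ringing data), and one year is subtracted
#' from all remaining life spans to avoid bias from the left-truncated
#' distribution: a bird recovered in year 2 becomes multinomial cell j = 1.
#' The horizon `k` is recomputed.
#'
#' @param ds A [recovery_data] object with raw spans.
#' @return The filtered, shifted [recovery_data].
#' @export
exclude_first_year <- function(ds) {
  stopifnot(inherits(ds, "recovery_data"))
  if (ds$first_year_excluded) {
    warn("first-year exclusion already applied; returning input unchanged")
    return(ds)
  }
  ds$records <- ds$records |>
    dplyr::filter(.data$years_to_recovery > 1L) |>
    dplyr::mutate(years_to_recovery = .data$years_to_recovery - 1L)
  ds$first_year_excluded <- TRUE
  refresh_k(ds)
}

#' Restrict records to each species' migration window
#'
#' Keeps only records whose capture day-of-year falls inside the species'
#' seasonal migration window (bounds inclusive). Windows are deliberately
#' narrower than the full migration period for species whose migration
#' overlaps breeding, so that actively breeding birds are excluded.
#'
#' @param ds A [recovery_data] object whose species table carries windows
#'   for `ds$season`.
#' @return The filtered [recovery_data]; `k` recomputed.
#' @export
apply_migration_window <- function(ds) {
  stopifnot(inherits(ds, "recovery_data"))
  wc <- window_cols(ds$season)
  sp_used <- unique(ds$records$species_id)
  meta <- ds$species[ds$species$species_id %in% sp_used, ]
  no_window <- meta$species_id[is.na(meta[[wc[1]]]) | is.na(meta[[wc[2]]])]
  if (length(no_window) > 0) {
    abort(paste0(
      "no ", ds$season, " migration window defined for species: ",
      paste(no_window, collapse = ", ")
    ))
  }
  lut <- setNames(seq_len(nrow(ds$species)), ds$species$species_id)
  idx <- lut[ds$records$species_id]
  lo <- ds$species[[wc[1]]][idx]
  hi <- ds$species[[wc[2]]][idx]
  keep <- ds$records$day_of_year >= lo & ds$records$day_of_year <= hi
  ds$records <- ds$records[keep, , drop = FALSE]
  refresh_k(ds)
}

#' Drop species with too few recoveries
#'
#' Retains species with at least `min_recoveries` birds recovered after the
#' first year (so [exclude_first_year()] must run first); all records of
#' dropped species are removed and the species table is pruned to the
#' retained species. The threshold exists because migration days are
#' standardized within species, which needs a minimal sample.
#'
#' @param ds A [recovery_data] object, first-year exclusion applied.
#' @param min_recoveries Minimum number of recoveries per species.
#' @return The filtered [recovery_data].
#' @export
apply_species_inclusion <- function(ds, min_recoveries = 5L) {
  stopifnot(inherits(ds, "recovery_data"))
  if (!ds$first_year_excluded) {
    abort("apply_species_inclusion() requires exclude_first_year() first")
  }
  counts <- table(ds$records$species_id)
  keep_sp <- names(counts)[counts >= min_recoveries]
  dropped <- setdiff(unique(ds$records$species_id), keep_sp)
  if (length(dropped) > 0) {
    inform(paste0(
      "dropping species with < ", min_recoveries, " recoveries: ",
      paste(dropped, collapse = ", ")
    ))
  }
  ds$records <- ds$records[ds$records$species_id %in% keep_sp, , drop = FALSE]
  ds$species <- ds$species[ds$species$species_id %in% keep_sp, , drop = FALSE]
  refresh_k(ds)
}

#' Standardize migration day within species
#'
#' Fills `std_day` by subtracting the species-specific mean day-of-year and
#' dividing by the species-specific standard deviation, and stores
#' `day_mean`/`day_sd` in the species table for back-transformation of
#' fitted curves to calendar dates. The mean and SD are computed over the
#' recovered birds in the analysis dataset.
#'
#' @param ds A [recovery_data] object after filtering.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return The [recovery_data] with `std_day` filled and `standardized`
#'   set; per species, `mean(std_day)` is 0 and `sd(std_day)` is 1 up to
#'   numerical tolerance.
#' @export
standardize_days <- function(ds, sd_type = c("sample", "population")) {
  stopifnot(inherits(ds, "recovery_data"))
  sd_type <- match.arg(sd_type)
  stats <- ds$records |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      day_mean = mean(.data$day_of_year),
      day_sd = sd(.data$day_of_year),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (sd_type == "population") {
    stats$day_sd <- stats$day_sd * sqrt((stats$n - 1) / stats$n)
  }
  degenerate <- stats$species_id[is.na(stats$day_sd) | stats$day_sd <= 0]
  if (length(degenerate) > 0) {
    abort(paste0(
      "cannot standardize: zero day-of-year variance for species: ",
      paste(degenerate, collapse = ", ")
    ))
  }
  lut_mean <- setNames(stats$day_mean, stats$species_id)
  lut_sd <- setNames(stats$day_sd, stats$species_id)
  ds$records$std_day <-
    (ds$records$day_of_year - lut_mean[ds$records$species_id]) /
      lut_sd[ds$records$species_id]
  names(ds$records$std_day) <- NULL
  m <- match(ds$species$species_id, stats$species_id)
  ds$species$day_mean <- stats$day_mean[m]
  ds$species$day_sd <- stats$day_sd[m]
  ds$standardized <- TRUE
  ds
}

#' Full data-preparation pipeline
#'
#' Applies, in order: migration-window filter, first-year exclusion,
#' species-inclusion filter, day standardization. This is the order the
#' analysis assumes (the inclusion rule counts recoveries *after* the first
#' year, and standardization uses the final analysis sample).
#'
#' @inheritParams apply_species_inclusion
#' @inheritParams standardize_days
#' @param window Apply the migration-window filter (default `TRUE`; set to
#'   `FALSE` when records carry no meaningful day-of-year, e.g. count
#'   expansions).
#' @return A prepared [recovery_data] ready for [fit_mcmc()].
#' @export
prepare_recovery_data <- function(ds, min_recoveries = 5L,
                                  sd_type = c("sample", "population"),
                                  window = TRUE) {
  if (window) ds <- apply_migration_window(ds)
  ds <- exclude_first_year(ds)
  ds <- apply_species_inclusion(ds, min_recoveries = min_recoveries)
  standardize_days(ds, sd_type = sd_type)
}

#' Correlation between ringing year and years to recovery
#'
#' Diagnostic for the assumption that recovery probability changes over
#' calendar time do not distort the span distribution: if span and ringing
#' year are uncorrelated, a temporal decline in recovery probability is
#' unlikely to bias the survival estimates. The standard error uses the
#' large-sample formula `sqrt((1 - r^2) / (n - 2))`.
#'
#' @param ds A [recovery_data] object with at least 3 records.
#' @return A tibble with columns `r`, `se`, `n`.
#' @export
ringing_year_span_correlation <- function(ds) {
  stopifnot(inherits(ds, "recovery_data"))
  x <- ds$records$ringing_year
  y <- ds$records$years_to_recovery
  n <- length(x)
  if (n < 3) abort("need at least 3 records for a correlation")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant column: correlation undefined")
  }
  r <- cor(x, y)
  tibble::tibble(r = r, se = sqrt((1 - r^2) / (n - 2)), n = n)
}
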