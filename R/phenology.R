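#' Read a capture-effort table
#'
#' Standardized-effort trapping counts: delimited text with columns
#' `species_id`, `sex` (`male`/`female`/`unknown`), `day_of_year`, `year`,
#' `count`. One row per species x sex x day x year; `count` is the number
#' of birds caught. Trapping effort is assumed fully standardized across
#' days and years (no effort correction is applied).
#'
#' @param path Path to the effort table.
#' @param delim Field delimiter.
#' @return A tibble of capture-effort records.
#' @export
read_effort_table <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("effort table not found: ", path))
  eff <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      species_id = readr::col_character(),
      sex = readr::col_character(),
      day_of_year = readr::col_integer(),
      year = readr::col_integer(),
      count = readr::col_integer()
    )
  )
  required <- c("species_id", "sex", "day_of_year", "year", "count")
  missing_cols <- setdiff(required, names(eff))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "effort table is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(eff$count < 0)) abort("negative counts in effort table")
  if (any(eff$day_of_year < 1 | eff$day_of_year > 366)) {
    abort("day_of_year outside [1, 366] in effort table")
  }
  eff
}

#' Daily capture percentages (migration-timing distribution)
#'
#' Percentage of birds caught per day over the migration window: birds per
#' day summed over all years, divided by the total number of birds, times
#' 100. Days inside the window with no captures are carried with percent
#' zero so cumulative sums are defined on every day.
#'
#' @param records Capture-effort tibble (see [read_effort_table()]).
#' @param species_id Species to extract.
#' @param sex Optional sex filter (`"male"` or `"female"`); `NULL` pools
#'   all records.
#' @param window Migration window as `c(first_day, last_day)` (inclusive);
#'   default spans the observed capture days of the selection.
#' @return A `timing_distribution` tibble: `species_id`, `sex`,
#'   `day_of_year`, `percent`, `cumulative_percent`; percents sum to 100.
#' @export
daily_percentages <- function(records, species_id, sex = NULL, window = NULL) {
  records <- tibble::as_tibble(records)
  sel <- records[records$species_id == species_id & records$count > 0, ]
  sex_label <- sex %||% "all"
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("male", "female", "unknown"))
    sel <- sel[sel$sex == sex, ]
  }
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] <= window[2])
    sel <- sel[sel$day_of_year >= window[1] & sel$day_of_year <= window[2], ]
  }
  total <- sum(sel$count)
  if (total == 0) {
    abort(paste0(
      "no captures for species ", species_id, ", sex filter '", sex_label, "'"
    ))
  }
  if (is.null(window)) window <- range(sel$day_of_year)
  by_day <- sel |>
    dplyr::group_by(day_of_year = .data$day_of_year) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  days <- tibble::tibble(day_of_year = seq(window[1], window[2]))
  out <- days |>
    dplyr::left_join(by_day, by = "day_of_year") |>
    dplyr::mutate(
      species_id = species_id,
      sex = sex_label,
      percent = 100 * dplyr::coalesce(.data$n, 0L) / total
    ) |>
    dplyr::mutate(cumulative_percent = cumsum(.data$percent)) |>
    dplyr::select(
      "species_id", "sex", "day_of_year", "percent", "cumulative_percent"
    )
  class(out) <- c("timing_distribution", class(out))
  attr(out, "total_birds") <- total
  out
}

#' Percentage of birds migrating before a given day
#'
#' Cumulative percentage strictly before `day` (captures on the day itself
#' are not counted as before; set `inclusive = TRUE` for the sensitivity
#' variant). Days at or before the window start give 0; days after the
#' window end give 100.
#'
#' @param dist A `timing_distribution` from [daily_percentages()].
#' @param day Day-of-year (typically a survival-optimum calendar day).
#' @param inclusive Count captures on `day` itself as before (default
#'   `FALSE`).
#' @return Percentage in `[0, 100]`.
#' @export
percent_before <- function(dist, day, inclusive = FALSE) {
  stopifnot(inherits(dist, "timing_distribution"), length(day) == 1)
  keep <- if (inclusive) {
    dist$day_of_year <= day
  } else {
    dist$day_of_year < day
  }
  sum(dist$percent[keep])
}

#' Sex-specific timing relative to the survival optimum
#'
#' Computes the percentage of males and of females migrating before the
#' survival-optimum day, from sex-specific daily capture distributions.
#' In protandric species the male distribution is shifted earlier, so the
#' male percentage exceeds the female percentage for any interior optimum.
#'
#' @param records Capture-effort tibble.
#' @param species_id Species to analyse.
#' @param optimum An `optimum_day` row (from [optimum_day()]) with
#'   `calendar_day` set, or a bare day-of-year.
#' @param window Migration window `c(first, last)`.
#' @param inclusive Passed to [percent_before()].
#' @return A tibble with one row per sex present: `species_id`, `sex`,
#'   `optimum_day`, `percent_before`, `n_birds`. A sex with zero captures
#'   is omitted with a warning.
#' @export
sex_comparison <- function(records, species_id, optimum, window = NULL,
                           inclusive = FALSE) {
  day <- if (inherits(optimum, "optimum_day") || is.data.frame(optimum)) {
    optimum$calendar_day[1]
  } else {
    optimum
  }
  if (is.na(day)) abort("optimum has no calendar day")
  rows <- lapply(c("male", "female"), function(sx) {
    dist <- tryCatch(
      daily_percentages(records, species_id, sex = sx, window = window),
      error = function(e) NULL
    )
    if (is.null(dist)) {
      warn(paste0("no ", sx, " captures for ", species_id, "; entry omitted"))
      return(NULL)
    }
    tibble::tibble(
      species_id = species_id, sex = sx, optimum_day = day,
      percent_before = percent_before(dist, day, inclusive = inclusive),
      n_birds = attr(dist, "total_birds")
    )
  })
  dplyr::bind_rows(rows)
}

#' Plot a timing distribution
#'
#' @param object A `timing_distribution` tibble.
#' @param optimum Optional day-of-year to mark (e.g. the survival optimum).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.timing_distribution <- function(object, optimum = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$day_of_year, .data$percent)) +
    ggplot2::geom_col(fill = "steelblue", width = 1) +
    ggplot2::labs(
      x = "day of year", y = "% of birds caught",
      title = paste0(
        "Migration timing: ", object$species_id[1], " (", object$sex[1], ")"
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(optimum)) {
    p <- p + ggplot2::geom_vline(xintercept = optimum, linetype = "dashed")
  }
  p
}
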