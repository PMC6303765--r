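default_grid <- function(lo, hi, n = 201L) {
  if (!is.finite(lo) || !is.finite(hi) || lo > hi) {
    abort("no standardized-day range available for this group")
  }
  if (lo == hi) {
    return(lo)
  }
  seq(lo, hi, length.out = n)
}

draws_matrix <- function(fit) {
  as.matrix(fit$draws[, setdiff(names(fit$draws), c(".chain", ".iteration"))])
}

curve_from_eta <- function(eta, grid, group, calendar_grid = NULL) {
  smat <- plogis(eta) # draws x grid
  qs <- apply(smat, 2, quantile, probs = c(0.025, 0.975), names = FALSE, type = 7)
  out <- tibble::tibble(
    group = group,
    std_day = grid,
    calendar_day = if (is.null(calendar_grid)) NA_real_ else calendar_grid,
    mean = colMeans(smat),
    lower = qs[1, ],
    upper = qs[2, ]
  )
  class(out) <- c("survival_curve", class(out))
  out
}

#' Population-level survival curve for a distance class
#'
#' Survival as a function of standardized migration day for short- or
#' long-distance migrants, evaluated per posterior draw through the
#' fixed-effects predictor (species deviations at zero, i.e. the
#' population-level curve), then summarized pointwise by the posterior
#' mean and central 95% credible band.
#'
#' @param fit A `migsurv_fit`.
#' @param group `"short"` or `"long"`.
#' @param grid Increasing vector of standardized days; default 201 points
#'   spanning the observed standardized-day range of the group.
#' @param year_value Value of the scaled year covariate at which to
#'   evaluate the curve (default 0, the mid-study year).
#' @return A `survival_curve` tibble: `group`, `std_day`, `calendar_day`
#'   (`NA` at population level), `mean`, `lower`, `upper`.
#' @export
curve_for_group <- function(fit, group = c("short", "long"), grid = NULL,
                            year_value = 0) {
  stopifnot(inherits(fit, "migsurv_fit"))
  group <- match.arg(group)
  if (nrow(fit$draws) == 0) abort("empty posterior")
  if (is.null(grid)) {
    rng <- fit$std_day_range[fit$std_day_range$distance_class == group, ]
    if (nrow(rng) == 0) abort(paste0("no records of distance class ", group))
    grid <- default_grid(rng$lo, rng$hi)
  }
  if (is.unsorted(grid, strictly = TRUE) && length(grid) > 1) {
    abort("grid must be strictly increasing")
  }
  B <- draws_matrix(fit)
  long <- as.numeric(group == "long")
  Xg <- rbind(
    1, grid, grid^2, long, long * grid, long * grid^2,
    year_value, year_value^2
  )
  eta <- B[, fixed_effect_names(), drop = FALSE] %*% Xg
  curve_from_eta(eta, grid, group)
}

#' Species-specific survival curve
#'
#' As [curve_for_group()] but adding the species' own posterior deviations
#' of the intercept and date effects per draw, and back-transforming the
#' standardized-day grid to calendar day-of-year using the species'
#' standardization constants (`calendar = day_mean + std_day * day_sd`).
#'
#' @param fit A `migsurv_fit` from a hierarchical fit.
#' @param species_id Species present in the fit.
#' @param grid Standardized-day grid; default spans the species' observed
#'   range.
#' @param year_value Scaled year covariate value (default 0).
#' @return A `survival_curve` tibble with `group = species_id` and
#'   `calendar_day` filled.
#' @export
curve_for_species <- function(fit, species_id, grid = NULL, year_value = 0) {
  stopifnot(inherits(fit, "migsurv_fit"))
  if (!species_id %in% fit$species_ids) {
    abort(paste0("species not in fit: ", species_id))
  }
  if (!fit$hierarchical) {
    abort("fit has no species-level deviations; use curve_for_group()")
  }
  meta <- fit$species[fit$species$species_id == species_id, ]
  if (is.null(grid)) {
    rng <- fit$species_day_range[
      fit$species_day_range$species_id == species_id,
    ]
    grid <- default_grid(rng$lo, rng$hi)
  }
  B <- draws_matrix(fit)
  long <- as.numeric(meta$distance_class == "long")
  Xg <- rbind(
    1, grid, grid^2, long, long * grid, long * grid^2,
    year_value, year_value^2
  )
  eta <- B[, fixed_effect_names(), drop = FALSE] %*% Xg
  a0 <- B[, paste0("a0[", species_id, "]")]
  a1 <- B[, paste0("a1[", species_id, "]")]
  a2 <- B[, paste0("a2[", species_id, "]")]
  eta <- eta + outer(a0, rep(1, length(grid))) + outer(a1, grid) +
    outer(a2, grid^2)
  calendar <- if (is.finite(meta$day_mean) && is.finite(meta$day_sd)) {
    meta$day_mean + grid * meta$day_sd
  } else {
    NULL
  }
  curve_from_eta(eta, grid, species_id, calendar)
}

#' Locate the survival optimum on a curve
#'
#' Argmax of the posterior-mean survival curve. Ties resolve to the
#' earliest grid point; `at_boundary` flags an argmax attained at a grid
#' endpoint (the optimum then lies at or beyond the edge of the evaluated
#' timing range). Because the inverse logit is strictly increasing, the
#' argmax is identical on the survival and logit scales; for a downward
#' parabola on the logit scale it matches the vertex
#' `d* = -b_day_eff / (2 b_day2_eff)` within one grid step.
#'
#' @param curve A `survival_curve` tibble.
#' @return An `optimum_day` tibble (one row): `group`, `std_day`,
#'   `calendar_day` (rounded to the nearest day, `NA` if the curve has no
#'   calendar grid), `calendar_day_exact`, `at_boundary`.
#' @export
optimum_day <- function(curve) {
  stopifnot(nrow(curve) > 0)
  i <- which.max(curve$mean)
  out <- tibble::tibble(
    group = curve$group[1],
    std_day = curve$std_day[i],
    calendar_day = if (is.na(curve$calendar_day[i])) {
      NA_integer_
    } else {
      as.integer(round(curve$calendar_day[i]))
    },
    calendar_day_exact = curve$calendar_day[i],
    at_boundary = i == 1L || i == nrow(curve)
  )
  class(out) <- c("optimum_day", class(out))
  out
}

#' Per-draw distribution of the survival optimum
#'
#' Uncertainty on the optimum: the argmax is located on each posterior
#' draw's own curve rather than on the posterior-mean curve.
#'
#' @inheritParams curve_for_group
#' @return A tibble with one row per draw: `.chain`, `.iteration`,
#'   `std_day`, `at_boundary`.
#' @export
optimum_day_draws <- function(fit, group = c("short", "long"), grid = NULL,
                              year_value = 0) {
  stopifnot(inherits(fit, "migsurv_fit"))
  group <- match.arg(group)
  if (is.null(grid)) {
    rng <- fit$std_day_range[fit$std_day_range$distance_class == group, ]
    grid <- default_grid(rng$lo, rng$hi)
  }
  B <- draws_matrix(fit)
  long <- as.numeric(group == "long")
  Xg <- rbind(
    1, grid, grid^2, long, long * grid, long * grid^2,
    year_value, year_value^2
  )
  eta <- B[, fixed_effect_names(), drop = FALSE] %*% Xg
  idx <- apply(eta, 1, which.max)
  tibble::tibble(
    .chain = fit$draws$.chain, .iteration = fit$draws$.iteration,
    std_day = grid[idx],
    at_boundary = idx == 1L | idx == length(grid)
  )
}

#' Build a degenerate fit from known parameters
#'
#' Wraps a [model_params] object as a one-draw posterior so the curve and
#' optimum machinery can be applied to fixed, known coefficients (e.g.
#' closed-form checks, or plotting a true curve alongside a fitted one).
#'
#' @param params A [model_params].
#' @param std_day_range Standardized-day range to attach, as
#'   `c(lo, hi)` (used for default grids).
#' @param species Optional species metadata tibble (as in
#'   [recovery_data()]) for calendar back-transformation.
#' @param season Season label.
#' @return A `migsurv_fit` whose posterior is a point mass at `params`.
#' @export
fit_from_params <- function(params, std_day_range = c(-2.5, 2.5),
                            species = NULL, season = "spring") {
  stopifnot(inherits(params, "model_params"))
  hierarchical <- !is.null(params$species)
  species_ids <- if (hierarchical) params$species$species_id else character()
  row <- c(params$fixed)
  if (hierarchical) {
    row <- c(
      row, setNames(params$sigma, paste0("sigma", 0:2)),
      setNames(params$species$a0, paste0("a0[", species_ids, "]")),
      setNames(params$species$a1, paste0("a1[", species_ids, "]")),
      setNames(params$species$a2, paste0("a2[", species_ids, "]"))
    )
  }
  draws <- dplyr::bind_cols(
    tibble::tibble(.chain = 1L, .iteration = 1L),
    tibble::as_tibble(as.list(row))
  )
  rng <- tibble::tibble(
    distance_class = c("short", "long"),
    lo = std_day_range[1], hi = std_day_range[2]
  )
  sp_rng <- tibble::tibble(
    species_id = species_ids,
    lo = std_day_range[1], hi = std_day_range[2]
  )
  structure(
    list(
      draws = draws,
      settings = NULL, priors = NULL,
      species = species %||% tibble::tibble(
        species_id = species_ids,
        name = species_ids,
        distance_class = rep("long", length(species_ids)),
        day_mean = NA_real_, day_sd = NA_real_
      ),
      species_ids = species_ids,
      hierarchical = hierarchical,
      active = setNames(rep(TRUE, 8), fixed_effect_names()),
      year_center = 0, year_scale = 1,
      k = NA_integer_, season = season,
      n_records = 0L,
      std_day_range = rng,
      species_day_range = sp_rng,
      map = row,
      acceptance = NULL,
      data_fingerprint = NA_character_
    ),
    class = "migsurv_fit"
  )
}

#' Plot a survival curve
#'
#' @param object A `survival_curve` tibble.
#' @param calendar Plot against calendar day-of-year when available.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_curve <- function(object, calendar = FALSE, ...) {
  xvar <- if (calendar && !all(is.na(object$calendar_day))) {
    "calendar_day"
  } else {
    "std_day"
  }
  ggplot2::ggplot(object, ggplot2::aes(.data[[xvar]], .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80"
    ) +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::labs(
      x = if (xvar == "std_day") "standardized migration day" else "day of year",
      y = "annual survival",
      title = paste0("Survival vs timing: ", object$group[1])
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
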