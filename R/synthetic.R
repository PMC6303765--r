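#' Ground-truth configuration for the synthetic-data generator
#'
#' Defines the data-generating process the analysis assumes: a community of
#' migrant species with Gaussian migration phenology (males earlier than
#' females by `protandry_shift` days), logit-linear annual survival in
#' standardized migration day, distance class and scaled year, and dead
#' recoveries distributed over years 1..`k_max` after the first year by the
#' conditional multinomial cell probabilities.
#'
#' Default fixed effects give short-distance migrants survival declining
#' with date and long-distance migrants a bell-shaped survival-date curve
#' (effective long-distance coefficients `b_day + b_day_dist = 0.2`,
#' `b_day2 + b_day2_dist = -0.5`, so a true standardized-day optimum of
#' 0.2); baseline annual survival is about 0.43, typical of small
#' passerines. Default community structure mirrors a spring analysis: 8
#' species (3 short-, 5 long-distance), ringing years 1950-2002, recovery
#' horizon 9 years, and 375 recovered adults per species.
#'
#' @param fixed Named numeric vector of true fixed effects (see
#'   [model_params()]); missing names default to the values above.
#' @param sigma True hierarchical SDs `c(sigma0, sigma1, sigma2)` (zero
#'   allowed: species deviations exactly zero).
#' @param n_species,n_per_species Community size and recovered adults per
#'   species.
#' @param species_day_means,species_day_sds Per-species phenology mean and
#'   SD in days (recycled to `n_species`).
#' @param distance_classes Per-species `"short"`/`"long"` (recycled).
#' @param year_range Ringing years, `c(first, last)`.
#' @param k_max Recovery horizon after the first-year shift.
#' @param protandry_shift Days by which the male mean precedes the female
#'   mean.
#' @param first_year_fraction Fraction of records relabelled as first-year
#'   deaths (span 1), to be removed again by [exclude_first_year()].
#' @param recovery_decline_rate Optional per-year exponential decline in
#'   recovery probability over the calendar year of death (default 0:
#'   constant recovery probability, which the conditional likelihood
#'   assumes it is immune to).
#' @param seed Master seed for the generator.
#' @return A `truth_config` object.
#' @export
truth_config <- function(fixed = c(
                           b0 = -0.3, b_day = -0.3, b_day2 = -0.1,
                           b_dist = 0.3, b_day_dist = 0.5, b_day2_dist = -0.4,
                           b_year = 0.1, b_year2 = -0.05
                         ),
                         sigma = c(0.2, 0.1, 0.05),
                         n_species = 8L, n_per_species = 375L,
                         species_day_means = NULL,
                         species_day_sds = 8,
                         distance_classes = NULL,
                         year_range = c(1950L, 2002L),
                         k_max = 9L,
                         protandry_shift = 6,
                         first_year_fraction = 0,
                         recovery_decline_rate = 0,
                         seed = 1L) {
  full <- c(
    b0 = -0.3, b_day = -0.3, b_day2 = -0.1,
    b_dist = 0.3, b_day_dist = 0.5, b_day2_dist = -0.4,
    b_year = 0.1, b_year2 = -0.05
  )
  if (length(fixed) > 0) {
    if (is.null(names(fixed)) || any(!names(fixed) %in% names(full))) {
      abort("truth_config: fixed must be named fixed-effect coefficients")
    }
    full[names(fixed)] <- fixed
  }
  if (length(sigma) != 3 || any(sigma < 0)) {
    abort("truth_config: sigma must be three non-negative values")
  }
  if (n_species < 1) abort("truth_config: n_species must be >= 1")
  if (n_per_species < 2) abort("truth_config: n_per_species must be >= 2")
  if (is.null(species_day_means)) {
    species_day_means <- round(seq(115, 150, length.out = n_species))
  }
  species_day_means <- rep_len(species_day_means, n_species)
  species_day_sds <- rep_len(species_day_sds, n_species)
  if (any(species_day_sds <= 0)) {
    abort("truth_config: species_day_sds must be positive")
  }
  if (is.null(distance_classes)) {
    distance_classes <- rep(
      c("short", "long"),
      c(ceiling(3 / 8 * n_species), n_species - ceiling(3 / 8 * n_species))
    )
  }
  distance_classes <- rep_len(distance_classes, n_species)
  if (any(!distance_classes %in% c("short", "long"))) {
    abort("truth_config: distance_classes must be 'short' or 'long'")
  }
  if (length(year_range) != 2 || year_range[1] > year_range[2]) {
    abort("truth_config: year_range must be c(first, last) with first <= last")
  }
  if (k_max < 1) abort("truth_config: k_max must be >= 1")
  if (first_year_fraction < 0 || first_year_fraction >= 1) {
    abort("truth_config: first_year_fraction must be in [0, 1)")
  }
  if (recovery_decline_rate < 0) {
    abort("truth_config: recovery_decline_rate must be >= 0")
  }
  structure(
    list(
      fixed = full,
      sigma = setNames(as.numeric(sigma), c("sigma0", "sigma1", "sigma2")),
      n_species = as.integer(n_species),
      n_per_species = as.integer(n_per_species),
      species_day_means = as.numeric(species_day_means),
      species_day_sds = as.numeric(species_day_sds),
      distance_classes = distance_classes,
      year_range = as.integer(year_range),
      k_max = as.integer(k_max),
      protandry_shift = as.numeric(protandry_shift),
      first_year_fraction = as.numeric(first_year_fraction),
      recovery_decline_rate = as.numeric(recovery_decline_rate),
      seed = as.integer(seed)
    ),
    class = "truth_config"
  )
}

truth_params <- function(cfg, deviations) {
  model_params(
    fixed = cfg$fixed,
    species = deviations,
    sigma = pmax(cfg$sigma, 1e-12)
  )
}

truth_species_meta <- function(cfg) {
  ids <- sprintf("sp%02d", seq_len(cfg$n_species))
  lo <- as.integer(floor(cfg$species_day_means - 3 * cfg$species_day_sds))
  hi <- as.integer(ceiling(cfg$species_day_means + 3 * cfg$species_day_sds))
  tibble::tibble(
    species_id = ids, name = ids,
    distance_class = cfg$distance_classes,
    window_spring_start = lo, window_spring_end = hi,
    window_autumn_start = lo, window_autumn_end = hi,
    day_mean = NA_real_, day_sd = NA_real_
  )
}

# integer day from a normal truncated to [lo, hi]
rday_trunc <- function(n, mean, sd, lo, hi) {
  p <- runif(
    n, stats::pnorm(lo - 0.5, mean, sd), stats::pnorm(hi + 0.5, mean, sd)
  )
  pmin(pmax(round(qnorm(p, mean, sd)), lo), hi)
}

#' Generate a synthetic ring-recovery dataset with known truth
#'
#' Simulates the full data-generating process: species deviations drawn
#' from their hierarchical normals; per bird a capture day from the
#' species/sex phenology (truncated to the species window), a uniform
#' ringing year, true annual survival through the logit-linear predictor,
#' and a recovery year drawn from the conditional multinomial cell
#' probabilities over `k_max` years. Raw life spans are the recovery year
#' plus one (the generated tables are pre-exclusion), and a
#' `first_year_fraction` of records is relabelled as first-year deaths so
#' the exclusion filter has work to do. With a positive
#' `recovery_decline_rate`, records are thinned with probability declining
#' exponentially in the calendar year of death, emulating the documented
#' decline of ring-reporting rates.
#'
#' @param cfg A [truth_config].
#' @param effort_birds_per_species Birds per species in the companion
#'   capture-effort table (see [generate_effort()]).
#' @param season Season label written into the records.
#' @return A `synthetic_bundle`: list with `dataset` (a [recovery_data]
#'   with raw spans), `effort` (capture-effort tibble), and `truth` (the
#'   config, realized [model_params], and per-record `std_day`,
#'   `year_scaled` and `survival` aligned with the records).
#' @export
generate_dataset <- function(cfg, effort_birds_per_species = 500L,
                             season = "spring") {
  stopifnot(inherits(cfg, "truth_config"))
  set.seed(cfg$seed)
  meta <- truth_species_meta(cfg)
  nsp <- cfg$n_species
  deviations <- tibble::tibble(
    species_id = meta$species_id,
    a0 = rnorm(nsp, 0, cfg$sigma[1]),
    a1 = rnorm(nsp, 0, cfg$sigma[2]),
    a2 = rnorm(nsp, 0, cfg$sigma[3])
  )
  params <- truth_params(cfg, deviations)
  n <- nsp * cfg$n_per_species
  g <- rep(seq_len(nsp), each = cfg$n_per_species)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  shift <- ifelse(sex == "male", -cfg$protandry_shift / 2, cfg$protandry_shift / 2)
  lo <- meta$window_spring_start[g]
  hi <- meta$window_spring_end[g]
  day <- rday_trunc(n, cfg$species_day_means[g] + shift, cfg$species_day_sds[g],
    lo, hi
  )
  year <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n, replace = TRUE)
  std_day <- (day - cfg$species_day_means[g]) / cfg$species_day_sds[g]
  ys <- scale_years(
    year,
    center = mean(cfg$year_range),
    scale = diff(cfg$year_range) / 2
  )
  frame <- tibble::tibble(
    species_id = meta$species_id[g],
    std_day = std_day,
    distance_class = meta$distance_class[g]
  )
  s_true <- annual_survival(frame, params, year_scaled = ys$y)
  j_post <- simulate_recovery_year(s_true, cfg$k_max)
  raw_span <- j_post + 1L
  if (cfg$first_year_fraction > 0) {
    fy <- rbinom(n, 1, cfg$first_year_fraction) == 1
    raw_span[fy] <- 1L
  }
  keep <- rep(TRUE, n)
  if (cfg$recovery_decline_rate > 0) {
    death_year <- year + raw_span
    w <- exp(-cfg$recovery_decline_rate * (death_year - min(death_year)))
    keep <- runif(n) < w
  }
  records <- tibble::tibble(
    species_id = meta$species_id[g],
    season = season,
    day_of_year = as.integer(day),
    ringing_year = as.integer(year),
    years_to_recovery = raw_span,
    distance_class = meta$distance_class[g],
    sex = sex
  )[keep, ]
  dataset <- recovery_data(records, species = meta, season = season)
  effort <- generate_effort(cfg, birds_per_species = effort_birds_per_species)
  structure(
    list(
      dataset = dataset,
      effort = effort,
      truth = list(
        cfg = cfg,
        params = params,
        year_center = ys$center,
        year_scale = ys$scale,
        std_day = std_day[keep],
        year_scaled = ys$y[keep],
        survival = s_true[keep]
      )
    ),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle> %d recovery records, %d species, %d effort rows\n",
    nrow(x$dataset$records), x$truth$cfg$n_species, nrow(x$effort)
  ))
  invisible(x)
}

#' Generate a synthetic capture-effort table
#'
#' Standardized-effort trapping counts with Gaussian phenology per species
#' x sex x year: each species contributes `birds_per_species` birds, split
#' evenly between the sexes, with the male daily mean earlier than the
#' female mean by the configured protandry shift. Days are truncated to
#' the species window; years are uniform over the year range. Determined
#' by `cfg$seed` (offset so the table is independent of the recovery
#' draws).
#'
#' @param cfg A [truth_config].
#' @param birds_per_species Total birds per species (split across sexes;
#'   totals match within rounding).
#' @return A capture-effort tibble (`species_id`, `sex`, `day_of_year`,
#'   `year`, `count`).
#' @export
generate_effort <- function(cfg, birds_per_species = 500L) {
  stopifnot(inherits(cfg, "truth_config"))
  set.seed((cfg$seed + 499979L) %% .Machine$integer.max)
  meta <- truth_species_meta(cfg)
  years <- seq(cfg$year_range[1], cfg$year_range[2])
  n_m <- floor(birds_per_species / 2)
  n_f <- birds_per_species - n_m
  rows <- list()
  for (g in seq_len(cfg$n_species)) {
    for (sx in c("male", "female")) {
      n_sx <- if (sx == "male") n_m else n_f
      shift <- if (sx == "male") -cfg$protandry_shift / 2 else cfg$protandry_shift / 2
      day <- rday_trunc(
        n_sx, cfg$species_day_means[g] + shift, cfg$species_day_sds[g],
        meta$window_spring_start[g], meta$window_spring_end[g]
      )
      yr <- sample(years, n_sx, replace = TRUE)
      tab <- tibble::tibble(day_of_year = day, year = yr) |>
        dplyr::count(.data$day_of_year, .data$year, name = "count")
      rows[[length(rows) + 1]] <- tibble::tibble(
        species_id = meta$species_id[g], sex = sx,
        day_of_year = as.integer(tab$day_of_year),
        year = as.integer(tab$year), count = as.integer(tab$count)
      )
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$species_id, .data$sex, .data$year, .data$day_of_year)
}

#' Write a capture-effort table
#'
#' @param effort Capture-effort tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_effort_table <- function(effort, path, delim = ",") {
  readr::write_delim(effort, path, delim = delim)
  invisible(path)
}

#' Serialize generator truth to a flat text file
#'
#' Writes the ground truth of a [generate_dataset()] bundle as flat
#' `name,value` text: fixed effects, hierarchical SDs, realized species
#' deviations, and the generator configuration scalars.
#'
#' @param bundle A `synthetic_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(bundle, path) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  tr <- bundle$truth
  p <- tr$params
  sp <- p$species
  rows <- c(
    setNames(as.list(p$fixed), names(p$fixed)),
    setNames(as.list(tr$cfg$sigma), names(tr$cfg$sigma)),
    setNames(as.list(sp$a0), paste0("a0[", sp$species_id, "]")),
    setNames(as.list(sp$a1), paste0("a1[", sp$species_id, "]")),
    setNames(as.list(sp$a2), paste0("a2[", sp$species_id, "]")),
    list(
      n_species = tr$cfg$n_species,
      n_per_species = tr$cfg$n_per_species,
      k_max = tr$cfg$k_max,
      protandry_shift = tr$cfg$protandry_shift,
      first_year_fraction = tr$cfg$first_year_fraction,
      recovery_decline_rate = tr$cfg$recovery_decline_rate,
      year_first = tr$cfg$year_range[1],
      year_last = tr$cfg$year_range[2],
      year_center = tr$year_center,
      year_scale = tr$year_scale,
      seed = tr$cfg$seed
    )
  )
  out <- tibble::tibble(
    name = names(rows),
    value = vapply(rows, function(v) format(v, digits = 17), "")
  )
  readr::write_csv(out, path)
  invisible(path)
}
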