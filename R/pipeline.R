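#' Run configuration for the pipeline commands
#'
#' Assembles the settings the pipeline runners ([run_simulate()],
#' [run_fit()], [run_report()], [run_sensitivity()]) share: input/output
#' paths, season and sex filters, filter thresholds, priors, MCMC
#' settings, curve-grid resolution, the percent-before convention and the
#' master seed. All defaults mirror the analysis defaults of the
#' underlying functions.
#'
#' @param out_dir Output directory (created if missing).
#' @param recovery_table,species_meta,effort_table Input paths (for
#'   [run_fit()]/[run_report()]; [run_simulate()] writes them).
#' @param season `"spring"` or `"autumn"`.
#' @param sex `"all"`, `"male"` or `"female"` (dataset filter before
#'   fitting).
#' @param min_recoveries Species-inclusion threshold.
#' @param priors A [prior_spec].
#' @param mcmc An [mcmc_settings]; its seed is overridden by `seed`.
#' @param grid_points Points in the standardized-day curve grid.
#' @param percent_before_inclusive Count birds on the optimum day as
#'   "before" (default FALSE).
#' @param truth Optional named list of [truth_config()] overrides for
#'   [run_simulate()].
#' @param seed Master seed recorded in every output.
#' @return A `run_config` object (a list).
#' @export
run_config <- function(out_dir = ".",
                       recovery_table = NULL, species_meta = NULL,
                       effort_table = NULL,
                       season = "spring", sex = "all",
                       min_recoveries = 5L,
                       priors = prior_spec(), mcmc = mcmc_settings(),
                       grid_points = 201L,
                       percent_before_inclusive = FALSE,
                       truth = list(), seed = 1L) {
  stopifnot(season %in% c("spring", "autumn"), sex %in% c("all", "male", "female"))
  mcmc$seed <- as.integer(seed)
  structure(
    list(
      out_dir = out_dir,
      recovery_table = recovery_table, species_meta = species_meta,
      effort_table = effort_table,
      season = season, sex = sex,
      min_recoveries = as.integer(min_recoveries),
      priors = priors, mcmc = mcmc,
      grid_points = as.integer(grid_points),
      percent_before_inclusive = isTRUE(percent_before_inclusive),
      truth = truth, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Flat, human-editable YAML; recognized top-level keys match the
#' arguments of [run_config()], with `priors`, `mcmc` and `truth` as
#' nested maps of the corresponding constructor arguments.
#'
#' @param path Path to the YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading config files requires the 'yaml' package")
  }
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  args <- raw[setdiff(names(raw), c("priors", "mcmc"))]
  if (!is.null(raw$priors)) args$priors <- do.call(prior_spec, raw$priors)
  if (!is.null(raw$mcmc)) args$mcmc <- do.call(mcmc_settings, raw$mcmc)
  do.call(run_config, args)
}

config_fingerprint <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

write_sidecar <- function(path, config, extra = list()) {
  meta <- c(
    list(
      package = "migsurv",
      version = as.character(utils::packageVersion("migsurv")),
      seed = config$seed,
      config_hash = config_fingerprint(config)
    ),
    extra
  )
  lines <- vapply(
    names(meta),
    function(nm) paste0(nm, ": ", paste(format(meta[[nm]]), collapse = " ")),
    ""
  )
  writeLines(lines, paste0(path, ".meta"))
  invisible(path)
}

#' Simulate a synthetic study to files
#'
#' Generates a synthetic recovery table, capture-effort table and ground-
#' truth file under `config$out_dir` (`recoveries.csv`, `effort.csv`,
#' `truth.csv`), each with a `.meta` sidecar recording the seed, config
#' hash and package version. Reruns with an identical config are
#' byte-identical.
#'
#' @param config A `run_config`; `config$truth` holds [truth_config()]
#'   overrides and `config$seed` seeds the generator.
#' @return Named character vector of the three file paths, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- do.call(truth_config, modifyList(config$truth, list(seed = config$seed)))
  bundle <- generate_dataset(cfg, season = config$season)
  paths <- c(
    recoveries = file.path(config$out_dir, "recoveries.csv"),
    effort = file.path(config$out_dir, "effort.csv"),
    truth = file.path(config$out_dir, "truth.csv")
  )
  write_recovery_table(bundle$dataset, paths["recoveries"])
  readr::write_csv(bundle$dataset$species[, 1:7], file.path(
    config$out_dir, "species_meta.csv"
  ))
  write_effort_table(bundle$effort, paths["effort"])
  write_truth(bundle, paths["truth"])
  for (p in paths) write_sidecar(p, config)
  inform(sprintf(
    "simulated %d recovery records and %d effort rows to %s",
    nrow(bundle$dataset$records), nrow(bundle$effort), config$out_dir
  ))
  invisible(paths)
}

#' Fit the survival model from files
#'
#' Reads the recovery table (and species metadata when given), applies the
#' preparation pipeline in the analysis order (migration window,
#' first-year exclusion, species inclusion, standardization), logs record
#' and species counts after each stage, fits the model and writes the
#' posterior draws (`posterior.csv`), the summary table (`summary.csv`)
#' and the convergence report (`rhat.csv`) to `config$out_dir`.
#'
#' @param config A `run_config` with `recovery_table` (and optionally
#'   `species_meta`) set.
#' @return The `migsurv_fit`, invisibly. Attribute `"converged"` is FALSE
#'   when any parameter has `r_hat > 1.1`.
#' @export
run_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$recovery_table)) abort("config$recovery_table is not set")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- config$species_meta
  ds <- read_recovery_table(config$recovery_table,
    season = config$season, species_meta = meta
  )
  log_stage <- function(label, ds) {
    inform(sprintf(
      "%s: %d records, %d species", label, nrow(ds$records),
      length(unique(ds$records$species_id))
    ))
  }
  log_stage("input", ds)
  has_windows <- all(!is.na(ds$species[[window_cols(config$season)[1]]]))
  if (has_windows) {
    ds <- apply_migration_window(ds)
    log_stage("after migration window", ds)
  }
  ds <- exclude_first_year(ds)
  log_stage("after first-year exclusion", ds)
  ds <- apply_species_inclusion(ds, min_recoveries = config$min_recoveries)
  log_stage("after species inclusion", ds)
  ds <- standardize_days(ds)
  sex <- if (config$sex == "all") NULL else config$sex
  fit <- fit_mcmc(ds, config$priors, config$mcmc, sex = sex)
  rh <- gelman_rubin(fit)
  paths <- c(
    posterior = file.path(config$out_dir, "posterior.csv"),
    summary = file.path(config$out_dir, "summary.csv"),
    rhat = file.path(config$out_dir, "rhat.csv")
  )
  readr::write_csv(fit$draws, paths["posterior"])
  readr::write_csv(summarize_posterior(fit), paths["summary"])
  readr::write_csv(rh, paths["rhat"])
  for (p in paths) {
    write_sidecar(p, config, extra = list(
      data_fingerprint = fit$data_fingerprint,
      year_center = fit$year_center, year_scale = fit$year_scale, k = fit$k
    ))
  }
  attr(fit, "converged") <- !any(rh$flagged)
  if (any(rh$flagged)) {
    warn(paste0(
      "convergence warning: r_hat > 1.1 for ",
      paste(rh$parameter[rh$flagged], collapse = ", ")
    ))
  }
  invisible(fit)
}

#' Curves, optima and percent-before report
#'
#' From a fitted model and a capture-effort table, writes the population-
#' level and species-specific survival curves (`curves.csv`), the optimum
#' table (`optima.csv`, boundary-flagged) and the sex-specific
#' percent-before-optimum table (`percent_before.csv`).
#'
#' @param config A `run_config` with `effort_table` set.
#' @param fit A `migsurv_fit` (from [run_fit()] or [fit_mcmc()]).
#' @return Named list with `curves`, `optima`, `percent_before` tibbles,
#'   invisibly.
#' @export
run_report <- function(config, fit) {
  stopifnot(inherits(config, "run_config"), inherits(fit, "migsurv_fit"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  groups <- unique(fit$std_day_range$distance_class)
  curves <- dplyr::bind_rows(
    lapply(groups, function(g) curve_for_group(fit, g)),
    if (fit$hierarchical) {
      lapply(fit$species_ids, function(sp) curve_for_species(fit, sp))
    }
  )
  optima <- dplyr::bind_rows(lapply(
    split(curves, factor(curves$group, levels = unique(curves$group))),
    optimum_day
  ))
  pb <- NULL
  if (!is.null(config$effort_table)) {
    effort <- read_effort_table(config$effort_table)
    sp_with_opt <- optima[optima$group %in% fit$species_ids &
      !is.na(optima$calendar_day), ]
    pb <- purrr::map_dfr(seq_len(nrow(sp_with_opt)), function(i) {
      sp <- sp_with_opt$group[i]
      if (!sp %in% effort$species_id) {
        return(NULL)
      }
      sex_comparison(effort, sp, sp_with_opt[i, ],
        inclusive = config$percent_before_inclusive
      )
    })
  }
  paths <- c(
    curves = file.path(config$out_dir, "curves.csv"),
    optima = file.path(config$out_dir, "optima.csv")
  )
  readr::write_csv(curves, paths["curves"])
  readr::write_csv(optima, paths["optima"])
  if (!is.null(pb)) {
    readr::write_csv(pb, file.path(config$out_dir, "percent_before.csv"))
    paths <- c(paths, percent_before = file.path(
      config$out_dir, "percent_before.csv"
    ))
  }
  for (p in paths) write_sidecar(p, config)
  invisible(list(curves = curves, optima = optima, percent_before = pb))
}

#' Prior-sensitivity rerun from a config
#'
#' Fits the prepared dataset under the configured prior and a comparison
#' prior (fixed-effect SD doubled by default) and writes the side-by-side
#' summary and the per-parameter maximum difference in posterior means.
#'
#' @param config A `run_config` with `recovery_table` set.
#' @param alt_priors Alternative [prior_spec] (default: fixed-effect SD
#'   doubled).
#' @return The `prior_sensitivity` object, invisibly.
#' @export
run_sensitivity <- function(config, alt_priors = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(alt_priors)) {
    alt_priors <- prior_spec(
      fixed_mean = config$priors$fixed_mean,
      fixed_sd = 2 * config$priors$fixed_sd,
      sigma_df = config$priors$sigma_df,
      sigma_scale = config$priors$sigma_scale
    )
  }
  ds <- read_recovery_table(config$recovery_table,
    season = config$season, species_meta = config$species_meta
  )
  has_windows <- all(!is.na(ds$species[[window_cols(config$season)[1]]]))
  ds <- prepare_recovery_data(ds,
    min_recoveries = config$min_recoveries, window = has_windows
  )
  sens <- prior_sensitivity(ds, list(config$priors, alt_priors), config$mcmc)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    sens$summaries, file.path(config$out_dir, "sensitivity_summaries.csv")
  )
  readr::write_csv(
    sens$delta, file.path(config$out_dir, "sensitivity_delta.csv")
  )
  invisible(sens)
}
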