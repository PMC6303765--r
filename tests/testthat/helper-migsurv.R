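# shared builders and a cache so expensive fits are computed once per run

make_records <- function(spans,
                         species_id = "sp01",
                         day_of_year = 120L,
                         ringing_year = 1970L,
                         distance_class = "short",
                         sex = "unknown",
                         season = "spring") {
  n <- length(spans)
  tibble::tibble(
    species_id = rep_len(species_id, n),
    season = season,
    day_of_year = as.integer(rep_len(day_of_year, n)),
    ringing_year = as.integer(rep_len(ringing_year, n)),
    years_to_recovery = as.integer(spans),
    distance_class = rep_len(distance_class, n),
    sex = rep_len(sex, n)
  )
}

# two-species prepared dataset, deterministic, for quick likelihood tests
small_prepared <- function(n_per = 30, seed = 5, k_max = 5) {
  set.seed(seed)
  recs <- dplyr::bind_rows(
    make_records(
      sample(2:(k_max + 1), n_per, replace = TRUE),
      species_id = "spA",
      day_of_year = sample(110:140, n_per, replace = TRUE),
      ringing_year = sample(1960:1990, n_per, replace = TRUE),
      distance_class = "short"
    ),
    make_records(
      sample(2:(k_max + 1), n_per, replace = TRUE),
      species_id = "spB",
      day_of_year = sample(120:150, n_per, replace = TRUE),
      ringing_year = sample(1960:1990, n_per, replace = TRUE),
      distance_class = "long"
    )
  )
  ds <- recovery_data(recs, season = "spring")
  ds <- exclude_first_year(ds)
  standardize_days(ds)
}

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fit_cache[[key]])) {
    assign(key, force(expr), envir = .fit_cache)
  }
  .fit_cache[[key]]
}

# the parameter-recovery study conditions: defaults of truth_config()
recovery_bundle <- function() {
  cached("bundle", generate_dataset(truth_config(seed = 101)))
}

recovery_fit <- function() {
  cached("fit", {
    prep <- prepare_recovery_data(recovery_bundle()$dataset)
    suppressWarnings(fit_mcmc(prep, settings = mcmc_settings(seed = 202)))
  })
}
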