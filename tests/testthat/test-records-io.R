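test_that("recovery tables parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  recs <- make_records(c(2, 3, 5),
    day_of_year = c(100L, 120L, 140L),
    ringing_year = c(1960L, 1975L, 1990L)
  )
  readr::write_csv(recs, path)
  ds <- read_recovery_table(path, "spring")
  expect_s3_class(ds, "recovery_data")
  expect_equal(nrow(ds$records), 3)
  expect_equal(ds$k, 5)

  out <- withr::local_tempfile(fileext = ".csv")
  write_recovery_table(ds, out)
  ds2 <- read_recovery_table(out, "spring")
  expect_equal(ds2$records, ds$records)

  # invalid rows are named
  bad <- recs
  bad$day_of_year[2] <- 0L
  readr::write_csv(bad, path)
  expect_error(read_recovery_table(path, "spring"), "day_of_year.*2")

  readr::write_csv(recs[, -1], path)
  expect_error(read_recovery_table(path, "spring"), "species_id")

  bad <- recs
  bad$distance_class[1] <- "medium"
  readr::write_csv(bad, path)
  expect_error(read_recovery_table(path, "spring"), "distance_class")
})

test_that("first-year exclusion removes span-1 birds and shifts the rest", {
  ds <- recovery_data(make_records(c(1, 2, 3, 5)), season = "spring")
  out <- exclude_first_year(ds)
  expect_equal(sort(out$records$years_to_recovery), c(1, 2, 4))
  expect_equal(out$k, 4)
  expect_true(out$first_year_excluded)

  all_first <- exclude_first_year(
    recovery_data(make_records(c(1, 1, 1)), season = "spring")
  )
  expect_equal(nrow(all_first$records), 0)

  none_first <- exclude_first_year(
    recovery_data(make_records(c(2, 3, 4)), season = "spring")
  )
  expect_equal(nrow(none_first$records), 3)
  expect_equal(none_first$records$years_to_recovery, c(1, 2, 3))
})

test_that("migration window bounds are inclusive and errors name species", {
  recs <- make_records(c(2, 2, 2, 2), day_of_year = c(90L, 91L, 151L, 152L))
  meta <- tibble::tibble(
    species_id = "sp01", name = "sp01", distance_class = "short",
    window_spring_start = 91L, window_spring_end = 151L,
    window_autumn_start = NA_integer_, window_autumn_end = NA_integer_
  )
  ds <- recovery_data(recs, species = meta, season = "spring")
  out <- apply_migration_window(ds)
  expect_equal(sort(out$records$day_of_year), c(91, 151))

  inside <- recovery_data(
    make_records(c(2, 3), day_of_year = c(100L, 120L)),
    species = meta, season = "spring"
  )
  expect_equal(apply_migration_window(inside)$records, inside$records)

  none <- recovery_data(
    make_records(c(2, 3), day_of_year = c(10L, 20L)),
    species = meta, season = "spring"
  )
  expect_equal(nrow(apply_migration_window(none)$records), 0)

  ds_autumn <- recovery_data(
    make_records(2, season = "autumn"),
    species = meta, season = "autumn"
  )
  expect_error(apply_migration_window(ds_autumn), "sp01")
})

test_that("species inclusion keeps species with enough recoveries", {
  recs <- dplyr::bind_rows(
    make_records(rep(2, 7), species_id = "A"),
    make_records(rep(2, 5), species_id = "B")
  )
  ds <- exclude_first_year(recovery_data(recs, season = "spring"))
  # A has 7, B has 5 post-exclusion records (none removed)
  out <- suppressMessages(apply_species_inclusion(ds, min_recoveries = 6))
  expect_equal(unique(out$records$species_id), "A")
  expect_false("B" %in% out$species$species_id)

  ident <- apply_species_inclusion(ds, min_recoveries = 1)
  expect_equal(ident$records, ds$records)

  # exclusion must come first: counting is on post-exclusion records
  expect_error(
    apply_species_inclusion(recovery_data(recs, season = "spring")),
    "exclude_first_year"
  )
})

test_that("standardization gives mean 0 / sd 1 per species and inverts", {
  recs <- dplyr::bind_rows(
    make_records(rep(2, 3), species_id = "A", day_of_year = c(130L, 140L, 150L)),
    make_records(rep(2, 4), species_id = "B", day_of_year = c(95L, 100L, 105L, 120L))
  )
  ds <- standardize_days(recovery_data(recs, season = "spring"))
  by_sp <- split(ds$records$std_day, ds$records$species_id)
  for (v in by_sp) {
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  expect_equal(
    ds$records$std_day[ds$records$species_id == "A"],
    c(-1, 0, 1)
  )
  # invertible via the stored constants
  m <- match(ds$records$species_id, ds$species$species_id)
  back <- ds$species$day_mean[m] + ds$records$std_day * ds$species$day_sd[m]
  expect_equal(back, as.numeric(ds$records$day_of_year), tolerance = 1e-9)
  # re-running reproduces the same std_day (recomputed from day_of_year)
  expect_equal(standardize_days(ds)$records$std_day, ds$records$std_day)
  # population-SD convention
  pop <- standardize_days(recovery_data(recs, season = "spring"),
    sd_type = "population"
  )
  a <- pop$records$std_day[pop$records$species_id == "A"]
  expect_equal(a, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)

  const <- recovery_data(
    make_records(c(2, 2), species_id = "C", day_of_year = 120L),
    season = "spring"
  )
  expect_error(standardize_days(const), "C")
})

test_that("ringing-year/span correlation matches hand computation", {
  # hand-computed: x = 1:4, y = c(2, 1, 4, 3) -> r = 3/5
  ds <- recovery_data(
    make_records(c(2, 1, 4, 3), ringing_year = c(1961L, 1962L, 1963L, 1964L)),
    season = "spring"
  )
  out <- ringing_year_span_correlation(ds)
  expect_equal(out$r, 0.6, tolerance = 1e-12)
  expect_equal(out$se, sqrt((1 - 0.36) / 2), tolerance = 1e-12)

  col <- recovery_data(
    make_records(c(2, 3, 4), ringing_year = c(1962L, 1963L, 1964L)),
    season = "spring"
  )
  expect_equal(ringing_year_span_correlation(col)$r, 1, tolerance = 1e-12)

  set.seed(99)
  big <- recovery_data(
    make_records(
      sample(1:10, 10000, replace = TRUE),
      ringing_year = sample(1950:2000, 10000, replace = TRUE)
    ),
    season = "spring"
  )
  expect_lt(abs(ringing_year_span_correlation(big)$r), 0.05)

  const <- recovery_data(make_records(c(2, 3, 4)), season = "spring")
  expect_error(ringing_year_span_correlation(const), "constant")
})

test_that("packaged recovery-count fixture matches the published accounting", {
  counts <- published_recovery_counts()
  spring <- counts[counts$season == "spring", ]
  totals <- as.numeric(tapply(spring$count, spring$species_id, sum))
  expect_equal(sort(totals), sort(c(22, 11, 16, 38, 52, 74, 28, 83)))
  expect_equal(sum(spring$count), 324)
  # autumn cells as printed sum to 298 (printed total reads 303)
  expect_equal(sum(counts$count[counts$season == "autumn"]), 298)

  ds <- published_counts_dataset("spring")
  expect_equal(nrow(ds$records), 324)
  prep <- apply_species_inclusion(exclude_first_year(ds))
  expect_equal(length(unique(prep$records$species_id)), 8)
  expect_equal(prep$k, 8)
})
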