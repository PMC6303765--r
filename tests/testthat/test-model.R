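test_that("recovery cell probabilities match hand-evaluated cases", {
  expect_equal(recovery_cell_probabilities(0.5, 1), 1)
  expect_equal(recovery_cell_probabilities(0.5, 2), c(2 / 3, 1 / 3),
    tolerance = 1e-15
  )
  # s = 0.9, k = 3: raw masses 0.1, 0.09, 0.081 over total 0.271
  expect_equal(
    recovery_cell_probabilities(0.9, 3),
    c(0.1, 0.09, 0.081) / 0.271,
    tolerance = 1e-12
  )
  expect_error(recovery_cell_probabilities(0, 3), "strictly inside")
  expect_error(recovery_cell_probabilities(1, 3), "strictly inside")
  expect_error(recovery_cell_probabilities(0.5, 0), "k")
})

test_that("cell probabilities normalize, decay geometrically, reach the geometric limit", {
  set.seed(11)
  for (i in 1:1000) {
    s <- runif(1, 0.01, 0.99)
    k <- sample(1:50, 1)
    p <- recovery_cell_probabilities(s, k)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p > 0))
    if (k > 1) {
      expect_equal(p[-1] / p[-k], rep(s, k - 1), tolerance = 1e-12)
      expect_true(all(diff(p) < 0))
    }
  }
  # k -> Inf: conditioning vanishes, cells approach the geometric pmf
  p <- recovery_cell_probabilities(0.5, 500)
  j <- 1:500
  expect_equal(p, 0.5^(j - 1) * 0.5, tolerance = 1e-12)
})

test_that("annual survival evaluates the logit-linear predictor", {
  frame <- tibble::tibble(
    species_id = "spA", std_day = 1, distance_class = "long"
  )
  expect_equal(annual_survival(frame, model_params()), 0.5)
  expect_equal(
    annual_survival(frame, model_params(c(b0 = qlogis(0.4)))),
    0.4,
    tolerance = 1e-12
  )
  # date effect cancelled by the interaction for long-distance birds at d = 1
  expect_equal(
    annual_survival(frame, model_params(c(b_day = 0.3, b_day_dist = -0.3))),
    0.5,
    tolerance = 1e-12
  )
  # unknown species rejected when params carry deviations
  p <- model_params(
    species = tibble::tibble(species_id = "spB", a0 = 0.1, a1 = 0, a2 = 0)
  )
  expect_error(annual_survival(frame, p), "spA")
})

test_that("log-likelihood composes cell probabilities over records", {
  one <- recovery_data(make_records(1), season = "spring")
  one$records$std_day <- 0
  expect_equal(log_likelihood(one, model_params()), 0)

  ds <- small_prepared()
  params <- model_params(c(b0 = 0.2, b_day = -0.3, b_day2 = -0.1, b_dist = 0.1))
  ll <- log_likelihood(ds, params)
  expect_true(is.finite(ll))

  # doubling the records doubles the log-likelihood
  ds2 <- ds
  ds2$records <- dplyr::bind_rows(ds$records, ds$records)
  expect_equal(log_likelihood(ds2, params), 2 * ll, tolerance = 1e-9)

  # record order is irrelevant
  ds3 <- ds
  set.seed(1)
  ds3$records <- ds3$records[sample(nrow(ds3$records)), ]
  expect_equal(log_likelihood(ds3, params), ll, tolerance = 1e-9)

  # j > k rejected
  ds4 <- ds
  ds4$k <- ds4$k - 1L
  expect_error(log_likelihood(ds4, params), "k")
})

test_that("log-likelihood equals a record-by-record brute-force oracle", {
  ds <- small_prepared(n_per = 10, seed = 21)
  params <- model_params(
    c(
      b0 = -0.2, b_day = 0.15, b_day2 = -0.2, b_dist = 0.3,
      b_day_dist = -0.1, b_day2_dist = 0.05, b_year = 0.1, b_year2 = -0.04
    ),
    species = tibble::tibble(
      species_id = c("spA", "spB"), a0 = c(0.1, -0.1),
      a1 = c(0.05, 0), a2 = c(0, -0.05)
    )
  )
  yrs <- ds$records$ringing_year
  ctr <- (min(yrs) + max(yrs)) / 2
  scl <- (max(yrs) - min(yrs)) / 2
  brute <- 0
  for (i in seq_len(nrow(ds$records))) {
    rec <- ds$records[i, ]
    b <- params$fixed
    dev <- params$species[params$species$species_id == rec$species_id, ]
    d <- rec$std_day
    long <- as.numeric(rec$distance_class == "long")
    y <- (rec$ringing_year - ctr) / scl
    eta <- (b[["b0"]] + dev$a0) + (b[["b_day"]] + dev$a1) * d +
      (b[["b_day2"]] + dev$a2) * d^2 +
      long * (b[["b_dist"]] + b[["b_day_dist"]] * d + b[["b_day2_dist"]] * d^2) +
      b[["b_year"]] * y + b[["b_year2"]] * y^2
    s <- 1 / (1 + exp(-eta))
    p <- s^(0:(ds$k - 1)) * (1 - s)
    p <- p / sum(p)
    brute <- brute + log(p[rec$years_to_recovery])
  }
  expect_equal(log_likelihood(ds, params), brute, tolerance = 1e-9)
})

test_that("constant-survival datasets match summed cell probabilities on an s grid", {
  spans <- c(1, 1, 2, 3, 3, 4)
  ds <- recovery_data(make_records(spans + 1), season = "spring")
  ds <- exclude_first_year(ds)
  ds$records$std_day <- 0
  for (s in c(0.2, 0.5, 0.8)) {
    params <- model_params(c(b0 = qlogis(s)))
    oracle <- sum(log(recovery_cell_probabilities(s, ds$k)[spans]))
    expect_equal(log_likelihood(ds, params), oracle, tolerance = 1e-10)
  }
})

test_that("recovery-year draws follow the conditional multinomial", {
  expect_equal(simulate_recovery_year(rep(0.5, 10), 1), rep(1L, 10))
  set.seed(31)
  draws <- simulate_recovery_year(rep(0.5, 100000), 2)
  freq1 <- mean(draws == 1)
  se <- sqrt(2 / 3 * 1 / 3 / 100000)
  expect_lt(abs(freq1 - 2 / 3), 3 * se)

  set.seed(7)
  a <- simulate_recovery_year(runif(50, 0.2, 0.8), 6)
  set.seed(7)
  b <- simulate_recovery_year(runif(50, 0.2, 0.8), 6)
  expect_identical(a, b)

  # chi-square goodness of fit at fixed covariates, horizon 5
  set.seed(41)
  s <- 0.62
  k <- 5
  draws <- simulate_recovery_year(rep(s, 100000), k)
  obs <- tabulate(draws, k)
  expected <- recovery_cell_probabilities(s, k) * 100000
  chisq <- sum((obs - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.99, df = k - 1))
})
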