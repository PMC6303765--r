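fake_draws <- function(chains) {
  dplyr::bind_rows(lapply(seq_along(chains), function(i) {
    tibble::tibble(
      .chain = i, .iteration = seq_along(chains[[i]]), theta = chains[[i]]
    )
  }))
}

test_that("gelman_rubin matches its defining formula and flags divergence", {
  x <- rnorm(200)
  # identical chains: B = 0, statistic at its lower bound sqrt((n-1)/n)
  rh <- gelman_rubin(fake_draws(list(x, x)))
  expect_equal(rh$rhat, sqrt(199 / 200), tolerance = 1e-9)
  expect_false(rh$flagged)

  set.seed(8)
  same <- fake_draws(list(rnorm(5000), rnorm(5000)))
  expect_lt(gelman_rubin(same)$rhat, 1.01)

  apart <- fake_draws(list(rnorm(500, -10), rnorm(500, 10)))
  expect_gt(gelman_rubin(apart)$rhat, 5)

  # invariant to chain relabeling
  swapped <- apart
  swapped$.chain <- 3 - swapped$.chain
  expect_equal(gelman_rubin(swapped)$rhat, gelman_rubin(apart)$rhat)

  expect_error(gelman_rubin(fake_draws(list(rnorm(100)))), "2 chains")
})

test_that("gelman_rubin agrees with coda on well-mixed chains", {
  set.seed(12)
  ch <- list(rnorm(2000), rnorm(2000))
  ours <- gelman_rubin(fake_draws(ch))$rhat
  ml <- coda::mcmc.list(lapply(ch, coda::mcmc))
  theirs <- unname(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1])
  expect_equal(ours, theirs, tolerance = 0.02)
})

test_that("posterior summaries use pooled draws and interpolated quantiles", {
  const <- fake_draws(list(rep(2.5, 50), rep(2.5, 50)))
  s <- summarize_posterior(const)
  expect_equal(s$mean, 2.5)
  expect_equal(s$median, 2.5)
  expect_equal(s$q2.5, 2.5)
  expect_equal(s$q97.5, 2.5)

  set.seed(13)
  z <- rnorm(100000)
  s <- summarize_posterior(fake_draws(list(z[1:50000], z[50001:100000])))
  expect_equal(s$q2.5, qnorm(0.025), tolerance = 0.03)
  expect_equal(s$q97.5, qnorm(0.975), tolerance = 0.03)
  expect_equal(s$mean, s$median, tolerance = 0.02)
})

test_that("log-posterior gradient matches numerical differentiation", {
  ds <- small_prepared(n_per = 15, seed = 3)
  mf <- migsurv:::build_model_frame(ds)
  priors <- prior_spec()
  set.seed(14)
  theta <- rnorm(mf$n_beta + 3 * mf$nsp + 3, 0, 0.3)
  ana <- migsurv:::mf_log_post_grad(theta, mf, priors)
  eps <- 1e-6
  num <- vapply(seq_along(theta), function(i) {
    up <- theta
    dn <- theta
    up[i] <- up[i] + eps
    dn[i] <- dn[i] - eps
    (migsurv:::mf_log_post(up, mf, priors) -
      migsurv:::mf_log_post(dn, mf, priors)) / (2 * eps)
  }, 1)
  expect_equal(ana, num, tolerance = 1e-5)
})

test_that("constant-survival MLE matches known solutions and flags boundaries", {
  expect_equal(fit_constant_survival_mle(c(2, 1))$s_hat, 0.5, tolerance = 1e-6)
  # equal counts in two cells push the ratio p2/p1 = s to its upper bound
  even <- fit_constant_survival_mle(c(1, 1))
  expect_true(even$boundary)
  expect_gt(even$s_hat, 0.999)
  # all mass in the first cell: s -> 0
  low <- fit_constant_survival_mle(c(5, 0, 0))
  expect_true(low$boundary)
  expect_lt(low$s_hat, 0.001)
  expect_error(fit_constant_survival_mle(c(3)), "k >= 2")
})

test_that("chain bookkeeping and determinism hold", {
  ds <- small_prepared(n_per = 25, seed = 6)
  st <- mcmc_settings(chains = 2, iterations = 400, burn_in = 100, thin = 3, seed = 9)
  fit1 <- suppressWarnings(fit_mcmc(ds, settings = st))
  expect_equal(sum(fit1$draws$.chain == 1), floor((400 - 100) / 3))
  expect_equal(sum(fit1$draws$.chain == 2), floor((400 - 100) / 3))
  fit2 <- suppressWarnings(fit_mcmc(ds, settings = st))
  expect_identical(fit1$draws, fit2$draws)
  fit3 <- suppressWarnings(
    fit_mcmc(ds, settings = mcmc_settings(
      chains = 2, iterations = 400, burn_in = 100, thin = 3, seed = 10
    ))
  )
  expect_false(identical(fit1$draws, fit3$draws))
  # exported layout: fixed effects, sigmas, per-species deviations
  expect_true(all(
    c("b0", "b_day_dist", "sigma0", "a2[spB]") %in% names(fit1$draws)
  ))
})

test_that("with flat data the posterior reproduces the prior", {
  # all birds recovered in the only possible year: the likelihood is constant
  set.seed(44)
  recs <- make_records(rep(2, 40),
    day_of_year = sample(100:140, 40, replace = TRUE)
  )
  ds <- standardize_days(exclude_first_year(recovery_data(recs, season = "spring")))
  fit <- suppressWarnings(suppressMessages(fit_mcmc(
    ds,
    settings = mcmc_settings(iterations = 6000, burn_in = 1000, thin = 1, seed = 3)
  )))
  b0 <- fit$draws$b0
  expect_equal(mean(b0), 0, tolerance = 0.4)
  expect_equal(sd(b0), 5, tolerance = 0.5)
})

test_that("posterior concentrates on the MLE with informative single-species data", {
  set.seed(17)
  n <- 1500
  day <- sample(100:140, n, replace = TRUE)
  d_std <- (day - mean(day)) / sd(day)
  s_true <- plogis(0.3 - 0.4 * d_std)
  recs <- make_records(simulate_recovery_year(s_true, 6L) + 1L,
    day_of_year = day, ringing_year = 1970L
  )
  ds <- standardize_days(exclude_first_year(recovery_data(recs, season = "spring")))
  fit <- suppressWarnings(suppressMessages(fit_mcmc(
    ds,
    settings = mcmc_settings(iterations = 4000, burn_in = 1000, thin = 3, seed = 23)
  )))
  # direct numerical ML on the same likelihood (flat priors)
  nll <- function(par) {
    -log_likelihood(ds, model_params(c(
      b0 = par[1], b_day = par[2], b_day2 = par[3]
    )))
  }
  mle <- optim(c(0, 0, 0), nll)$par
  s <- summarize_posterior(fit)
  for (i in 1:2) {
    pn <- c("b0", "b_day")[i]
    post <- fit$draws[[pn]]
    expect_lt(abs(mean(post) - mle[i]), 2 * sd(post))
  }
})

test_that("posterior matches an independent Gibbs implementation on a small case", {
  set.seed(19)
  n <- 400
  day <- sample(95:145, n, replace = TRUE)
  d_std <- (day - mean(day)) / sd(day)
  s_true <- plogis(0.2 - 0.5 * d_std - 0.2 * d_std^2)
  recs <- make_records(simulate_recovery_year(s_true, 5L) + 1L,
    day_of_year = day, ringing_year = 1970L
  )
  ds <- standardize_days(exclude_first_year(recovery_data(recs, season = "spring")))
  fit <- suppressWarnings(suppressMessages(fit_mcmc(
    ds,
    settings = mcmc_settings(iterations = 8000, burn_in = 1000, thin = 2, seed = 29)
  )))
  model_str <- "
  model {
    for (i in 1:n) {
      logit(S[i]) <- b0 + b_day * d[i] + b_day2 * d2[i]
      ll[i] <- (j[i] - 1) * log(S[i]) + log(1 - S[i]) - log(1 - pow(S[i], k))
      zeros[i] ~ dpois(-ll[i])
    }
    b0 ~ dnorm(0, 0.04)
    b_day ~ dnorm(0, 0.04)
    b_day2 ~ dnorm(0, 0.04)
  }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(
      n = nrow(ds$records), k = ds$k, j = ds$records$years_to_recovery,
      d = ds$records$std_day, d2 = ds$records$std_day^2,
      zeros = rep(0, nrow(ds$records))
    ),
    inits = list(
      .RNG.name = "base::Mersenne-Twister", .RNG.seed = 99
    ),
    n.chains = 1, n.adapt = 500, quiet = TRUE
  )
  sm <- rjags::coda.samples(jm, c("b0", "b_day", "b_day2"), n.iter = 4000)
  jags_mean <- colMeans(as.matrix(sm))
  for (pn in c("b0", "b_day", "b_day2")) {
    post <- fit$draws[[pn]]
    expect_lt(abs(mean(post) - jags_mean[[pn]]), 0.25 * max(sd(post), 0.1))
  }
})

test_that("prior sensitivity is negligible with informative data, visible with tight priors", {
  ds <- cached("sens_ds", {
    bundle <- generate_dataset(truth_config(seed = 303))
    prepare_recovery_data(bundle$dataset)
  })
  st <- mcmc_settings(iterations = 3000, burn_in = 500, thin = 5, seed = 31)
  sens <- suppressWarnings(prior_sensitivity(
    ds, list(prior_spec(fixed_sd = 5), prior_spec(fixed_sd = 10)), st
  ))
  day_terms <- c("b_day", "b_day2", "b_day_dist", "b_day2_dist")
  deltas <- sens$delta$max_abs_diff_mean[sens$delta$parameter %in% day_terms]
  expect_true(all(deltas < 0.1))

  # identical priors, same seed: identical summaries
  sens_id <- suppressWarnings(prior_sensitivity(
    small_prepared(), list(prior_spec(), prior_spec()),
    mcmc_settings(iterations = 400, burn_in = 100, seed = 5)
  ))
  wide <- sens_id$summaries
  expect_equal(
    wide$mean[wide$prior == 1], wide$mean[wide$prior == 2],
    tolerance = 1e-12
  )

  # a very tight prior shrinks the date coefficients toward zero
  sens_shrink <- suppressWarnings(prior_sensitivity(
    ds, list(prior_spec(fixed_sd = 0.01), prior_spec(fixed_sd = 5)), st
  ))
  s1 <- sens_shrink$summaries
  tight <- s1$mean[s1$prior == 1 & s1$parameter == "b_day_dist"]
  wide2 <- s1$mean[s1$prior == 2 & s1$parameter == "b_day_dist"]
  expect_lt(abs(tight), abs(wide2) / 4)
})
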