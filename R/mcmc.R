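#' Prior specification
#'
#' Weakly informative priors: independent normals on every fixed-effect
#' coefficient and a folded-t distribution (the absolute value of a scaled
#' t variate) on each hierarchical standard deviation. Defaults are
#' N(0, 5) for the coefficients and folded-t with 2 degrees of freedom and
#' scale 1 for the SDs.
#'
#' @param fixed_mean Prior mean for fixed effects.
#' @param fixed_sd Prior SD for fixed effects (> 0).
#' @param sigma_df Degrees of freedom of the folded-t prior on SDs.
#' @param sigma_scale Scale of the folded-t prior (> 0).
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(fixed_mean = 0, fixed_sd = 5, sigma_df = 2,
                       sigma_scale = 1) {
  stopifnot(is.finite(fixed_mean), fixed_sd > 0, sigma_df >= 1, sigma_scale > 0)
  structure(
    list(
      fixed_mean = fixed_mean, fixed_sd = fixed_sd,
      sigma_df = sigma_df, sigma_scale = sigma_scale
    ),
    class = "prior_spec"
  )
}

#' MCMC settings
#'
#' Chain layout defaults: two chains of length 10,000 with the first 1,000
#' iterations discarded as burn-in (during which proposal scales adapt) and
#' thinning of 5, giving 1,800 retained draws per chain.
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iterations Total iterations per chain.
#' @param burn_in Iterations discarded at the start of each chain.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @return An `mcmc_settings` object.
#' @export
mcmc_settings <- function(chains = 2L, iterations = 10000L, burn_in = 1000L,
                          thin = 5L, seed = 1L) {
  stopifnot(chains >= 1, burn_in >= 0, burn_in < iterations, thin >= 1)
  structure(
    list(
      chains = as.integer(chains), iterations = as.integer(iterations),
      burn_in = as.integer(burn_in), thin = as.integer(thin),
      seed = as.integer(seed)
    ),
    class = "mcmc_settings"
  )
}

# ---- internal model frame ------------------------------------------------

# Assembles design columns, active-term bookkeeping and parameter indexing
# for a prepared dataset.
build_model_frame <- function(ds, include_distance_main = TRUE) {
  r <- ds$records
  if (nrow(r) == 0) abort("cannot fit an empty dataset")
  if (!ds$first_year_excluded) {
    warn("fitting a dataset without first-year exclusion applied")
  }
  if (anyNA(r$std_day)) abort("std_day missing; run standardize_days() first")
  ys <- scale_years(r$ringing_year)
  species_ids <- sort(unique(r$species_id))
  nsp <- length(species_ids)
  sp <- match(r$species_id, species_ids)
  d <- r$std_day
  long <- as.numeric(r$distance_class == "long")
  y <- ys$y
  X_full <- cbind(
    b0 = 1, b_day = d, b_day2 = d^2,
    b_dist = long, b_day_dist = long * d, b_day2_dist = long * d^2,
    b_year = y, b_year2 = y^2
  )
  active <- rep(TRUE, 8)
  names(active) <- fixed_effect_names()
  if (length(unique(long)) == 1) {
    active[c("b_dist", "b_day_dist", "b_day2_dist")] <- FALSE
    inform("single distance class in data: distance terms dropped from the fit")
  } else if (!include_distance_main) {
    active["b_dist"] <- FALSE
  }
  if (length(unique(r$ringing_year)) == 1) {
    active[c("b_year", "b_year2")] <- FALSE
    inform("single ringing year in data: year terms dropped from the fit")
  }
  hierarchical <- nsp >= 2
  if (!hierarchical) {
    warn("fewer than 2 species: fitting fixed effects only (no random effects)")
  }
  list(
    X = X_full[, active, drop = FALSE], active = active,
    sp = sp, species_ids = species_ids, nsp = nsp,
    d = d, d2 = d^2, j = r$years_to_recovery, k = ds$k,
    year_center = ys$center, year_scale = ys$scale,
    hierarchical = hierarchical,
    n_beta = sum(active)
  )
}

# log posterior pieces; theta = c(beta_active, a0, a1, a2, log_sigma)
mf_unpack <- function(theta, mf) {
  nb <- mf$n_beta
  beta <- theta[seq_len(nb)]
  if (mf$hierarchical) {
    nsp <- mf$nsp
    a <- matrix(theta[nb + seq_len(3 * nsp)], nrow = nsp, ncol = 3)
    ls <- theta[nb + 3 * nsp + 1:3]
  } else {
    a <- NULL
    ls <- NULL
  }
  list(beta = beta, a = a, ls = ls)
}

mf_eta <- function(mf, beta, a) {
  eta <- drop(mf$X %*% beta)
  if (!is.null(a)) {
    eta <- eta + a[mf$sp, 1] + a[mf$sp, 2] * mf$d + a[mf$sp, 3] * mf$d2
  }
  eta
}

folded_t_log <- function(sigma, df, scale) {
  log(2) + dt(sigma / scale, df = df, log = TRUE) - log(scale)
}

mf_log_post <- function(theta, mf, priors) {
  p <- mf_unpack(theta, mf)
  eta <- mf_eta(mf, p$beta, p$a)
  lp <- sum(loglik_terms(eta, mf$j, mf$k)) +
    sum(dnorm(p$beta, priors$fixed_mean, priors$fixed_sd, log = TRUE))
  if (mf$hierarchical) {
    sig <- exp(p$ls)
    for (e in 1:3) {
      lp <- lp + sum(dnorm(p$a[, e], 0, sig[e], log = TRUE)) +
        folded_t_log(sig[e], priors$sigma_df, priors$sigma_scale) + p$ls[e]
    }
  }
  lp
}

# derivative of the per-record log cell probability wrt eta
dloglik_deta <- function(eta, j, k) {
  s <- plogis(eta)
  sk <- exp(k * plogis(eta, log.p = TRUE))
  (j - 1) * (1 - s) - s + k * sk * (1 - s) / (1 - sk)
}

mf_log_post_grad <- function(theta, mf, priors) {
  p <- mf_unpack(theta, mf)
  eta <- mf_eta(mf, p$beta, p$a)
  g <- dloglik_deta(eta, mf$j, mf$k)
  grad_beta <- unname(drop(crossprod(mf$X, g))) -
    (p$beta - priors$fixed_mean) / priors$fixed_sd^2
  if (!mf$hierarchical) {
    return(grad_beta)
  }
  sig <- exp(p$ls)
  ga0 <- rowsum_by(g, mf$sp, mf$nsp) - p$a[, 1] / sig[1]^2
  ga1 <- rowsum_by(g * mf$d, mf$sp, mf$nsp) - p$a[, 2] / sig[2]^2
  ga2 <- rowsum_by(g * mf$d2, mf$sp, mf$nsp) - p$a[, 3] / sig[3]^2
  gls <- numeric(3)
  for (e in 1:3) {
    # deviations term + folded-t prior + Jacobian, all wrt log sigma
    s_e <- sig[e]
    dev <- p$a[, e]
    d_dev <- sum(dev^2 / s_e^2) - mf$nsp
    u <- s_e / priors$sigma_scale
    d_prior <- -(priors$sigma_df + 1) * u^2 / (priors$sigma_df + u^2)
    gls[e] <- d_dev + d_prior + 1
  }
  c(grad_beta, ga0, ga1, ga2, gls)
}

rowsum_by <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# ---- posterior sampler ---------------------------------------------------

#' Fit the hierarchical dead-recovery survival model by MCMC
#'
#' Samples the posterior of the logit-linear survival model (see
#' [model_params()]) under the conditional multinomial ring-recovery
#' likelihood. The sampler is a blocked random-walk Metropolis scheme whose
#' proposal covariances come from a Laplace approximation at the posterior
#' mode (fixed effects as one block, each species' three deviations as a
#' block, log hierarchical SDs by univariate slice sampling); block scales
#' adapt toward a target acceptance rate during burn-in only.
#'
#' The ringing-year covariate is centred at the midpoint of the observed
#' ringing years and scaled by half their range, so it lies in [-1, 1]; the
#' constants are stored in the fit for prediction. With a single distance
#' class or a single ringing year in the data the corresponding terms are
#' dropped (reported as zero draws). With fewer than two species the model
#' falls back to fixed effects only, with a warning.
#'
#' @param ds A prepared [recovery_data] (see [prepare_recovery_data()]).
#' @param priors A [prior_spec].
#' @param settings An [mcmc_settings].
#' @param include_distance_main Include the distance-class main effect
#'   `b_dist` alongside the date-by-distance interactions (default TRUE).
#' @param sex Optional sex filter (`"male"` or `"female"`): fit only the
#'   records of that sex, as a separate model.
#' @return A `migsurv_fit` object with elements `draws` (tibble: `.chain`,
#'   `.iteration`, one column per parameter), `settings`, `priors`,
#'   `species` (metadata with standardization constants), `year_center`,
#'   `year_scale`, `k`, `season`, `std_day_range` (per distance class),
#'   `map` (posterior mode), `data_fingerprint` and `acceptance`.
#' @seealso [gelman_rubin()], [summarize_posterior()], [curve_for_group()]
#' @export
fit_mcmc <- function(ds, priors = prior_spec(), settings = mcmc_settings(),
                     include_distance_main = TRUE, sex = NULL) {
  stopifnot(
    inherits(ds, "recovery_data"), inherits(priors, "prior_spec"),
    inherits(settings, "mcmc_settings")
  )
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("male", "female"))
    ds$records <- ds$records[ds$records$sex == sex, , drop = FALSE]
    ds <- refresh_k(ds)
  }
  if (nrow(ds$records) == 0) abort("no records to fit")
  mf <- build_model_frame(ds, include_distance_main = include_distance_main)
  n_par <- mf$n_beta + if (mf$hierarchical) 3 * mf$nsp + 3 else 0
  lp_fun <- function(th) mf_log_post(th, mf, priors)
  gr_fun <- function(th) mf_log_post_grad(th, mf, priors)

  # Laplace approximation at the posterior mode
  theta0 <- rep(0, n_par)
  if (mf$hierarchical) theta0[mf$n_beta + 3 * mf$nsp + 1:3] <- log(0.3)
  opt <- optim(theta0, function(th) -lp_fun(th), function(th) -gr_fun(th),
    method = "BFGS", control = list(maxit = 500)
  )
  map <- opt$par
  H <- optimHess(map, function(th) -lp_fun(th), function(th) -gr_fun(th))
  map_ls <- if (mf$hierarchical) map[mf$n_beta + 3 * mf$nsp + 1:3] else NULL
  prop <- proposal_blocks(H, mf, map_ls)

  keep <- floor((settings$iterations - settings$burn_in) / settings$thin)
  par_names <- posterior_par_names(mf)
  chains <- vector("list", settings$chains)
  acc <- matrix(0, settings$chains, 2,
    dimnames = list(NULL, c("beta", "species"))
  )
  for (ch in seq_len(settings$chains)) {
    seed_ch <- (settings$seed + ch * 104729L) %% .Machine$integer.max
    set.seed(seed_ch)
    run <- run_chain(map, mf, priors, settings, prop, keep)
    chains[[ch]] <- expand_draws(run$draws, mf, par_names)
    acc[ch, ] <- run$acceptance
  }
  draws <- dplyr::bind_rows(lapply(seq_along(chains), function(ch) {
    out <- tibble::as_tibble(chains[[ch]])
    dplyr::bind_cols(
      tibble::tibble(.chain = ch, .iteration = seq_len(nrow(out))), out
    )
  }))
  species_tbl <- ds$species[ds$species$species_id %in% mf$species_ids, ]
  rng <- ds$records |>
    dplyr::group_by(.data$distance_class) |>
    dplyr::summarise(
      lo = min(.data$std_day), hi = max(.data$std_day), .groups = "drop"
    )
  fit <- structure(
    list(
      draws = draws,
      settings = settings, priors = priors,
      species = species_tbl,
      species_ids = mf$species_ids,
      hierarchical = mf$hierarchical,
      active = mf$active,
      year_center = mf$year_center, year_scale = mf$year_scale,
      k = mf$k, season = ds$season,
      n_records = nrow(ds$records),
      std_day_range = rng,
      species_day_range = ds$records |>
        dplyr::group_by(.data$species_id) |>
        dplyr::summarise(
          lo = min(.data$std_day), hi = max(.data$std_day), .groups = "drop"
        ),
      map = setNames(expand_draws(matrix(map, 1), mf, par_names)[1, ], par_names),
      acceptance = acc,
      data_fingerprint = rlang::hash(ds$records)
    ),
    class = "migsurv_fit"
  )
  rh <- gelman_rubin(fit)
  bad <- rh$parameter[!is.na(rh$rhat) & rh$rhat > 1.1]
  if (length(bad) > 0) {
    warn(paste0(
      "possible non-convergence (r_hat > 1.1) for: ", paste(bad, collapse = ", ")
    ))
  }
  fit
}

posterior_par_names <- function(mf) {
  nm <- fixed_effect_names()
  if (mf$hierarchical) {
    nm <- c(
      nm, paste0("sigma", 0:2),
      paste0("a0[", mf$species_ids, "]"),
      paste0("a1[", mf$species_ids, "]"),
      paste0("a2[", mf$species_ids, "]")
    )
  }
  nm
}

# maps raw theta draws (active beta, a, log sigma) to the full named layout
expand_draws <- function(draws, mf, par_names) {
  n <- nrow(draws)
  out <- matrix(0, n, length(par_names), dimnames = list(NULL, par_names))
  out[, names(mf$active)[mf$active]] <- draws[, seq_len(mf$n_beta), drop = FALSE]
  if (mf$hierarchical) {
    nsp <- mf$nsp
    out[, paste0("a0[", mf$species_ids, "]")] <-
      draws[, mf$n_beta + seq_len(nsp), drop = FALSE]
    out[, paste0("a1[", mf$species_ids, "]")] <-
      draws[, mf$n_beta + nsp + seq_len(nsp), drop = FALSE]
    out[, paste0("a2[", mf$species_ids, "]")] <-
      draws[, mf$n_beta + 2 * nsp + seq_len(nsp), drop = FALSE]
    out[, paste0("sigma", 0:2)] <-
      exp(draws[, mf$n_beta + 3 * nsp + 1:3, drop = FALSE])
  }
  out
}

proposal_blocks <- function(H, mf, map_ls = NULL) {
  nb <- mf$n_beta
  safe_chol_inv <- function(Hblk) {
    Sig <- tryCatch(solve(Hblk), error = function(e) NULL)
    if (is.null(Sig) || any(!is.finite(Sig)) ||
      inherits(tryCatch(chol(Sig), error = function(e) e), "error")) {
      Sig <- diag(1 / pmax(diag(Hblk), 1e-8), nrow(Hblk))
    }
    chol(Sig)
  }
  beta_L <- safe_chol_inv(H[seq_len(nb), seq_len(nb), drop = FALSE]) *
    (2.38 / sqrt(nb))
  sp_prec_lik <- NULL
  if (mf$hierarchical) {
    # likelihood-only precision per species block: subtract the prior
    # precision at the MAP so the prior part can track the current sigma
    sig_map <- exp(map_ls)
    sp_prec_lik <- lapply(seq_len(mf$nsp), function(g) {
      idx <- nb + c(g, mf$nsp + g, 2 * mf$nsp + g)
      blk <- H[idx, idx, drop = FALSE] - diag(1 / sig_map^2, 3)
      diag(blk) <- pmax(diag(blk), 1e-8)
      blk
    })
  }
  list(beta_L = beta_L, sp_prec_lik = sp_prec_lik)
}

run_chain <- function(map, mf, priors, settings, prop, keep) {
  nb <- mf$n_beta
  nsp <- if (mf$hierarchical) mf$nsp else 0
  theta <- map + rnorm(length(map), 0, 0.05)
  p <- mf_unpack(theta, mf)
  eta <- mf_eta(mf, p$beta, p$a)
  ll_rec <- loglik_terms(eta, mf$j, mf$k)
  beta_steps <- 5L
  sp_steps <- 2L
  log_scale_beta <- 0
  log_scale_sp <- rep(0, max(nsp, 1))
  log_scale_tr <- rep(log(0.2), 3)
  log_scale_sc <- rep(log(0.3), 3)
  # which active-beta index each hierarchical effect translates against
  trans_beta_idx <- match(
    c("b0", "b_day", "b_day2"), names(mf$active)[mf$active]
  )
  # per-record multiplier of each effect's deviation in the predictor
  x_cols <- list(rep(1, length(mf$d)), mf$d, mf$d2)
  n_try_beta <- n_acc_beta <- 0
  n_try_sp <- n_acc_sp <- 0
  draws <- matrix(NA_real_, keep, length(map))
  kept <- 0L
  sp_rows <- if (nsp > 0) split(seq_along(mf$sp), mf$sp) else NULL
  beta_prior_log <- function(b) {
    sum(dnorm(b, priors$fixed_mean, priors$fixed_sd, log = TRUE))
  }
  for (t in seq_len(settings$iterations)) {
    adapting <- t <= settings$burn_in
    # fixed-effects block
    for (rep_i in seq_len(beta_steps)) {
      bprop <- p$beta + exp(log_scale_beta) *
        drop(rnorm(nb) %*% prop$beta_L)
      eta_prop <- mf_eta(mf, bprop, p$a)
      ll_prop <- loglik_terms(eta_prop, mf$j, mf$k)
      lr <- sum(ll_prop) - sum(ll_rec) +
        beta_prior_log(bprop) - beta_prior_log(p$beta)
      n_try_beta <- n_try_beta + 1
      if (is.finite(lr) && log(runif(1)) < lr) {
        p$beta <- bprop
        eta <- eta_prop
        ll_rec <- ll_prop
        n_acc_beta <- n_acc_beta + 1
        if (adapting) log_scale_beta <- log_scale_beta + 2 / sqrt(t + 10)
      } else if (adapting) {
        log_scale_beta <- log_scale_beta - 0.7 / sqrt(t + 10)
      }
    }
    if (mf$hierarchical) {
      sig <- exp(p$ls)
      for (rep_i in seq_len(sp_steps)) {
        for (g in seq_len(nsp)) {
          rows <- sp_rows[[as.character(g)]]
          cur <- p$a[g, ]
          # proposal covariance: inverse of likelihood precision plus the
          # prior precision at the *current* sigma, so steps shrink with it
          prec <- prop$sp_prec_lik[[g]] + diag(1 / sig^2, 3)
          Ru <- tryCatch(chol(prec), error = function(e) NULL)
          step <- if (is.null(Ru)) {
            rnorm(3) / sqrt(diag(prec))
          } else {
            backsolve(Ru, rnorm(3))
          }
          aprop <- cur + exp(log_scale_sp[g]) * (2.38 / sqrt(3)) * step
          eta_g <- drop(mf$X[rows, , drop = FALSE] %*% p$beta) +
            aprop[1] + aprop[2] * mf$d[rows] + aprop[3] * mf$d2[rows]
          ll_g <- loglik_terms(eta_g, mf$j[rows], mf$k)
          lr <- sum(ll_g) - sum(ll_rec[rows]) +
            sum(dnorm(aprop, 0, sig, log = TRUE)) -
            sum(dnorm(cur, 0, sig, log = TRUE))
          n_try_sp <- n_try_sp + 1
          if (is.finite(lr) && log(runif(1)) < lr) {
            p$a[g, ] <- aprop
            eta[rows] <- eta_g
            ll_rec[rows] <- ll_g
            n_acc_sp <- n_acc_sp + 1
            if (adapting) log_scale_sp[g] <- log_scale_sp[g] + 2 / sqrt(t + 10)
          } else if (adapting) {
            log_scale_sp[g] <- log_scale_sp[g] - 0.7 / sqrt(t + 10)
          }
        }
      }
      # translation moves: shift a fixed date effect and its species
      # deviations in opposite directions; eta (hence the likelihood) is
      # unchanged, only the priors enter the ratio. Decouples the fixed
      # effects from the random-effect means.
      for (e in 1:3) {
        be <- trans_beta_idx[e]
        if (is.na(be)) next
        delta <- rnorm(1, 0, exp(log_scale_tr[e]))
        lr <- dnorm(p$beta[be] + delta, priors$fixed_mean, priors$fixed_sd,
          log = TRUE
        ) -
          dnorm(p$beta[be], priors$fixed_mean, priors$fixed_sd, log = TRUE) +
          sum(dnorm(p$a[, e] - delta, 0, sig[e], log = TRUE)) -
          sum(dnorm(p$a[, e], 0, sig[e], log = TRUE))
        if (is.finite(lr) && log(runif(1)) < lr) {
          p$beta[be] <- p$beta[be] + delta
          p$a[, e] <- p$a[, e] - delta
          if (adapting) log_scale_tr[e] <- log_scale_tr[e] + 1.2 / sqrt(t + 10)
        } else if (adapting) {
          log_scale_tr[e] <- log_scale_tr[e] - 0.8 / sqrt(t + 10)
        }
      }
      # hierarchical SDs: univariate slice updates on the log scale
      for (e in 1:3) {
        dev <- p$a[, e]
        target <- function(ls_e) {
          s_e <- exp(ls_e)
          sum(dnorm(dev, 0, s_e, log = TRUE)) +
            folded_t_log(s_e, priors$sigma_df, priors$sigma_scale) + ls_e
        }
        p$ls[e] <- slice_1d(p$ls[e], target)
      }
      # scale moves: rescale one effect's deviations and its sigma jointly,
      # traversing the funnel between them. Acceptance ratio includes the
      # likelihood change, the folded-t prior ratio and the log-scale
      # Jacobian (the deviation-prior and a-space Jacobian terms cancel).
      for (e in 1:3) {
        delta <- rnorm(1, 0, exp(log_scale_sc[e]))
        cc <- exp(delta)
        s_old <- exp(p$ls[e])
        s_new <- s_old * cc
        eta_prop <- eta + (cc - 1) * p$a[mf$sp, e] * x_cols[[e]]
        ll_prop <- loglik_terms(eta_prop, mf$j, mf$k)
        lr <- sum(ll_prop) - sum(ll_rec) +
          folded_t_log(s_new, priors$sigma_df, priors$sigma_scale) -
          folded_t_log(s_old, priors$sigma_df, priors$sigma_scale) +
          delta
        if (is.finite(lr) && log(runif(1)) < lr) {
          p$a[, e] <- p$a[, e] * cc
          p$ls[e] <- p$ls[e] + delta
          eta <- eta_prop
          ll_rec <- ll_prop
          if (adapting) log_scale_sc[e] <- log_scale_sc[e] + 1.4 / sqrt(t + 10)
        } else if (adapting) {
          log_scale_sc[e] <- log_scale_sc[e] - 0.6 / sqrt(t + 10)
        }
      }
    }
    if (!adapting && (t - settings$burn_in) %% settings$thin == 0 &&
      kept < keep) {
      kept <- kept + 1L
      draws[kept, ] <- c(
        p$beta,
        if (mf$hierarchical) c(as.vector(p$a), p$ls)
      )
    }
  }
  if (mf$hierarchical) {
    # stored as log sigma; expand_draws exponentiates
  }
  list(
    draws = draws,
    acceptance = c(
      beta = n_acc_beta / max(n_try_beta, 1),
      species = if (n_try_sp > 0) n_acc_sp / n_try_sp else NA_real_
    )
  )
}

# univariate slice sampler (stepping out + shrinkage; Neal 2003)
slice_1d <- function(x0, log_f, w = 1, m = 30) {
  y <- log_f(x0) - stats::rexp(1) # log-height under the density: log U + log f
  lo <- x0 - w * runif(1)
  hi <- lo + w
  j <- floor(m * runif(1))
  kk <- m - 1 - j
  while (j > 0 && y < log_f(lo)) {
    lo <- lo - w
    j <- j - 1
  }
  while (kk > 0 && y < log_f(hi)) {
    hi <- hi + w
    kk <- kk - 1
  }
  repeat {
    x1 <- runif(1, lo, hi)
    if (y < log_f(x1)) {
      return(x1)
    }
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

#' @export
print.migsurv_fit <- function(x, ...) {
  cat(sprintf(
    "<migsurv_fit> %s: %d records, %d species, k = %d\n",
    x$season, x$n_records, length(x$species_ids), x$k
  ))
  cat(sprintf(
    "  %d chains x %d draws (iterations %d, burn-in %d, thin %d)\n",
    x$settings$chains, sum(x$draws$.chain == 1), x$settings$iterations,
    x$settings$burn_in, x$settings$thin
  ))
  rh <- gelman_rubin(x)
  cat(sprintf("  max r_hat: %.3f\n", max(rh$rhat, na.rm = TRUE)))
  invisible(x)
}

# ---- diagnostics and summaries ------------------------------------------

#' Brooks-Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per scalar parameter:
#' `sqrt(((n-1)/n W + B/n) / W)` with `W` the mean within-chain variance
#' and `B/n` the variance of the chain means. Values near 1 indicate
#' convergence; parameters with `r_hat > 1.1` are flagged. Parameters with
#' zero variance in every chain (e.g. terms fixed at zero) get `NA`.
#'
#' @param fit A `migsurv_fit` (or any object with a `draws` tibble holding
#'   `.chain` and parameter columns).
#' @return A tibble with columns `parameter`, `rhat`, `flagged`.
#' @export
gelman_rubin <- function(fit) {
  draws <- if (inherits(fit, "migsurv_fit")) fit$draws else fit
  chains <- unique(draws$.chain)
  if (length(chains) < 2) abort("gelman_rubin() needs at least 2 chains")
  n <- min(table(draws$.chain))
  if (n < 10) abort("gelman_rubin() needs at least 10 draws per chain")
  pars <- setdiff(names(draws), c(".chain", ".iteration"))
  rhat <- vapply(pars, function(pn) {
    x <- split(draws[[pn]], draws$.chain)
    W <- mean(vapply(x, var, 1))
    Bn <- var(vapply(x, mean, 1))
    if (!is.finite(W) || W == 0) {
      return(NA_real_)
    }
    sqrt(((n - 1) / n * W + Bn) / W)
  }, 1)
  tibble::tibble(
    parameter = pars, rhat = unname(rhat),
    flagged = !is.na(rhat) & rhat > 1.1
  )
}

#' Posterior summary table
#'
#' Pooled across chains (post burn-in draws only are stored): posterior
#' mean, median and central 95% credible interval per parameter. Quantiles
#' use linear interpolation between order statistics.
#'
#' @param fit A `migsurv_fit`.
#' @return A tibble with columns `parameter`, `mean`, `median`, `q2.5`,
#'   `q97.5`.
#' @export
summarize_posterior <- function(fit) {
  draws <- if (inherits(fit, "migsurv_fit")) fit$draws else fit
  pars <- setdiff(names(draws), c(".chain", ".iteration"))
  purrr::map_dfr(pars, function(pn) {
    x <- draws[[pn]]
    q <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    tibble::tibble(
      parameter = pn, mean = mean(x), median = q[2], q2.5 = q[1], q97.5 = q[3]
    )
  })
}

#' @export
tidy.migsurv_fit <- function(x, ...) {
  s <- summarize_posterior(x)
  rh <- gelman_rubin(x)
  tibble::tibble(
    term = s$parameter, estimate = s$mean,
    conf.low = s$q2.5, conf.high = s$q97.5,
    rhat = rh$rhat[match(s$parameter, rh$parameter)]
  )
}

#' @export
glance.migsurv_fit <- function(x, ...) {
  rh <- gelman_rubin(x)
  tibble::tibble(
    n_records = x$n_records,
    n_species = length(x$species_ids),
    k = x$k,
    chains = x$settings$chains,
    draws_per_chain = sum(x$draws$.chain == 1),
    max_rhat = max(rh$rhat, na.rm = TRUE),
    converged = !any(rh$flagged)
  )
}

#' Posterior-mean parameters from a fit
#'
#' Collapses the posterior to its mean and returns a [model_params] object
#' (useful for plugging into [annual_survival()] or [log_likelihood()]).
#'
#' @param fit A `migsurv_fit`.
#' @return A [model_params] object.
#' @export
posterior_mean_params <- function(fit) {
  s <- summarize_posterior(fit)
  est <- setNames(s$mean, s$parameter)
  fixed <- est[fixed_effect_names()]
  if (fit$hierarchical) {
    sp <- tibble::tibble(
      species_id = fit$species_ids,
      a0 = unname(est[paste0("a0[", fit$species_ids, "]")]),
      a1 = unname(est[paste0("a1[", fit$species_ids, "]")]),
      a2 = unname(est[paste0("a2[", fit$species_ids, "]")])
    )
    sig <- pmax(unname(est[paste0("sigma", 0:2)]), 1e-12)
    model_params(fixed = fixed, species = sp, sigma = sig)
  } else {
    model_params(fixed = fixed)
  }
}

# ---- constant-survival MLE ----------------------------------------------

#' Constant-survival maximum likelihood from recovery counts
#'
#' Single-parameter version of the dead-recovery model: given counts of
#' recoveries by year `j = 1..k` (after the first-year shift), finds the
#' annual survival `s` maximizing the conditional multinomial likelihood.
#' Useful as a quick species-level estimate and as a testing oracle for
#' the full likelihood.
#'
#' @param counts Non-negative integer vector of recovery counts by year;
#'   `k = length(counts)`.
#' @return A tibble with columns `s_hat`, `log_lik`, `boundary` (`TRUE`
#'   when the maximizer lies on the boundary of (0, 1), e.g. all mass in
#'   the first or last cell).
#' @export
#' @examples
#' fit_constant_survival_mle(c(14, 3, 3, 1, 1))
fit_constant_survival_mle <- function(counts) {
  if (any(counts < 0) || sum(counts) < 1) {
    abort("counts must be non-negative with at least one recovery")
  }
  k <- length(counts)
  if (k < 2) abort("need k >= 2 cells for an identifiable survival")
  j <- seq_len(k)
  nll <- function(s) {
    -sum(counts * ((j - 1) * log(s) + log1p(-s) - log1mexp(k * log(s))))
  }
  eps <- 1e-9
  opt <- optimize(nll, c(eps, 1 - eps), tol = 1e-10)
  s_hat <- opt$minimum
  boundary <- s_hat < 1e-4 || s_hat > 1 - 1e-4
  tibble::tibble(s_hat = s_hat, log_lik = -opt$objective, boundary = boundary)
}

# ---- prior sensitivity ---------------------------------------------------

#' Prior sensitivity analysis
#'
#' Refits the model under each prior specification (same data, same MCMC
#' settings and seed) and tabulates the posterior summaries side by side,
#' with the maximum absolute difference in posterior means across priors
#' per parameter. With informative data the fixed-effect priors should
#' have a negligible effect.
#'
#' @param ds A prepared [recovery_data].
#' @param priors_list List of at least two [prior_spec] objects.
#' @param settings An [mcmc_settings].
#' @param ... Passed on to [fit_mcmc()].
#' @return A `prior_sensitivity` object: list with `summaries` (long
#'   tibble: `prior`, `parameter`, `mean`, `median`, `q2.5`, `q97.5`) and
#'   `delta` (tibble: `parameter`, `max_abs_diff_mean`).
#' @export
prior_sensitivity <- function(ds, priors_list, settings = mcmc_settings(), ...) {
  if (length(priors_list) < 2) abort("need at least two prior specifications")
  fits <- lapply(priors_list, function(pr) fit_mcmc(ds, pr, settings, ...))
  summaries <- purrr::map_dfr(seq_along(fits), function(i) {
    dplyr::bind_cols(
      tibble::tibble(prior = i), summarize_posterior(fits[[i]])
    )
  })
  delta <- summaries |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      max_abs_diff_mean = max(.data$mean) - min(.data$mean), .groups = "drop"
    )
  structure(
    list(summaries = summaries, delta = delta, n_priors = length(priors_list)),
    class = "prior_sensitivity"
  )
}

#' @export
print.prior_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<prior_sensitivity> %d priors; max |difference in posterior mean| = %.4f\n",
    x$n_priors, max(x$delta$max_abs_diff_mean)
  ))
  print(x$delta, n = 15)
  invisible(x)
}
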