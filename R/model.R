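#' Model parameters for the dead-recovery survival model
#'
#' Bundles the fixed-effect coefficients of the logit-linear survival
#' predictor with the species-level random deviations and their
#' hierarchical standard deviations.
#'
#' The predictor for the annual survival probability `S_i` of bird `i` of
#' species `g`, standardized migration day `d`, distance class indicator
#' `long` (0 = short, 1 = long) and scaled ringing year `y`, is
#'
#' `logit(S_i) = (b0 + a0_g) + (b_day + a1_g) d + (b_day2 + a2_g) d^2 +
#'   long (b_dist + b_day_dist d + b_day2_dist d^2) + b_year y + b_year2 y^2`
#'
#' with `a0_g, a1_g, a2_g ~ N(0, sigma0/1/2^2)`.
#'
#' @param fixed Named numeric vector with elements `b0`, `b_day`, `b_day2`,
#'   `b_dist`, `b_day_dist`, `b_day2_dist`, `b_year`, `b_year2` (all on the
#'   logit scale; missing names default to 0).
#' @param species Tibble with columns `species_id`, `a0`, `a1`, `a2`
#'   (species-level deviations), or `NULL` for no species effects.
#' @param sigma Named or positional numeric vector of the three
#'   hierarchical SDs `sigma0`, `sigma1`, `sigma2` (must be > 0).
#' @return A `model_params` object.
#' @export
#' @examples
#' model_params(fixed = c(b_day = 0.2, b_day2 = -0.1))
model_params <- function(fixed = numeric(), species = NULL,
                         sigma = c(sigma0 = 1, sigma1 = 1, sigma2 = 1)) {
  full <- setNames(numeric(length(fixed_effect_names())), fixed_effect_names())
  if (length(fixed) > 0) {
    if (is.null(names(fixed)) || any(!names(fixed) %in% names(full))) {
      abort(paste0(
        "fixed must be named from: ", paste(fixed_effect_names(), collapse = ", ")
      ))
    }
    full[names(fixed)] <- fixed
  }
  if (any(!is.finite(full))) abort("all fixed-effect coefficients must be finite")
  if (!is.null(species)) {
    species <- tibble::as_tibble(species)
    stopifnot(all(c("species_id", "a0", "a1", "a2") %in% names(species)))
    if (any(!is.finite(c(species$a0, species$a1, species$a2)))) {
      abort("species deviations must be finite")
    }
  }
  sigma <- unname(sigma)
  if (length(sigma) != 3 || any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("sigma must be three finite positive values")
  }
  structure(
    list(
      fixed = full,
      species = species,
      sigma = setNames(sigma, c("sigma0", "sigma1", "sigma2"))
    ),
    class = "model_params"
  )
}

fixed_effect_names <- function() {
  c(
    "b0", "b_day", "b_day2", "b_dist", "b_day_dist", "b_day2_dist",
    "b_year", "b_year2"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n fixed:\n")
  print(round(x$fixed, 4))
  cat(" sigma:", paste(round(x$sigma, 4), collapse = ", "), "\n")
  if (!is.null(x$species)) {
    cat(" species deviations for", nrow(x$species), "species\n")
  }
  invisible(x)
}

#' Conditional recovery-year cell probabilities
#'
#' Probability that a bird that is recovered dead within `k` years after
#' ringing is recovered in year `j`, under constant annual survival `s`:
#' `p_j = s^(j-1) (1 - s) / (1 - s^k)`, `j = 1, ..., k`. The conditioning
#' on recovery within `k` years is what removes the recovery probability
#' from the likelihood.
#'
#' @param s Annual survival probability, strictly inside (0, 1).
#' @param k Recovery horizon (maximal years from ringing to recovery).
#' @return Numeric vector of length `k`; strictly positive, sums to 1,
#'   strictly decreasing with ratio `p_(j+1)/p_j = s`.
#' @export
#' @examples
#' recovery_cell_probabilities(0.5, 2) # 2/3, 1/3
recovery_cell_probabilities <- function(s, k) {
  if (length(s) != 1 || !is.finite(s) || s <= 0 || s >= 1) {
    abort("s must be a single probability strictly inside (0, 1)")
  }
  if (length(k) != 1 || is.na(k) || k < 1 || k != as.integer(k)) {
    abort("k must be a single integer >= 1")
  }
  j <- seq_len(k)
  p <- exp((j - 1) * log(s) + log1p(-s) - log1mexp(k * log(s)))
  p / sum(p)
}

# log(1 - exp(x)) for x < 0, numerically stable near 0 and -Inf
log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

#' Annual survival from the logit-linear predictor
#'
#' Evaluates the survival predictor (see [model_params()]) for each row of
#' `data`. Species deviations are looked up by `species_id`; rows whose
#' species is absent from `params$species` are an error. When
#' `params$species` is `NULL`, deviations are taken as zero (population-
#' level prediction).
#'
#' @param data Data frame with columns `std_day`, `distance_class`,
#'   `species_id`.
#' @param params A [model_params] object.
#' @param year_scaled Scaled year covariate (scalar or one value per row);
#'   see [fit_mcmc()] for the scaling convention.
#' @return Numeric vector of survival probabilities, strictly inside (0, 1).
#' @export
annual_survival <- function(data, params, year_scaled = 0) {
  stopifnot(inherits(params, "model_params"))
  eta <- survival_linpred(data, params, year_scaled)
  plogis(eta)
}

survival_linpred <- function(data, params, year_scaled = 0) {
  d <- if (inherits(data, "recovery_data")) data$records else data
  stopifnot(all(c("std_day", "distance_class", "species_id") %in% names(d)))
  if (anyNA(d$std_day)) {
    abort("std_day is missing; run standardize_days() first")
  }
  b <- params$fixed
  if (is.null(params$species)) {
    a0 <- a1 <- a2 <- rep(0, nrow(d))
  } else {
    m <- match(d$species_id, params$species$species_id)
    if (anyNA(m)) {
      abort(paste0(
        "species without deviations in params: ",
        paste(unique(d$species_id[is.na(m)]), collapse = ", ")
      ))
    }
    a0 <- params$species$a0[m]
    a1 <- params$species$a1[m]
    a2 <- params$species$a2[m]
  }
  day <- d$std_day
  long <- as.numeric(d$distance_class == "long")
  y <- year_scaled
  unname(
    (b["b0"] + a0) + (b["b_day"] + a1) * day + (b["b_day2"] + a2) * day^2 +
      long * (b["b_dist"] + b["b_day_dist"] * day + b["b_day2_dist"] * day^2) +
      b["b_year"] * y + b["b_year2"] * y^2
  )
}

#' Log-likelihood of a prepared recovery dataset
#'
#' Sum over records of the log conditional multinomial cell probability of
#' the observed recovery year, with each bird's annual survival given by
#' the logit-linear predictor (survival constant over an individual's
#' life). Requires a prepared dataset (first-year exclusion and day
#' standardization applied).
#'
#' @param ds A prepared [recovery_data] object.
#' @param params A [model_params] object with deviations for every species
#'   in `ds` (or `NULL` species for the fixed-effects-only model).
#' @param year_center,year_scale Centering and scaling constants for the
#'   ringing-year covariate: `y = (ringing_year - year_center) /
#'   year_scale`. Defaults reproduce the convention of [fit_mcmc()]
#'   (midpoint and half-range of the observed ringing years).
#' @return The log-likelihood (a finite scalar for finite parameters).
#' @export
log_likelihood <- function(ds, params, year_center = NULL, year_scale = NULL) {
  stopifnot(inherits(ds, "recovery_data"))
  if (nrow(ds$records) == 0) abort("empty dataset")
  if (any(ds$records$years_to_recovery > ds$k)) {
    abort("record with years_to_recovery > k")
  }
  ys <- scale_years(ds$records$ringing_year, year_center, year_scale)
  eta <- survival_linpred(ds$records, params, ys$y)
  sum(loglik_terms(eta, ds$records$years_to_recovery, ds$k))
}

# per-record log cell probabilities given logit-survival eta
loglik_terms <- function(eta, j, k) {
  log_s <- plogis(eta, log.p = TRUE)
  log_1ms <- plogis(-eta, log.p = TRUE)
  (j - 1) * log_s + log_1ms - log1mexp(k * log_s)
}

scale_years <- function(years, center = NULL, scale = NULL) {
  if (is.null(center)) center <- (min(years) + max(years)) / 2
  if (is.null(scale)) {
    scale <- (max(years) - min(years)) / 2
    if (scale == 0) scale <- 1
  }
  list(y = (years - center) / scale, center = center, scale = scale)
}

#' Draw recovery years from the conditional multinomial
#'
#' Inverse-transform draws from [recovery_cell_probabilities()]: one draw
#' per element of `s`. Used by the synthetic-data generator. Uses R's
#' global random stream, so results are reproducible under [set.seed()].
#'
#' @param s Vector of annual survival probabilities in (0, 1).
#' @param k Recovery horizon.
#' @return Integer vector of recovery years in `[1, k]`, same length as `s`.
#' @export
simulate_recovery_year <- function(s, k) {
  if (any(!is.finite(s)) || any(s <= 0) || any(s >= 1)) {
    abort("s must lie strictly inside (0, 1)")
  }
  if (length(k) != 1 || k < 1) abort("k must be a single integer >= 1")
  if (k == 1) {
    return(rep(1L, length(s)))
  }
  u <- runif(length(s))
  # CDF F(j) = (1 - s^j) / (1 - s^k); invert for the smallest j with F(j) >= u
  j <- ceiling(log1p(-u * (1 - s^k)) / log(s))
  as.integer(pmin(pmax(j, 1L), k))
}
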