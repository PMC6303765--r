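# migsurv

Survival consequences of migration timing, estimated from dead-recovery
ringing data.

## The problem

For migratory songbirds, returning early to the breeding grounds pays off in
reproduction but may cost survival: the earliest birds risk cold spells and
food shortage, the latest tend to be individuals in poor condition, and
males — which typically migrate ahead of females (protandry) — may be pushed
past the survival-optimal date by competition for territories. migsurv is
for ornithologists and ringing-scheme analysts who want to quantify this
trade-off from two standard data types:

1. **ring-recovery tables** — birds captured once on migration (giving a
   migration date) and later reported dead (giving an exact life span); and
2. **standardized-effort trapping tables** — daily capture counts at a
   stopover site, sexed where plumage allows, giving the timing
   distribution of each species and sex.

## The model

Ringing totals for specific migration windows are unknown, so the package
uses the BTO dead-recovery likelihood: conditional on a bird being recovered
dead within *k* years of ringing, the probability its death fell in year
*j* is

```
p_j = S^(j-1) (1 - S) / (1 - S^k),      j = 1, ..., k
```

with *S* the bird's annual survival. The recovery probability cancels out of
this conditional multinomial entirely. Each bird's survival follows a
hierarchical logit-linear predictor

```
logit(S_i) = (b0 + a0_g) + (b_day + a1_g) d_i + (b_day2 + a2_g) d_i^2
           + long_i (b_dist + b_day_dist d_i + b_day2_dist d_i^2)
           + b_year y_i + b_year2 y_i^2
```

where `d_i` is the migration day standardized within species, `long_i`
flags long-distance (sub-Saharan) migrants, `y_i` is the scaled ringing
year, and the species deviations `a0_g, a1_g, a2_g ~ N(0, sigma^2)` pool
information across species. Inference is Bayesian (N(0, 5) priors on
coefficients, folded-t(2) on the hierarchical SDs; two chains of 10,000,
burn-in 1,000, thinning 5), with Brooks–Gelman–Rubin diagnostics. Survival
curves with 95% credible bands, their optimum dates, and the percentage of
males and females migrating before the optimum complete the pipeline.
First-year deaths are excluded (with all spans shifted down one year), and
species need at least five recoveries after that exclusion to enter.

Individual-level ringing data of the motivating study are not public, so
the package ships a ground-truth synthetic generator
(`truth_config()` / `generate_dataset()` / `generate_effort()`) emulating
both input types, plus a packaged transcription of the published
per-species recovery counts (`published_recovery_counts()`).

## Worked example

```r
library(migsurv)

cfg    <- truth_config(seed = 7)      # 8 species, 3000 recovered adults
bundle <- generate_dataset(cfg)

prep <- bundle$dataset |> prepare_recovery_data()
#> <recovery_data> spring: 3000 records, 8 species, k = 9

fit <- fit_mcmc(prep, priors = prior_spec(), settings = mcmc_settings(seed = 7))
glance(fit)
#>   n_records n_species     k chains draws_per_chain max_rhat converged
#> 1      3000         8     9      2            1800     1.01 TRUE

tidy(fit)
#>    term        estimate conf.low conf.high  rhat
#>  1 b0           -0.284  -0.660      0.106  1.00
#>  2 b_day        -0.238  -0.441     -0.0218 1.00
#>  3 b_day2       -0.0959 -0.205      0.0116 1.00
#>  5 b_day_dist    0.676   0.391      0.935  1.00
#>  6 b_day2_dist  -0.504  -0.665     -0.352  1.00
#>  ...
```

`max_rhat = 1.01` says the chains agree; the negative `b_day` (short-
distance survival declines with date) and the negative effective quadratic
for long-distance migrants (`b_day2 + b_day2_dist ≈ -0.6`) recover the
generator's truth (-0.3 and -0.5). Curves and the protandry comparison:

```r
optimum_day(curve_for_group(fit, "long"))
#>   group std_day calendar_day at_boundary
#> 1 long    0.353           NA       FALSE        # truth: d* = 0.2

sp_opt <- optimum_day(curve_for_species(fit, "sp05"))
#>   group std_day calendar_day at_boundary
#> 1 sp05    0.455          139       FALSE

sex_comparison(bundle$effort, "sp05", sp_opt, window = c(109, 157))
#>   species_id sex    optimum_day percent_before n_birds
#> 1 sp05       male           139           78.8     250
#> 2 sp05       female         139           55.2     250
```

With the generator's 6-day male advance, 79% of males but only 55% of
females pass the stopover before the survival-optimal day — the protandry
signature the analysis is designed to expose. A quick species-level
constant-survival estimate from published-style counts:

```r
fit_constant_survival_mle(c(14, 3, 3, 1, 1))   # pied flycatcher cells Y2..Y6
#>   s_hat log_lik boundary
#> 1 0.451   -25.5 FALSE
```

A command-line front end over the same functions is in
`inst/cli/migsurv` (`simulate`, `fit`, `report`, `sensitivity`), and the
methods vignette (`vignettes/migration-survival.Rmd`) documents the model,
priors, sampler and the generator's assumptions in detail.

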