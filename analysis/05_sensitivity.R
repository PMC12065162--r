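#!/usr/bin/env Rscript

# Stage 5: sensitivity of the estimates to year-precision vital dates.
#
# Regenerates the cohort with birth and death dates degraded to
# calendar-year windows, then repeats the fit-and-estimate pipeline five
# times with different uniformly drawn exact dates inside those windows.
# The spread of the frailty-free life-expectancy point estimates across
# jitter seeds is compared with the half-width of the bootstrap interval:
# date imprecision should move the estimates far less than sampling
# uncertainty does.

suppressPackageStartupMessages(library(frailspan))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

cohort <- synthetic_cohort("standard", seed = seed, genders = "women",
                           date_precision = "year")
grid <- le_grid(age0 = 50, h = 0.5, age_max = 115)
spec <- msm_spec(covariates = c("age", "wealth"), stratum = "women")

ff <- numeric(5)
half_width <- NA_real_
for (k in 1:5) {
  jp <- rejitter_panel(cohort, seed = seed + 1000L + k)
  v <- validate_panel(jp)
  fit <- fit_msm(v$panel, spec)
  init <- initial_state_distribution(v$panel, grid$age0)
  if (k == 1) {
    b <- bootstrap_les(fit, covariate_profile(wealth_q = 3), grid, init,
                       n_draws = 1000, seed = seed + 7L)
    ff[k] <- b$frailty_free
    half_width <- (b$ci$frailty_free[2] - b$ci$frailty_free[1]) / 2
  } else {
    ff[k] <- marginal_les(state_specific_les(
      fit, covariate_profile(wealth_q = 3), grid), init)$frailty_free
  }
  message(sprintf("jitter seed %d: frailty-free LE50 = %.3f years", k, ff[k]))
}

spread <- max(ff) - min(ff)
message(sprintf(
  "spread across 5 jitter seeds: %.3f years; bootstrap CI half-width: %.3f years",
  spread, half_width))
message(if (spread < half_width)
  "date imprecision is immaterial next to sampling uncertainty" else
  "WARNING: date imprecision is not negligible here")

write.csv(data.frame(jitter_seed = 1:5, frailty_free_le50 = ff,
                     spread = spread, ci_half_width = half_width),
          "results/sensitivity.csv", row.names = FALSE)
message("written to results/sensitivity.csv")
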