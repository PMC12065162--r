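#!/usr/bin/env Rscript

# Stage 2: fit the four-state continuous-time Markov model per gender.
#
# Reads the panel written by 01_simulate_cohort.R, fits two candidate
# covariate structures per stratum (age only; age + wealth on every
# transition), ranks them by BIC, and writes the selected fits and their
# hazard-ratio tables under results/.

suppressPackageStartupMessages(library(frailspan))
stopifnot(file.exists("results/panel.csv"))
panel <- read_panel("results/panel.csv")

for (g in c("women", "men")) {
  glab <- if (g == "women") "woman" else "man"
  sub <- panel[panel$gender == glab, , drop = FALSE]
  message("== ", g, ": ", length(unique(sub$subject_id)), " subjects ==")

  fit_age <- fit_msm(sub, msm_spec(covariates = "age", stratum = g))
  fit_aw <- fit_msm(sub, msm_spec(covariates = c("age", "wealth"),
                                  stratum = g))
  cmp <- compare_models(age_only = fit_age, age_wealth = fit_aw)
  print(cmp)
  best <- list(age_only = fit_age, age_wealth = fit_aw)[[cmp$model[1]]]
  message("selected by BIC: ", cmp$model[1])

  write_fit_json(best, paste0("results/fit_", g, ".json"))
  hr <- hazard_ratios(best)
  write.csv(hr, paste0("results/hazard_ratios_", g, ".csv"),
            row.names = FALSE)
  message("hazard ratios (wealth terms):")
  print(hr[hr$term == "wealth", c("transition", "hr", "lower", "upper")],
        row.names = FALSE, digits = 3)
}
message("fits written to results/fit_{women,men}.json")
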