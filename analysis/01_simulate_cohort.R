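#!/usr/bin/env Rscript

# Stage 1: generate the synthetic ageing cohort the analysis runs on.
#
# Emulates an English ageing-cohort design: ~2,000 adults aged 50+ (54.5%
# women), nine biennial interview waves, per-wave attrition, wealth and
# deprivation quintiles with a positive rank correlation, and deaths
# recorded at their exact age. Writes the interval-censored panel and a
# baseline characteristics summary under results/.

suppressPackageStartupMessages(library(frailspan))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

cohort <- synthetic_cohort("standard", seed = seed,
                           genders = c("women", "men"))
print(cohort)

val <- validate_panel(cohort$panel)
print(val)
message("exclusions: ", nrow(val$excluded),
        " subjects lacked longitudinal data")

write_panel(val$panel, "results/panel.csv")

# baseline characteristics (first observation per subject)
base <- val$panel[!duplicated(val$panel$subject_id), ]
summ <- data.frame(
  characteristic = c("subjects", "women_pct", "married_pct",
                     "robust_pct", "prefrail_pct", "frail_pct",
                     "median_age"),
  value = round(c(
    nrow(base),
    100 * mean(base$gender == "woman"),
    100 * mean(base$married == 1),
    100 * mean(base$state == 1), 100 * mean(base$state == 2),
    100 * mean(base$state == 3),
    median(base$age)
  ), 1)
)
write.csv(summ, "results/baseline_characteristics.csv", row.names = FALSE)
message("baseline characteristics:")
print(summ, row.names = FALSE)
message("panel written to results/panel.csv (",
        nrow(val$panel), " records)")
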