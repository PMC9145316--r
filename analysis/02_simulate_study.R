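#!/usr/bin/env Rscript
# Generate the seeded synthetic study: a two-day consumption survey of
# toddlers, a food-to-composite-sample conversion table, and heavily
# left-censored lognormal concentration data for eleven mycotoxins, plus
# a paired dose-response fixture for the RPF tier. Emulates the shape of
# a total-diet-study based assessment; it is not real monitoring data.

suppressPackageStartupMessages(library(tieredmix))

seed <- 2026
fx <- mycotoxin_study_fixture(seed, n_individuals = 300)

paths <- write_study_csvs(fx, "results/study")

cat("Synthetic study (seed", seed, "):\n")
cat(" -", nrow(fx$survey$individuals), "individuals,",
    nrow(fx$survey$records), "consumption records\n")
cat(" -", nrow(fx$concentrations), "concentration measurements,",
    sprintf("%.0f%%", 100 * mean(fx$concentrations$censored)),
    "left-censored\n")
cat(" - dose-response fixture: true T2-vs-NIV potency ratio",
    fx$dr_design$true_rpf[["T2HT2"]], "\n")
cat("Wrote", paste(basename(paths), collapse = ", "), "to results/study/\n")
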