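#!/usr/bin/env Rscript
# Combined risk at the common-target-organ and common-phenomenon tiers:
# per-compound reference point quotients, the percentile-sum mRPI, the
# individually combined metric from reference-value scaling, and the
# tiered decision trail.

suppressPackageStartupMessages({
  library(tieredmix)
  library(dplyr)
})

seed <- 2026
fx <- mycotoxin_study_fixture(seed, n_individuals = 300)
trv <- function(cp, gr) fx$trvs$trv[fx$trvs$compound == cp &
                                      fx$trvs$group == gr]

metrics <- list()
group_summary <- list()
for (gr in names(fx$groups)) {
  members <- fx$groups[[gr]]
  for (sc in c("LB", "UB")) {
    ex <- lapply(members, function(cp) {
      oim_exposure(fx$survey, fx$concentrations, fx$conversion, sc, cp)
    })
    names(ex) <- members
    trvs <- vapply(members, function(cp) trv(cp, gr), numeric(1))
    for (p in c(50, 95)) {
      rpqs <- bind_rows(lapply(members, function(cp) {
        pu <- percentile_with_uncertainty(ex[[cp]], p, B = 100, seed = seed)
        risk_quotient(cp, gr, sc, p, pu$median_boot, trvs[[cp]])
      }))
      metrics[[length(metrics) + 1]] <- rpqs |>
        transmute(group = gr, scenario = sc, percentile = p,
                  method = "RPQ", value = quotient,
                  reference_compound = compound)
      msum <- mrpi_sum(rpqs, expected_members = members)
      comb <- cumulative_exposure_trv_scaling(ex, trvs, members[1])
      mind <- risk_characterisation(comb, trvs[[members[1]]],
                                    percentiles = p, B = 100, seed = seed) |>
        mutate(group = gr, method = "mRPI_individual")
      metrics[[length(metrics) + 1]] <- msum
      metrics[[length(metrics) + 1]] <-
        mind[, c("group", "scenario", "percentile", "method", "value",
                 "reference_compound")]
      group_summary[[paste(gr, sc, p)]] <- c(sum = msum$value,
                                             individual = mind$value)
    }
  }
}
metrics <- bind_rows(metrics)

gmax <- function(gr) max(metrics$value[metrics$group == gr &
                                         metrics$method != "RPQ"])
trail <- tiered_assessment(list(
  list(id = "kidney",
       metrics = tibble::tibble(value = gmax("kidney"))),
  list(id = "liver", metrics = tibble::tibble(value = gmax("liver"))),
  list(id = "haematological",
       metrics = tibble::tibble(value = gmax("haematological")),
       phenomenon = list(id = "wbc",
                         metrics = tibble::tibble(value = gmax("wbc")),
                         has_dose_response_pair = TRUE))
))

write_report(metrics, trail, "results", name = "combined_risk")

cat("Combined risk metrics (UB P95):\n")
for (gr in names(fx$groups)) {
  s <- group_summary[[paste(gr, "UB", 95)]]
  cat(sprintf("  %-15s mRPI(sum) %-8s individually combined %s\n", gr,
              signif(s[["sum"]], 2), signif(s[["individual"]], 2)))
}
cat("\nTier decisions:\n")
print(as.data.frame(trail))
cat("\nThe percentile sum sits at or above the individually combined",
    "metric at P95, the expected overestimation from summing marginal",
    "high percentiles.\nWrote results/combined_risk.{csv,json,txt}\n")
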