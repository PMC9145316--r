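rq <- function(compound, q, group = "g", scenario = "UB", percentile = 95,
               flavor = "RPQ") {
  tibble::tibble(compound = compound, group = group, scenario = scenario,
                 percentile = percentile, quotient = q, flavor = flavor)
}

test_that("hazard index sums hazard quotients and rejects mixed percentiles", {
  hqs <- dplyr::bind_rows(rq("A", 0.2), rq("B", 0.3))
  expect_equal(hazard_index(hqs)$value, 0.5)
  expect_equal(hazard_index(rq("A", 1))$value, 1)
  expect_equal(hazard_index(dplyr::bind_rows(rq("A", 0), rq("B", 0)))$value, 0)
  mixed <- dplyr::bind_rows(rq("A", 0.2), rq("B", 0.3, percentile = 50))
  expect_error(hazard_index(mixed), "percentile")
})

test_that("summed quotients reproduce the worked upper-bound P95 group sums", {
  # haematological group, toddlers: per-compound P95 UB quotients
  haem <- dplyr::bind_rows(
    rq("DAS", 0.004), rq("NIV", 0.020), rq("MON", 0.71),
    rq("T2", 9.6), rq("HT2", 6.9)
  )
  m <- mrpi_sum(haem)
  expect_equal(m$value, 17.234)
  expect_equal(signif(m$value, 2), 17)

  kidney <- dplyr::bind_rows(
    rq("CIT", 1.0), rq("FB1", 0.088), rq("FB2", 0.084), rq("FB3", 0.084),
    rq("NIV", 0.005), rq("OTA", 1.2), rq("PAT", 0.025)
  )
  m <- mrpi_sum(kidney)
  expect_equal(m$value, 2.486)
  expect_equal(signif(m$value, 2), 2.5)

  zeros <- dplyr::bind_rows(rq("A", 0), rq("B", 0))
  expect_equal(mrpi_sum(zeros)$value, 0)
  expect_warning(mrpi_sum(haem, expected_members = c("DAS", "NIV", "XX")),
                 "XX")
})

test_that("TRV-ratio scaling is invariant to the reference compound", {
  ex <- random_exposures(n = 80, seed = 3)
  trvs <- c(A = 0.5, B = 2, C = 10)
  metrics <- sapply(names(trvs), function(ref) {
    comb <- cumulative_exposure_trv_scaling(ex, trvs, ref)
    stats::quantile(comb$values, 0.95, names = FALSE) / trvs[[ref]]
  })
  expect_equal(metrics[["A"]], metrics[["B"]], tolerance = 1e-12)
  expect_equal(metrics[["A"]], metrics[["C"]], tolerance = 1e-12)

  # single compound with itself as reference is the identity
  one <- ex["A"]
  comb <- cumulative_exposure_trv_scaling(one, trvs, "A")
  expect_equal(comb$values, ex$A$values, ignore_attr = TRUE)

  # equal TRVs reduce to the plain per-individual sum
  eq <- cumulative_exposure_trv_scaling(ex, c(A = 2, B = 2, C = 2), "A")
  expect_equal(unname(eq$values),
               unname(ex$A$values + ex$B$values + ex$C$values))

  expect_error(cumulative_exposure_trv_scaling(ex, c(A = 1, B = 1), "A"),
               "missing TRV")
})

test_that("RPF combination follows the reference-equivalent arithmetic", {
  ex <- list(
    NIV = structure(list(compound = "NIV", scenario = "UB",
                         values = c(i1 = 1)), class = "exposure_dist"),
    T2HT2 = structure(list(compound = "T2HT2", scenario = "UB",
                           values = c(i1 = 0.01)), class = "exposure_dist")
  )
  comb <- combine_with_rpf(ex, rpf_set("NIV", c(T2HT2 = 140)))
  expect_equal(unname(comb$values), 1 + 0.01 * 140)  # 2.4 NIV equivalents

  self <- combine_with_rpf(ex["NIV"], rpf_set("NIV"))
  expect_equal(self$values, ex$NIV$values, ignore_attr = TRUE)

  expect_error(rpf_set("NIV", c(T2HT2 = -1)), "positive")
})

test_that("the metric ratio across RPF reference choices equals RPF x TRV ratio", {
  ex <- random_exposures(n = 120, compounds = c("NIV", "T2HT2"), seed = 9)
  trvs <- c(NIV = 1.75, T2HT2 = 0.02)
  rpf_niv <- rpf_set("NIV", c(T2HT2 = 140))
  rpf_t2 <- rebase_rpf(rpf_niv, "T2HT2")
  expect_equal(rpf_t2$rpf[["NIV"]], 1 / 140)

  for (p in c(0.5, 0.95)) {
    m_niv <- stats::quantile(combine_with_rpf(ex, rpf_niv)$values, p,
                             names = FALSE) / trvs[["NIV"]]
    m_t2 <- stats::quantile(combine_with_rpf(ex, rpf_t2)$values, p,
                            names = FALSE) / trvs[["T2HT2"]]
    # monotone rescaling preserves ranks, so percentiles scale exactly
    expect_equal(m_niv / m_t2, 140 * trvs[["T2HT2"]] / trvs[["NIV"]],
                 tolerance = 1e-12)
  }
  # the worked numbers: 140 x 0.02 / 1.75 = 1.6
  expect_equal(140 * 0.02 / 1.75, 1.6)
})

test_that("comonotonic exposures make percentile-sum and individual combination agree", {
  ex <- random_exposures(n = 150, seed = 21, comonotonic = TRUE)
  trvs <- c(A = 0.5, B = 2, C = 10)
  for (p in c(0.5, 0.95)) {
    sum_of_q <- sum(sapply(names(ex), function(cp) {
      stats::quantile(ex[[cp]]$values, p, names = FALSE) / trvs[[cp]]
    }))
    comb <- cumulative_exposure_trv_scaling(ex, trvs, "A")
    q_of_sum <- stats::quantile(comb$values, p, names = FALSE) / trvs[["A"]]
    expect_equal(sum_of_q, q_of_sum, tolerance = 1e-10)
  }
})

test_that("every combined method collapses to the single RPQ for one compound", {
  ex <- random_exposures(n = 60, compounds = "A", seed = 5)
  trvs <- c(A = 0.7)
  p95 <- stats::quantile(ex$A$values, 0.95, names = FALSE)
  rpq <- p95 / trvs[["A"]]
  comb_trv <- cumulative_exposure_trv_scaling(ex, trvs, "A")
  comb_rpf <- combine_with_rpf(ex, rpf_set("A"))
  expect_equal(stats::quantile(comb_trv$values, 0.95, names = FALSE) / 0.7, rpq)
  expect_equal(stats::quantile(comb_rpf$values, 0.95, names = FALSE) / 0.7, rpq)
})

test_that("risk characterisation divides bootstrap-median percentiles by the TRV", {
  ex <- random_exposures(n = 100, compounds = "A", seed = 2)
  comb <- cumulative_exposure_trv_scaling(ex, c(A = 2), "A")
  rc <- risk_characterisation(comb, trv_ref = 2, percentiles = c(50, 95),
                              B = 50, seed = 4)
  expect_equal(nrow(rc), 2)
  expect_equal(rc$method, rep("mRPI_individual", 2))
  rc2 <- risk_characterisation(comb, trv_ref = 4, percentiles = c(50, 95),
                               B = 50, seed = 4)
  expect_equal(rc$value, 2 * rc2$value)  # halving by doubling the TRV
})

test_that("the tiered decision flow stops, refines or flags as designed", {
  low <- list(id = "liver", metrics = tibble::tibble(value = c(0.5, 0.9)))
  high_no_ph <- list(id = "kidney",
                     metrics = tibble::tibble(value = c(0.8, 2.5)))
  high_ph <- list(
    id = "haematological", metrics = tibble::tibble(value = c(1.3, 17)),
    phenomenon = list(id = "wbc",
                      metrics = tibble::tibble(value = c(1.1, 16)),
                      has_dose_response_pair = TRUE)
  )
  trail <- tiered_assessment(list(low, high_no_ph, high_ph))
  expect_false(trail$proceed[trail$group == "liver"])
  expect_match(trail$note[trail$group == "kidney"], "not possible")
  expect_true("rpf" %in% trail$tier[trail$group == "wbc"])

  no_pair <- high_ph
  no_pair$phenomenon$has_dose_response_pair <- FALSE
  trail2 <- tiered_assessment(list(no_pair))
  expect_match(trail2$note[trail2$tier == "phenomenon"], "skipped")
  expect_false(any(trail2$tier == "rpf"))
})
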