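test_that("generation is fully deterministic under a seed", {
  d <- survey_design(25)
  expect_identical(generate_survey(d, 99), generate_survey(d, 99))
  expect_false(identical(generate_survey(d, 99)$records,
                         generate_survey(d, 100)$records))

  cd <- contamination_design(tibble::tibble(
    sample_code = "s1", compound = c("A", "B"), p_occur = 0.5,
    meanlog = 0, sdlog = 1, lod = 0.5, loq = 1
  ))
  expect_identical(generate_concentrations(cd, 5),
                   generate_concentrations(cd, 5))

  dd <- dose_response_design("A", c(A = 1))
  expect_identical(generate_dose_response(dd, 3),
                   generate_dose_response(dd, 3))
})

test_that("degenerate survey designs behave as designed", {
  empty <- generate_survey(survey_design(0), 1)
  expect_equal(nrow(empty$individuals), 0)
  expect_equal(nrow(empty$records), 0)

  sure <- survey_design(10, n_days = 2, foods = tibble::tibble(
    food_code = "bread", p_consume = 1, amount_meanlog = log(50),
    amount_sdlog = 0
  ))
  sv <- generate_survey(sure, 2)
  expect_equal(nrow(sv$records), 10 * 2)  # every individual, every day
  expect_equal(unique(sv$records$amount_g), 50)
})

test_that("censoring structure follows the design", {
  mk <- function(p_occur, lod, loq = lod) {
    contamination_design(tibble::tibble(
      sample_code = sprintf("s%05d", 1:10000), compound = "A",
      p_occur = p_occur, meanlog = 0, sdlog = 1, lod = lod, loq = loq
    ))
  }
  # occurrence 0: everything censored
  all_cens <- generate_concentrations(mk(0, 0.5), 1)
  expect_true(all(all_cens$censored))
  # LOD 0: nothing censored at the LOD
  none <- generate_concentrations(mk(1, 0), 1)
  expect_true(all(!none$censored | none$censor_flag != "<LOD"))
  # designed ~70% censoring: LOD at the 70th percentile of the lognormal
  tab <- generate_concentrations(mk(1, stats::qlnorm(0.7, 0, 1)), 17)
  frac <- mean(tab$censored)
  expect_gte(frac, 0.68)
  expect_lte(frac, 0.72)
})

test_that("designed marginals are recovered within sampling error", {
  sv <- generate_survey(survey_design(5000), 23)
  ks <- stats::ks.test(sv$individuals$body_weight_kg, "plnorm",
                       meanlog = log(12), sdlog = 0.15)
  expect_gt(ks$p.value, 0.01)
})

test_that("zero-noise dose-response lies exactly on the true curve", {
  dd <- dose_response_design("A", c(A = 1), sigma_log = 0)
  dr <- generate_dose_response(dd, 1)$A
  g <- 1 - exp(-(0.002 * dr$data$dose))
  truth <- 10 * (1 + (0.2 - 1) * g)
  expect_equal(dr$data$mean, truth, tolerance = 1e-6)
})

test_that("the full study bundle drives the tiered flow as calibrated", {
  fx <- mycotoxin_study_fixture(seed = 101, n_individuals = 120)
  trv <- function(cp, gr) fx$trvs$trv[fx$trvs$compound == cp &
                                        fx$trvs$group == gr]
  metric <- function(group_id, members) {
    ex <- lapply(members, function(cp) {
      oim_exposure(fx$survey, fx$concentrations, fx$conversion, "UB", cp)
    })
    names(ex) <- members
    trvs <- vapply(members, function(cp) trv(cp, group_id), numeric(1))
    comb <- cumulative_exposure_trv_scaling(ex, trvs, members[1])
    stats::quantile(comb$values, 0.95, names = FALSE) / trvs[[1]]
  }
  liver <- metric("liver", fx$groups$liver)
  wbc <- metric("wbc", fx$groups$wbc)
  expect_lt(liver, 1)   # assessment stops at the organ tier
  expect_gt(wbc, 1)     # phenomenon tier triggers refinement

  trail <- tiered_assessment(list(
    list(id = "liver", metrics = tibble::tibble(value = liver)),
    list(id = "haematological", metrics = tibble::tibble(value = wbc),
         phenomenon = list(id = "wbc", metrics = tibble::tibble(value = wbc),
                           has_dose_response_pair = TRUE))
  ))
  expect_false(trail$proceed[trail$group == "liver"])
  expect_true("rpf" %in% trail$tier)
})

test_that("a comonotonic contamination variant equates the two combination routes", {
  fx <- mycotoxin_study_fixture(seed = 55, n_individuals = 80,
                             rank_correlation = 1)
  members <- fx$groups$wbc
  ex <- lapply(members, function(cp) {
    oim_exposure(fx$survey, fx$concentrations, fx$conversion, "UB", cp)
  })
  names(ex) <- members
  # same consumption pattern scales all compounds: not exactly comonotonic
  # at individual level, so assert near-equality of the two routes
  trvs <- vapply(members, function(cp) {
    fx$trvs$trv[fx$trvs$compound == cp & fx$trvs$group == "wbc"]
  }, numeric(1))
  sum_q <- sum(vapply(members, function(cp) {
    stats::quantile(ex[[cp]]$values, 0.95, names = FALSE) / trvs[[cp]]
  }, numeric(1)))
  comb <- cumulative_exposure_trv_scaling(ex, trvs, members[1])
  ind_q <- stats::quantile(comb$values, 0.95, names = FALSE) / trvs[[1]]
  expect_equal(ind_q, sum_q, tolerance = 0.25)
})
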