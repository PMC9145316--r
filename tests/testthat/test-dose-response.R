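test_that("SD and SEM interconvert exactly", {
  expect_equal(sd_to_sem(4, 16), 1)
  expect_equal(sd_to_sem(2.5, 1), 2.5)
  expect_equal(sd_to_sem(3.5, 10), 3.5 / sqrt(10))
  expect_equal(sem_to_sd(sd_to_sem(3.7, 12), 12), 3.7)
  expect_error(sd_to_sem(1, 0), ">= 1")
})

test_that("dataset validation enforces control group and positive means", {
  expect_error(
    dose_response_dataset("A", "e", c(10, 20), c(5, 4), c(1, 1), "SD",
                          c(10, 10)),
    "control"
  )
  expect_error(
    dose_response_dataset("A", "e", c(0, 10), c(5, -1), c(1, 1), "SD",
                          c(10, 10)),
    "positive"
  )
})

test_that("noise-free exponential data are recovered almost exactly", {
  dd <- dose_response_design("A", c(A = 1), sigma_log = 0)
  dr <- generate_dose_response(dd, 1)$A
  fit <- fit_model(dr, "exp3")
  expect_equal(fit$par$a, 10, tolerance = 1e-6)
  expect_equal(fit$par$b, 0.002, tolerance = 1e-5)
  expect_equal(fit$par$c, 0.2, tolerance = 1e-5)
})

test_that("likelihoods nest: full >= exponential >= null", {
  dd <- dose_response_design("A", c(A = 1), sigma_log = 0.15)
  for (seed in c(2, 3, 4)) {
    dr <- generate_dose_response(dd, seed)$A
    ll <- sapply(c("null", "exp3", "full"),
                 function(f) fit_model(dr, f)$logLik)
    expect_gte(ll[["exp3"]], ll[["null"]] - 1e-6)
    expect_gte(ll[["full"]], ll[["exp3"]] - 1e-6)
  }
})

test_that("flat data leave the potency unidentified and the BMD unbounded", {
  dr <- dose_response_dataset("A", "e", c(0, 100, 200, 400), rep(8, 4),
                              rep(0.8, 4), "SD", rep(10, 4))
  f_null <- fit_model(dr, "null")
  f_exp <- fit_model(dr, "exp3")
  expect_equal(f_exp$logLik, f_null$logLik, tolerance = 1e-4)
  bmd <- bmd_from_model(f_exp, 0.10)
  expect_true(is.infinite(bmd) || isTRUE(attr(bmd, "unbounded")))
})

test_that("the benchmark dose inverts the fitted curve at the benchmark response", {
  dd <- dose_response_design("A", c(A = 1), sigma_log = 0.1)
  dr <- generate_dose_response(dd, 6)$A
  for (fam in c("exp3", "hill3")) {
    fit <- fit_model(dr, fam)
    for (bmr in c(0.05, 0.10, 0.20)) {
      bmd <- as.numeric(bmd_from_model(fit, bmr))
      lhs <- exp(predict_logmean(fit, bmd))
      rhs <- exp(predict_logmean(fit, 0)) * (1 - bmr)
      expect_equal(lhs, rhs, tolerance = 1e-8)
    }
    # monotone in the benchmark response
    bmds <- sapply(c(0.02, 0.05, 0.10, 0.20),
                   function(b) as.numeric(bmd_from_model(fit, b)))
    expect_true(all(diff(bmds) > 0))
  }
})

test_that("AIC weights normalise and model averaging keeps BMDL <= BMD <= BMDU", {
  drs <- read_dose_response(wbc_fixture_path())
  fits <- lapply(c("exp3", "hill3"), function(f) fit_model(drs$NIV, f))
  w <- aic_weights(fits)
  expect_equal(sum(w), 1)

  ma <- model_average_bmd(drs$NIV, bmr = 0.10, B = 200, seed = 31)
  expect_lte(ma$bmdl, ma$bmd)
  expect_lte(ma$bmd, ma$bmdu)
  expect_gt(ma$bmdl, 0)

  ma2 <- model_average_bmd(drs$NIV, bmr = 0.10, B = 200, seed = 31)
  expect_equal(ma$bmd, ma2$bmd)
  expect_equal(ma$bmdl, ma2$bmdl)

  # single family degenerates to that family's bootstrap interval
  ma1 <- model_average_bmd(drs$NIV, bmr = 0.10, families = "exp3",
                           B = 100, seed = 8)
  expect_equal(unname(ma1$weights), 1)
  expect_lte(ma1$bmdl, ma1$bmd)
  expect_lte(ma1$bmd, ma1$bmdu)
})

test_that("two identical datasets give a relative potency of one", {
  dd <- dose_response_design(c("A", "B"), c(A = 1, B = 1), sigma_log = 0)
  drs <- generate_dose_response(dd, 4)
  sf <- simultaneous_fit(drs, "A")
  expect_equal(sf$rpf$rpf[["B"]], 1, tolerance = 1e-4)
})

test_that("dose scaling is recovered as the relative potency", {
  dd <- dose_response_design(c("A", "B"), c(A = 1, B = 50), sigma_log = 0.05)
  drs <- generate_dose_response(dd, 12)
  sf <- suppressWarnings(simultaneous_fit(drs, "A"))
  expect_equal(sf$rpf$rpf[["B"]], 50, tolerance = 0.05)
  # dose-unit equivariance: shrinking one compound's doses by k raises
  # its potency (and RPF) by k
  drs2 <- drs
  d2 <- drs2$B$data
  drs2$B <- dose_response_dataset("B", drs2$B$endpoint, d2$dose / 4,
                                  d2$mean, d2$dispersion,
                                  d2$dispersion_type, d2$n,
                                  drs2$B$direction)
  sf2 <- suppressWarnings(simultaneous_fit(drs2, "A"))
  expect_equal(sf2$rpf$rpf[["B"]], 4 * sf$rpf$rpf[["B"]], tolerance = 0.01)
})

test_that("the RPF from a shared-shape fit is independent of the benchmark response", {
  drs <- read_dose_response(wbc_fixture_path())
  sf <- suppressWarnings(simultaneous_fit(drs, "NIV"))
  r05 <- rpf_at_bmr(sf, 0.05)
  r10 <- rpf_at_bmr(sf, 0.10)
  expect_equal(r05[["T2"]], r10[["T2"]], tolerance = 1e-9)
  expect_equal(r10[["T2"]], sf$rpf$rpf[["T2"]], tolerance = 1e-9)
})

test_that("median BMD recovery error stays moderate at study-scale group sizes", {
  dd <- dose_response_design("A", c(A = 1), sigma_log = 0.15)
  true_bmd <- -log(1 - 0.10 / 0.8) / 0.002
  errs <- sapply(1:50, function(s) {
    dr <- generate_dose_response(dd, s)$A
    fit <- fit_model(dr, "exp3")
    abs(as.numeric(bmd_from_model(fit, 0.10)) / true_bmd - 1)
  })
  expect_lt(median(errs), 0.15)
})

test_that("the reference compound minimises the BMDU/BMDL ratio", {
  tab <- tibble::tibble(compound = c("NIV", "T2HT2"),
                        bmdl = c(750, 4.7), bmdu = c(2700, 22))
  expect_equal(select_reference_compound(tab), "NIV")
  expect_equal(select_reference_compound(tab[1, ]), "NIV")
  tie <- tibble::tibble(compound = c("B", "A"), bmdl = c(1, 2),
                        bmdu = c(3, 6))
  expect_equal(select_reference_compound(tie), "A")
})
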