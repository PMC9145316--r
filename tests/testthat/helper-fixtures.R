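# Shared miniature fixtures, all built in code.

toy_survey <- function() {
  list(
    individuals = tibble::tibble(
      individual_id = "i1", body_weight_kg = 10, age_group = "1-2yr"
    ),
    records = tibble::tibble(
      individual_id = "i1", day = 1:2,
      food_code = c("bread", "bread"), amount_g = c(100, 0)
    )
  )
}

toy_conversion <- function() {
  tibble::tibble(food_code = "bread", sample_code = "s1", proportion = 1)
}

toy_concentrations <- function(value = 50, censored = FALSE,
                               flag = NA_character_, lod = NA_real_,
                               loq = NA_real_) {
  tibble::tibble(
    sample_code = "s1", compound = "X",
    value = if (censored) NA_real_ else value,
    censored = censored, censor_flag = flag, lod = lod, loq = loq
  )
}

# independent lognormal per-compound exposure distributions over shared ids
random_exposures <- function(n = 100, compounds = c("A", "B", "C"),
                             seed = 1, scenario = "UB",
                             meanlog = 0, sdlog = 1, comonotonic = FALSE) {
  withr::with_seed(seed, {
    ids <- sprintf("i%03d", seq_len(n))
    base <- stats::rnorm(n)
    out <- lapply(compounds, function(cp) {
      z <- if (comonotonic) base else stats::rnorm(n)
      structure(
        list(compound = cp, scenario = scenario,
             values = stats::setNames(exp(meanlog + sdlog * z), ids)),
        class = "exposure_dist"
      )
    })
    stats::setNames(out, compounds)
  })
}

wbc_fixture_path <- function() {
  system.file("extdata", "wbc_doseresponse_synthetic.csv",
              package = "tieredmix")
}
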