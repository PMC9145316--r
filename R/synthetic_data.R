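#' Seeded synthetic fixtures with the structure the assessment assumes
#'
#' The generator emulates the data shapes of a total-diet-study based
#' dietary exposure assessment: multi-day consumption diaries with
#' lognormal body weights, food-to-composite-sample conversion, heavily
#' left-censored lognormal concentration data with LOD/LOQ reporting, and
#' continuous dose-response summary datasets with a known potency ratio.
#' All randomness flows from one root seed via named substreams so each
#' component can be regenerated independently.
#'
#' @name synthetic_data
NULL

# deterministic substream seeds below 2^31
.substream <- function(seed, name) {
  offset <- c(survey = 11L, concentration = 23L, doseresponse = 37L,
              fixture = 53L)[[name]]
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

#' Describe a consumption-survey design
#'
#' @param n_individuals Number of individuals.
#' @param n_days Survey days per individual (default 2).
#' @param bw_meanlog,bw_sdlog Lognormal body-weight parameters (kg scale);
#'   defaults approximate toddlers (median ~12 kg).
#' @param age_group Age-group label.
#' @param foods Tibble with `food_code`, `p_consume` (daily consumption
#'   probability), `amount_meanlog`, `amount_sdlog` (lognormal gram
#'   amounts).
#' @return A `survey_design` list.
#' @export
survey_design <- function(n_individuals, n_days = 2,
                          bw_meanlog = log(12), bw_sdlog = 0.15,
                          age_group = "1-2yr",
                          foods = default_foods()) {
  stopifnot(n_individuals >= 0, n_days >= 1,
            all(foods$p_consume >= 0 & foods$p_consume <= 1))
  structure(
    list(n_individuals = n_individuals, n_days = n_days,
         bw_meanlog = bw_meanlog, bw_sdlog = bw_sdlog,
         age_group = age_group, foods = tibble::as_tibble(foods)),
    class = "survey_design"
  )
}

#' Default food list for synthetic surveys
#' @return Tibble of foods with consumption probabilities and lognormal
#'   amount parameters (grams/day).
#' @export
default_foods <- function() {
  tibble::tribble(
    ~food_code, ~p_consume, ~amount_meanlog, ~amount_sdlog,
    "bread",     0.95,       log(80),         0.4,
    "porridge",  0.60,       log(150),        0.5,
    "pasta",     0.35,       log(120),        0.5,
    "biscuits",  0.50,       log(30),         0.6,
    "fruit",     0.90,       log(100),        0.5,
    "juice",     0.55,       log(150),        0.6,
    "potato",    0.45,       log(100),        0.5,
    "dairy",     0.97,       log(300),        0.4
  )
}

#' Generate a seeded synthetic consumption survey
#'
#' @param design A [survey_design()].
#' @param seed Root seed.
#' @return A list with `individuals` (tibble: `individual_id`,
#'   `body_weight_kg`, `age_group`) and `records` (tibble:
#'   `individual_id`, `day`, `food_code`, `amount_g`).
#' @export
generate_survey <- function(design, seed) {
  stopifnot(inherits(design, "survey_design"))
  withr::with_seed(.substream(seed, "survey"), {
    n <- design$n_individuals
    individuals <- tibble::tibble(
      individual_id = sprintf("ind%04d", seq_len(n)),
      body_weight_kg = stats::rlnorm(n, design$bw_meanlog, design$bw_sdlog),
      age_group = design$age_group
    )
    if (n == 0) {
      return(list(
        individuals = individuals,
        records = tibble::tibble(individual_id = character(),
                                 day = integer(), food_code = character(),
                                 amount_g = numeric())
      ))
    }
    grid <- tidyr::expand_grid(
      individual_id = individuals$individual_id,
      day = seq_len(design$n_days),
      design$foods
    )
    eats <- stats::runif(nrow(grid)) < grid$p_consume
    amounts <- stats::rlnorm(nrow(grid), grid$amount_meanlog,
                             grid$amount_sdlog)
    records <- grid[eats, c("individual_id", "day", "food_code")]
    records$amount_g <- amounts[eats]
    list(individuals = individuals, records = records)
  })
}

#' Describe a contamination design for composite samples
#'
#' @param samples Tibble with one row per (sample_code, compound):
#'   `sample_code`, `compound`, `p_occur` (occurrence probability),
#'   `meanlog`, `sdlog` (lognormal concentration, ug/kg), `lod`, `loq`
#'   (ug/kg, `lod <= loq`).
#' @param rank_correlation Optional correlation in (0, 1]: when set, all
#'   compounds within a sample share one latent normal draw scaled by
#'   this weight, producing co-occurring (up to comonotonic) contamination.
#' @return A `contamination_design` list.
#' @export
contamination_design <- function(samples, rank_correlation = NULL) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(samples$p_occur >= 0 & samples$p_occur <= 1),
            all(samples$lod <= samples$loq))
  if (!is.null(rank_correlation)) {
    stopifnot(rank_correlation > 0, rank_correlation <= 1)
  }
  structure(list(samples = samples, rank_correlation = rank_correlation),
            class = "contamination_design")
}

#' Generate seeded synthetic concentration measurements
#'
#' Draws occurrence then a lognormal concentration per (sample, compound).
#' Non-occurring and below-LOD values are emitted as censored `"<LOD"`
#' rows; values between LOD and LOQ as censored `"<LOQ"` rows; quantified
#' values carry their concentration.
#'
#' @param design A [contamination_design()].
#' @param seed Root seed.
#' @return Tibble with `sample_code`, `compound`, `value`, `censored`,
#'   `censor_flag`, `lod`, `loq`.
#' @export
generate_concentrations <- function(design, seed) {
  stopifnot(inherits(design, "contamination_design"))
  withr::with_seed(.substream(seed, "concentration"), {
    s <- design$samples
    m <- nrow(s)
    if (is.null(design$rank_correlation)) {
      z <- stats::rnorm(m)
    } else {
      lat <- stats::setNames(stats::rnorm(length(unique(s$sample_code))),
                             unique(s$sample_code))
      w <- sqrt(design$rank_correlation)
      z <- w * lat[s$sample_code] + sqrt(1 - w^2) * stats::rnorm(m)
    }
    occurs <- stats::runif(m) < s$p_occur
    conc <- exp(s$meanlog + s$sdlog * z)
    conc[!occurs] <- 0
    below_lod <- conc < s$lod
    below_loq <- !below_lod & conc < s$loq
    tibble::tibble(
      sample_code = s$sample_code,
      compound = s$compound,
      value = ifelse(below_lod | below_loq, NA_real_, conc),
      censored = below_lod | below_loq,
      censor_flag = dplyr::case_when(
        below_lod ~ "<LOD",
        below_loq ~ "<LOQ",
        TRUE ~ NA_character_
      ),
      lod = s$lod,
      loq = s$loq
    )
  })
}

#' Describe a dose-response simulation design
#'
#' The first compound follows the stated true curve; each further
#' compound's curve is the reference curve with doses divided by its true
#' relative potency (parallel curves on log-dose), enabling potency
#' recovery tests.
#'
#' @param compounds Character vector of compound ids (first = reference).
#' @param true_rpf Named numeric true RPFs (reference = 1).
#' @param family `"exp3"` or `"hill3"` shape of the true curve.
#' @param a,b,c,d True curve parameters on the reference dose scale
#'   (mean = `a (1 + (c-1) g(b x))`).
#' @param dose_grid Doses tested for the reference compound (other
#'   compounds use `dose_grid / true_rpf`).
#' @param n_per_group Animals per dose group.
#' @param sigma_log Residual log-scale SD of individual responses.
#' @param dispersion_type `"SD"` or `"SEM"` reporting mode.
#' @param direction Adverse direction.
#' @param endpoint Endpoint label.
#' @return A `dr_design` list.
#' @export
dose_response_design <- function(compounds, true_rpf,
                                 family = "exp3", a = 10, b = 0.002,
                                 c = 0.2, d = 1,
                                 dose_grid = c(0, 125, 250, 500, 1000, 2000),
                                 n_per_group = 10, sigma_log = 0.15,
                                 dispersion_type = "SD",
                                 direction = "decrease",
                                 endpoint = "white blood cell count") {
  stopifnot(all(true_rpf > 0), compounds[1] %in% names(true_rpf),
            abs(true_rpf[[compounds[1]]] - 1) < 1e-12)
  structure(
    list(compounds = compounds, true_rpf = true_rpf, family = family,
         a = a, b = b, c = c, d = d, dose_grid = dose_grid,
         n_per_group = n_per_group, sigma_log = sigma_log,
         dispersion_type = dispersion_type, direction = direction,
         endpoint = endpoint),
    class = "dr_design"
  )
}

#' Generate seeded synthetic dose-response summary datasets
#'
#' Individual log responses are normal around the true log-scale curve;
#' group summary statistics are formed from the simulated log-scale sample
#' moments and back-converted to arithmetic mean and SD (or SEM), the form
#' toxicity studies report.
#'
#' @param design A [dose_response_design()].
#' @param seed Root seed.
#' @return Named list of `dr_data` objects, one per compound.
#' @export
generate_dose_response <- function(design, seed) {
  stopifnot(inherits(design, "dr_design"))
  withr::with_seed(.substream(seed, "doseresponse"), {
    out <- lapply(design$compounds, function(cp) {
      rpf <- design$true_rpf[[cp]]
      doses <- design$dose_grid / rpf
      # true log-scale mean at the compound's own doses
      g <- .g_fun(design$b * rpf * doses, design$d, design$family)
      mu <- log(design$a) + log(1 + (design$c - 1) * g)
      n <- design$n_per_group
      ybar <- if (design$sigma_log > 0) {
        stats::rnorm(length(doses), mu, design$sigma_log / sqrt(n))
      } else {
        mu
      }
      s2 <- if (design$sigma_log > 0) {
        design$sigma_log^2 * stats::rchisq(length(doses), n - 1) / (n - 1)
      } else {
        rep(1e-8, length(doses))
      }
      m <- exp(ybar + s2 / 2)
      sd <- m * sqrt(exp(s2) - 1)
      disp <- if (design$dispersion_type == "SEM") sd_to_sem(sd, n) else sd
      dose_response_dataset(
        compound = cp, endpoint = design$endpoint, dose = doses,
        mean = m, dispersion = disp,
        dispersion_type = design$dispersion_type,
        n = rep(n, length(doses)), direction = design$direction
      )
    })
    stats::setNames(out, design$compounds)
  })
}

#' Full synthetic study bundle for the tiered assessment
#'
#' Builds a complete seeded fixture with three assessment groups shaped
#' like the worked mycotoxin assessment — a kidney-like group, a
#' liver-like group and a haematological group with a reduced-white-blood
#' -cell-count phenomenon subgroup — using the built-in reference points
#' and TRVs. Contamination levels are calibrated by design so that the
#' liver-like group's upper-bound P95 combined metric stays below one
#' (assessment stops at the organ tier) while the haematological/WBC
#' group's exceeds one (assessment refines), exercising the full tiered
#' decision flow. A paired dose-response fixture with a true potency
#' ratio of 140 supports the RPF tier.
#'
#' @param seed Root seed.
#' @param n_individuals Survey size (default 300).
#' @param rank_correlation Optional co-occurrence correlation passed to
#'   [contamination_design()].
#' @return A list: `survey`, `conversion`, `concentrations`, `trvs`
#'   (tibble from [derive_trv_table()]), `groups` (named member lists),
#'   `dr_design`, `dose_response` (list of `dr_data`), `seed`.
#' @export
mycotoxin_study_fixture <- function(seed, n_individuals = 300,
                                 rank_correlation = NULL) {
  survey <- generate_survey(survey_design(n_individuals), seed)

  conversion <- tibble::tribble(
    ~food_code, ~sample_code,    ~proportion,
    "bread",    "wheat_comp",    0.7,
    "porridge", "oat_comp",      0.5,
    "porridge", "dairy_comp",    0.4,
    "pasta",    "wheat_comp",    0.8,
    "biscuits", "wheat_comp",    0.5,
    "biscuits", "maize_comp",    0.2,
    "fruit",    "fruit_comp",    1.0,
    "juice",    "fruit_comp",    0.9,
    "potato",   "potato_comp",   1.0,
    "dairy",    "dairy_comp",    1.0
  )

  # per-compound contamination: heavy left-censoring, levels set so that
  # UB P95 risk < 1 for the liver-like group and > 1 for the WBC group
  # (driven by T2/HT2's very low TRV)
  base <- tibble::tribble(
    ~compound, ~p_occur, ~meanlog,   ~sdlog, ~lod,  ~loq,  ~samples,
    "CIT",     0.15,     log(2),     0.8,    1.0,   2.0,   "wheat_comp,oat_comp,maize_comp",
    "OTA",     0.30,     log(0.5),   0.7,    0.1,   0.2,   "wheat_comp,oat_comp,fruit_comp",
    "PAT",     0.20,     log(5),     0.8,    2.0,   4.0,   "fruit_comp",
    "FB1",     0.35,     log(8),     0.9,    2.0,   5.0,   "maize_comp,wheat_comp",
    "FB2",     0.30,     log(4),     0.9,    2.0,   5.0,   "maize_comp,wheat_comp",
    "FB3",     0.25,     log(3),     0.9,    2.0,   5.0,   "maize_comp",
    "ZEN",     0.30,     log(3),     0.8,    0.5,   1.0,   "wheat_comp,maize_comp,oat_comp",
    "DAS",     0.10,     log(1),     0.7,    0.5,   1.0,   "wheat_comp,oat_comp",
    "NIV",     0.40,     log(10),    0.8,    3.0,   6.0,   "wheat_comp,oat_comp",
    "MON",     0.25,     log(5),     0.8,    2.0,   4.0,   "maize_comp,wheat_comp",
    "T2HT2",   0.45,     log(4),     0.9,    1.0,   2.0,   "oat_comp,wheat_comp"
  )
  samples <- base |>
    dplyr::mutate(sample_code = strsplit(.data$samples, ",")) |>
    tidyr::unnest("sample_code") |>
    dplyr::select("sample_code", "compound", "p_occur", "meanlog",
                  "sdlog", "lod", "loq")
  concentrations <- generate_concentrations(
    contamination_design(samples, rank_correlation), seed
  )

  trvs <- derive_trv_table(mycotoxin_reference_points())
  groups <- list(
    kidney = c("CIT", "FB1", "FB2", "FB3", "NIV", "OTA", "PAT"),
    liver = c("FB1", "FB2", "FB3", "ZEN"),
    haematological = c("DAS", "NIV", "MON", "T2HT2"),
    wbc = c("DAS", "NIV", "T2HT2")
  )

  drd <- dose_response_design(
    compounds = c("NIV", "T2HT2"),
    true_rpf = c(NIV = 1, T2HT2 = 140)
  )
  dose_response <- generate_dose_response(drd, seed)

  list(survey = survey, conversion = conversion,
       concentrations = concentrations, trvs = trvs, groups = groups,
       dr_design = drd, dose_response = dose_response, seed = seed)
}
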