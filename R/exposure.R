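#' Resolve a possibly left-censored concentration under a bound scenario
#'
#' Left-censored measurements (below the limit of detection or
#' quantification) are substituted according to the scenario: lower bound
#' (`LB`) replaces them with zero, medium bound (`MB`) with half the limit,
#' upper bound (`UB`) with the full limit. The applicable limit is the LOQ
#' when the record is flagged `"<LOQ"` (detected but not quantified) and
#' the LOD when flagged `"<LOD"`.
#'
#' @param value Measured concentration in ug/kg (`NA` when censored).
#' @param censored Logical, whether the measurement is left-censored.
#' @param censor_flag `"<LOD"` or `"<LOQ"` for censored records, `NA`
#'   otherwise.
#' @param lod,loq Limits of detection/quantification in ug/kg (`NA` when
#'   not recorded).
#' @param scenario One of `"LB"`, `"MB"`, `"UB"`.
#'
#' @return Resolved concentration(s) in ug/kg. Vectorised over rows.
#' @export
resolve_concentration <- function(value, censored, censor_flag, lod, loq,
                                  scenario = c("LB", "MB", "UB")) {
  scenario <- match.arg(scenario)
  censored <- as.logical(censored)
  limit <- ifelse(!is.na(censor_flag) & censor_flag == "<LOQ",
                  ifelse(is.na(loq), lod, loq),
                  ifelse(is.na(lod), loq, lod))
  if (any(censored & is.na(limit))) {
    stop("censored measurement with no LOD or LOQ recorded", call. = FALSE)
  }
  if (any(!censored & (is.na(value) | value < 0))) {
    stop("uncensored measurement must have a non-negative value", call. = FALSE)
  }
  substituted <- switch(scenario,
    LB = 0 * limit,
    MB = limit / 2,
    UB = limit
  )
  ifelse(censored, substituted, value)
}

#' Map a consumed food to contaminated composite samples
#'
#' Total-diet studies analyse composite samples of prepared foods; foods
#' not sampled directly are linked to composites via a conversion table,
#' proportionally to their composition.
#'
#' @param food_code Food code as consumed.
#' @param amount_g Consumed amount in grams.
#' @param conversion A data frame with columns `food_code`, `sample_code`,
#'   `proportion` (each in (0, 1], summing to at most 1 per food).
#'
#' @return A tibble with columns `sample_code` and `amount_g` (the mapped
#'   gram amounts). A food absent from the table maps to zero rows with a
#'   warning; callers can aggregate these into a coverage report.
#' @export
map_food_to_samples <- function(food_code, amount_g, conversion) {
  rows <- conversion[conversion$food_code == food_code, , drop = FALSE]
  if (nrow(rows) == 0L) {
    warning("food '", food_code, "' has no composite-sample mapping; ",
            "contributes zero exposure", call. = FALSE)
    return(tibble::tibble(sample_code = character(), amount_g = numeric()))
  }
  tibble::tibble(
    sample_code = rows$sample_code,
    amount_g = amount_g * rows$proportion
  )
}

#' Observed-individual-mean dietary exposure for one compound
#'
#' Computes each survey individual's mean daily dietary exposure to one
#' compound: consumed amounts are mapped to composite samples via the
#' conversion table, multiplied by the scenario-resolved sample
#' concentration, summed within each individual over all survey days,
#' divided by body weight and averaged over the individual's number of
#' survey days (the observed individual mean, a simple chronic-exposure
#' estimate). Amounts are in g, concentrations in ug/kg, body weights in
#' kg; the result is in ug/kg bw/d.
#'
#' @param survey A list with elements `individuals` (tibble: `individual_id`,
#'   `body_weight_kg`, `age_group`) and `records` (tibble: `individual_id`,
#'   `day`, `food_code`, `amount_g`), as produced by [generate_survey()] or
#'   [read_survey()].
#' @param concentrations Tibble of measurements: `sample_code`, `compound`,
#'   `value`, `censored`, `censor_flag`, `lod`, `loq`.
#' @param conversion Food-to-sample conversion tibble (`food_code`,
#'   `sample_code`, `proportion`).
#' @param scenario `"LB"`, `"MB"` or `"UB"`.
#' @param compound Compound id to assess.
#'
#' @return An `exposure_dist` object: list with `compound`, `scenario` and
#'   `values`, a named numeric vector of per-individual exposures in
#'   ug/kg bw/d (zero for non-consumers), one entry per survey individual.
#' @export
oim_exposure <- function(survey, concentrations, conversion,
                         scenario = c("LB", "MB", "UB"), compound) {
  scenario <- match.arg(scenario)
  ind <- tibble::as_tibble(survey$individuals)
  rec <- tibble::as_tibble(survey$records)
  stopifnot(all(rec$individual_id %in% ind$individual_id),
            all(ind$body_weight_kg > 0))

  days <- rec |>
    dplyr::distinct(.data$individual_id, .data$day) |>
    dplyr::count(.data$individual_id, name = "n_days")
  if (nrow(days) && any(days$n_days < 1)) {
    stop("every individual needs at least one survey day", call. = FALSE)
  }

  conc <- concentrations |>
    dplyr::filter(.data$compound == !!compound) |>
    dplyr::mutate(resolved = resolve_concentration(
      .data$value, .data$censored, .data$censor_flag,
      .data$lod, .data$loq, scenario
    )) |>
    dplyr::select("sample_code", "resolved")

  unmapped <- setdiff(unique(rec$food_code), unique(conversion$food_code))
  if (length(unmapped)) {
    warning("foods without composite-sample mapping (zero contribution): ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }

  # amount [g] x proportion x concentration [ug/kg] x 1e-3 [kg/g] = ug
  contrib <- rec |>
    dplyr::inner_join(conversion, by = "food_code",
                      relationship = "many-to-many") |>
    dplyr::inner_join(conc, by = "sample_code",
                      relationship = "many-to-many") |>
    dplyr::mutate(ug = .data$amount_g * .data$proportion *
             .data$resolved * 1e-3) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(total_ug = sum(.data$ug), .groups = "drop")

  per_ind <- ind |>
    dplyr::left_join(days, by = "individual_id") |>
    dplyr::left_join(contrib, by = "individual_id") |>
    dplyr::mutate(
      total_ug = dplyr::coalesce(.data$total_ug, 0),
      n_days = dplyr::coalesce(.data$n_days, NA_integer_),
      exposure = dplyr::if_else(
        is.na(.data$n_days), 0,
        .data$total_ug / .data$body_weight_kg / .data$n_days
      )
    )

  structure(
    list(
      compound = compound, scenario = scenario,
      values = stats::setNames(per_ind$exposure, per_ind$individual_id)
    ),
    class = "exposure_dist"
  )
}

#' @export
print.exposure_dist <- function(x, ...) {
  cat(sprintf("Exposure distribution: %s [%s], n = %d, median %.4g ug/kg bw/d\n",
              x$compound, x$scenario, length(x$values),
              stats::median(x$values)))
  invisible(x)
}

#' Exposure percentile with bootstrap uncertainty
#'
#' Empirical percentile of a per-individual exposure distribution with a
#' non-parametric bootstrap over individuals: individuals are resampled
#' with replacement `B` times, the percentile is recomputed per replicate,
#' and the median across replicates (the value reported throughout the
#' assessment) plus a central 95% uncertainty interval are returned.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7). Identical seeds give identical output.
#'
#' @param dist An `exposure_dist` or a bare numeric vector of values.
#' @param p Percentile in (0, 100), e.g. 50 or 95.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#'
#' @return A list with `point` (empirical percentile of the observed
#'   distribution), `median_boot` (median across bootstrap replicates),
#'   `ci` (2.5% and 97.5% bootstrap percentiles) and `p`, `B`, `seed`.
#' @export
percentile_with_uncertainty <- function(dist, p, B = 100, seed) {
  values <- if (inherits(dist, "exposure_dist")) dist$values else dist
  if (length(values) == 0L) stop("empty exposure distribution", call. = FALSE)
  if (!is.numeric(p) || p <= 0 || p >= 100) {
    stop("percentile p must lie in (0, 100)", call. = FALSE)
  }
  stopifnot(B >= 1)
  if (missing(seed)) stop("a seed is required", call. = FALSE)

  prob <- p / 100
  n <- length(values)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      stats::quantile(values[sample.int(n, n, replace = TRUE)],
                      probs = prob, names = FALSE, type = 7)
    }, numeric(1))
  })
  list(
    point = stats::quantile(values, probs = prob, names = FALSE, type = 7),
    median_boot = stats::median(boots),
    ci = stats::quantile(boots, probs = c(0.025, 0.975), names = FALSE,
                         type = 7),
    p = p, B = B, seed = as.integer(seed)
  )
}
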