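#' Risk quotients and combined risk metrics
#'
#' A risk quotient divides an exposure percentile by a reference value:
#' the hazard quotient (HQ) uses the compound's health-based guidance
#' value; the reference point quotient (RPQ) uses the group-specific
#' toxicological reference value, restricting the comparison to one target
#' organ or phenomenon. Combined metrics sum quotients across the
#' compounds of an assessment group under the dose-addition assumption.
#'
#' @param compound,group,scenario,percentile Metadata carried on the
#'   quotient.
#' @param exposure Exposure percentile in ug/kg bw/d.
#' @param trv Reference value in ug/kg bw/d.
#' @param flavor `"HQ"` (vs HBGV) or `"RPQ"` (vs group TRV).
#' @return A one-row tibble of class `risk_quotient` columns.
#' @export
risk_quotient <- function(compound, group, scenario, percentile, exposure,
                          trv, flavor = c("RPQ", "HQ")) {
  flavor <- match.arg(flavor)
  stopifnot(trv > 0, exposure >= 0)
  tibble::tibble(
    compound = compound, group = group, scenario = scenario,
    percentile = percentile, quotient = exposure / trv, flavor = flavor
  )
}

.check_same <- function(quotients, what) {
  for (col in what) {
    if (length(unique(quotients[[col]])) > 1L) {
      stop("quotients mix different values of '", col,
           "'; combine one ", col, " at a time", call. = FALSE)
    }
  }
}

#' Hazard index: sum of hazard quotients
#'
#' @param hqs A tibble of quotients (as from [risk_quotient()]) sharing one
#'   percentile and scenario.
#' @return A one-row tibble: `group`, `scenario`, `percentile`, `method`
#'   (`"HI"`), `value`.
#' @export
hazard_index <- function(hqs) {
  .check_same(hqs, c("percentile", "scenario"))
  tibble::tibble(
    group = unique(hqs$group), scenario = unique(hqs$scenario),
    percentile = unique(hqs$percentile), method = "HI",
    value = sum(hqs$quotient), reference_compound = NA_character_
  )
}

#' Modified reference point index by percentile summation
#'
#' Sums the per-compound reference point quotients of an assessment group
#' at one percentile and scenario. Because the compound-wise percentiles
#' are computed marginally, this sum treats all compounds as if the same
#' individuals were the highest exposed to each — an upper-end convention
#' that can overestimate the combined risk at high percentiles relative to
#' individual-level combination.
#'
#' @param rpqs Tibble of RPQs for the group's compounds at one
#'   percentile/scenario.
#' @param expected_members Optional character vector of group members; any
#'   member without an RPQ is reported in the `missing` attribute.
#' @return One-row tibble with `method = "mRPI_sum"`.
#' @export
mrpi_sum <- function(rpqs, expected_members = NULL) {
  .check_same(rpqs, c("percentile", "scenario", "group"))
  out <- tibble::tibble(
    group = unique(rpqs$group), scenario = unique(rpqs$scenario),
    percentile = unique(rpqs$percentile), method = "mRPI_sum",
    value = sum(rpqs$quotient), reference_compound = NA_character_
  )
  if (!is.null(expected_members)) {
    miss <- setdiff(expected_members, rpqs$compound)
    if (length(miss)) {
      warning("group members without an RPQ: ",
              paste(miss, collapse = ", "), call. = FALSE)
      attr(out, "missing") <- miss
    }
  }
  out
}

.align_exposures <- function(exposures) {
  ids <- names(exposures[[1]]$values)
  for (e in exposures) {
    if (!identical(names(e$values), ids)) {
      stop("exposure distributions cover different individuals", call. = FALSE)
    }
  }
  ids
}

#' Individual-level cumulative exposure by reference-value scaling
#'
#' Expresses each compound's per-individual exposure as equivalents of a
#' reference compound using the ratio of toxicological reference values
#' (TRV_ref / TRV_i) and sums within individuals. Dividing the resulting
#' percentiles by TRV_ref yields a combined risk metric that is invariant
#' to the choice of reference compound, because the scaling reduces to
#' summing E_i / TRV_i.
#'
#' @param exposures Named list of `exposure_dist` objects (one per
#'   compound), all over the same individuals.
#' @param trvs Named numeric vector of TRVs covering every compound in
#'   `exposures`.
#' @param reference Reference compound id (must be in `trvs`).
#' @return An `exposure_dist` in reference-compound equivalents, with
#'   attribute fields `reference` and `method = "trv_ratio"`.
#' @export
cumulative_exposure_trv_scaling <- function(exposures, trvs, reference) {
  compounds <- names(exposures)
  missing_trv <- setdiff(c(compounds, reference), names(trvs))
  if (length(missing_trv)) {
    stop("missing TRV for: ", paste(missing_trv, collapse = ", "),
         call. = FALSE)
  }
  ids <- .align_exposures(exposures)
  total <- rep(0, length(ids))
  for (cp in compounds) {
    total <- total + exposures[[cp]]$values * (trvs[[reference]] / trvs[[cp]])
  }
  structure(
    list(
      compound = paste0(reference, "_EQ"),
      scenario = exposures[[1]]$scenario,
      values = stats::setNames(total, ids),
      reference = reference, method = "trv_ratio"
    ),
    class = "exposure_dist"
  )
}

#' Individual-level cumulative exposure using relative potency factors
#'
#' Sums per-individual exposures after scaling each compound by its
#' relative potency factor (RPF) against the reference compound
#' (RPF_reference = 1). Unlike TRV-ratio scaling, the resulting risk
#' metric depends on the chosen reference whenever the TRV ratio differs
#' from the RPF.
#'
#' @param exposures Named list of `exposure_dist` objects.
#' @param rpfs An `rpf_set` from [rpf_set()] (or [simultaneous_fit()]).
#' @return An `exposure_dist` in reference-compound equivalents.
#' @export
combine_with_rpf <- function(exposures, rpfs) {
  stopifnot(inherits(rpfs, "rpf_set"))
  compounds <- names(exposures)
  missing_rpf <- setdiff(compounds, names(rpfs$rpf))
  if (length(missing_rpf)) {
    stop("RPF set does not cover: ", paste(missing_rpf, collapse = ", "),
         call. = FALSE)
  }
  ids <- .align_exposures(exposures)
  total <- rep(0, length(ids))
  for (cp in compounds) {
    total <- total + exposures[[cp]]$values * rpfs$rpf[[cp]]
  }
  structure(
    list(
      compound = paste0(rpfs$reference, "_EQ"),
      scenario = exposures[[1]]$scenario,
      values = stats::setNames(total, ids),
      reference = rpfs$reference, method = "rpf"
    ),
    class = "exposure_dist"
  )
}

#' Construct a relative potency factor set
#'
#' @param reference Reference compound id.
#' @param rpf Named numeric vector of RPFs (> 0). The reference's RPF is
#'   fixed to 1 and added if absent.
#' @return An `rpf_set` object.
#' @export
rpf_set <- function(reference, rpf = numeric()) {
  rpf <- c(rpf)
  if (!reference %in% names(rpf)) rpf[[reference]] <- 1
  if (any(rpf <= 0) || any(!is.finite(rpf))) {
    stop("all RPFs must be positive and finite", call. = FALSE)
  }
  if (abs(rpf[[reference]] - 1) > 1e-12) {
    stop("the RPF of the reference compound must equal 1", call. = FALSE)
  }
  structure(list(reference = reference, rpf = rpf), class = "rpf_set")
}

#' Re-express an RPF set against another reference compound
#'
#' @param rpfs An `rpf_set`.
#' @param new_reference A compound present in the set.
#' @return An `rpf_set` with RPFs divided by the new reference's RPF.
#' @export
rebase_rpf <- function(rpfs, new_reference) {
  stopifnot(inherits(rpfs, "rpf_set"),
            new_reference %in% names(rpfs$rpf))
  rpf_set(new_reference, rpfs$rpf / rpfs$rpf[[new_reference]])
}

#' Risk characterisation of a combined exposure distribution
#'
#' Divides bootstrap-median percentiles of an individual-level combined
#' exposure distribution by the reference compound's TRV.
#'
#' @param combined An `exposure_dist` of reference-compound equivalents.
#' @param trv_ref TRV of the reference compound (ug/kg bw/d, > 0).
#' @param percentiles Percentiles to characterise (default 50 and 95).
#' @param B,seed Bootstrap settings, see [percentile_with_uncertainty()].
#' @return Tibble with one row per percentile: `group` (the combined
#'   label), `scenario`, `percentile`, `method`, `value` (risk metric,
#'   bootstrap-median percentile / TRV_ref), `value_reported` (2
#'   significant figures), `ci_lo`, `ci_hi`, `reference_compound`.
#' @export
risk_characterisation <- function(combined, trv_ref,
                                  percentiles = c(50, 95), B = 100, seed) {
  stopifnot(trv_ref > 0)
  method <- if (identical(combined$method, "rpf")) {
    "RPF_individual"
  } else {
    "mRPI_individual"
  }
  rows <- lapply(percentiles, function(p) {
    pu <- percentile_with_uncertainty(combined, p, B = B, seed = seed)
    tibble::tibble(
      group = combined$compound, scenario = combined$scenario,
      percentile = p, method = method,
      value = pu$median_boot / trv_ref,
      value_reported = signif_report(pu$median_boot / trv_ref),
      ci_lo = pu$ci[1] / trv_ref, ci_hi = pu$ci[2] / trv_ref,
      reference_compound = combined$reference %||% NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

#' Tiered mixture risk assessment decision flow
#'
#' Runs the tiered decision flow over prepared assessment groups: the
#' organ tier is evaluated first; a group proceeds to the phenomenon tier
#' only if any combined metric at any examined percentile/scenario exceeds
#' one; the phenomenon tier proceeds to the RPF tier only where a concern
#' remains and paired dose-response data on a common endpoint exist.
#' Groups flagged for refinement without a phenomenon-level subgroup are
#' reported as "refinement not possible".
#'
#' @param groups A list of group descriptors, each a list with `id`,
#'   `metrics` (tibble of combined metrics with a `value` column, as from
#'   [mrpi_sum()] / [risk_characterisation()]), optional `phenomenon` (a
#'   nested descriptor of the same shape) and optional logical
#'   `has_dose_response_pair` on the phenomenon descriptor.
#' @return A tibble decision trail: `group`, `tier`, `max_metric`,
#'   `proceed`, `note`.
#' @export
tiered_assessment <- function(groups) {
  trail <- list()
  for (g in groups) {
    max_metric <- max(g$metrics$value)
    proceed <- max_metric > 1
    note <- if (!proceed) {
      "no combined metric exceeds 1; no refinement needed"
    } else if (is.null(g$phenomenon)) {
      "refinement not possible: no common phenomenological effect identified"
    } else {
      "combined metric exceeds 1; proceed to phenomenon tier"
    }
    trail[[length(trail) + 1L]] <- tibble::tibble(
      group = g$id, tier = "organ", max_metric = max_metric,
      proceed = proceed && !is.null(g$phenomenon), note = note
    )
    if (proceed && !is.null(g$phenomenon)) {
      ph <- g$phenomenon
      ph_max <- max(ph$metrics$value)
      ph_proceed <- ph_max > 1
      ph_note <- if (!ph_proceed) {
        "no combined metric exceeds 1; no refinement needed"
      } else if (!isTRUE(ph$has_dose_response_pair)) {
        "RPF tier skipped: no paired dose-response data on a common endpoint"
      } else {
        "concern remains; derive relative potency factors"
      }
      trail[[length(trail) + 1L]] <- tibble::tibble(
        group = ph$id, tier = "phenomenon", max_metric = ph_max,
        proceed = ph_proceed && isTRUE(ph$has_dose_response_pair),
        note = ph_note
      )
      if (ph_proceed && isTRUE(ph$has_dose_response_pair)) {
        trail[[length(trail) + 1L]] <- tibble::tibble(
          group = ph$id, tier = "rpf", max_metric = ph_max,
          proceed = FALSE, note = "RPF tier reached"
        )
      }
    }
  }
  dplyr::bind_rows(trail)
}
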