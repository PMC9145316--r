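#' Closed vocabularies for reference-point metadata
#'
#' Reference points are points of departure (NOAEL, LOEL or benchmark-dose
#' lower bounds) from animal or human studies. Their metadata drive the
#' default assessment-factor scheme.
#'
#' @name rp_vocabularies
#' @keywords internal
NULL

.rp_types <- c("NOAEL", "LOEL", "BMDL05", "BMDL10")
.rp_species <- c("rat", "mouse", "pig", "human")
.rp_durations <- c("chronic", "subchronic", "clinical_nonchronic")

#' Compose default assessment factors for a reference point
#'
#' Builds the multiplicative set of assessment factors (AFs) applied when a
#' toxicological reference value is derived from an animal or human study
#' reference point, following EFSA-style default conventions: a factor 10
#' for interspecies differences (omitted for human studies), a factor 10
#' for intraspecies (interindividual) variability, a duration factor (2 for
#' extrapolating a subchronic study to chronic exposure; 10 for a
#' non-chronic human clinical study with an intermittent dosing regimen),
#' and a factor 3 for extrapolating a LOEL to a NOAEL. Additional
#' data-limitation factors (e.g. EFSA's 1.5) can be supplied via
#' `extra_factors`.
#'
#' @param rp_type Reference-point type, one of `"NOAEL"`, `"LOEL"`,
#'   `"BMDL05"`, `"BMDL10"`.
#' @param species Study species, one of `"rat"`, `"mouse"`, `"pig"`,
#'   `"human"`.
#' @param duration_class Study duration class, one of `"chronic"`,
#'   `"subchronic"`, `"clinical_nonchronic"`.
#' @param extra_factors Numeric vector of additional factors, each >= 1.
#'
#' @return An object of class `af_set`: a list with `factors` (a named
#'   numeric vector of the applied factors) and `composed` (their exact
#'   product).
#'
#' @examples
#' compose_assessment_factors("NOAEL", "rat", "subchronic")$composed  # 200
#' compose_assessment_factors("LOEL", "rat", "chronic")$composed      # 300
#' @export
compose_assessment_factors <- function(rp_type, species, duration_class,
                                       extra_factors = numeric()) {
  if (!rp_type %in% .rp_types) {
    stop("unknown rp_type: ", rp_type, call. = FALSE)
  }
  if (!species %in% .rp_species) {
    stop("unknown species: ", species, call. = FALSE)
  }
  if (!duration_class %in% .rp_durations) {
    stop("unknown duration_class: ", duration_class, call. = FALSE)
  }
  if (length(extra_factors) && any(extra_factors < 1)) {
    stop("extra assessment factors must all be >= 1", call. = FALSE)
  }

  factors <- c(
    if (species != "human") c(interspecies = 10),
    c(intraspecies = 10),
    switch(duration_class,
      chronic = NULL,
      subchronic = c(duration = 2),
      clinical_nonchronic = c(duration = 10)
    ),
    if (rp_type == "LOEL") c(loel_to_noael = 3),
    if (length(extra_factors)) {
      stats::setNames(extra_factors, paste0("extra", seq_along(extra_factors)))
    }
  )

  structure(
    list(factors = factors, composed = prod(factors)),
    class = "af_set"
  )
}

#' @export
print.af_set <- function(x, ...) {
  cat("Assessment factors:",
      paste(names(x$factors), x$factors, sep = "=", collapse = " x "),
      "-> composed", x$composed, "\n")
  invisible(x)
}

#' Construct a reference-point record
#'
#' @param compound Compound id (short code, e.g. `"NIV"`).
#' @param group Assessment-group id.
#' @param value Reference point in ug/kg bw/d, > 0.
#' @param rp_type,species,duration_class Closed-vocabulary metadata, see
#'   [compose_assessment_factors()].
#' @param effect Free-text description of the effect.
#' @param is_critical_effect Whether the group's effect is the compound's
#'   critical effect.
#'
#' @return A `reference_point` list.
#' @export
reference_point <- function(compound, group, value, rp_type, species,
                            duration_class, effect = "",
                            is_critical_effect = FALSE) {
  stopifnot(is.numeric(value), length(value) == 1)
  if (!is.finite(value) || value <= 0) {
    stop("reference point value must be positive", call. = FALSE)
  }
  if (!rp_type %in% .rp_types) stop("unknown rp_type: ", rp_type, call. = FALSE)
  if (!species %in% .rp_species) stop("unknown species: ", species, call. = FALSE)
  if (!duration_class %in% .rp_durations) {
    stop("unknown duration_class: ", duration_class, call. = FALSE)
  }
  structure(
    list(
      compound = compound, group = group, value = value, rp_type = rp_type,
      species = species, duration_class = duration_class, effect = effect,
      is_critical_effect = isTRUE(is_critical_effect)
    ),
    class = "reference_point"
  )
}

#' Round to a number of significant figures
#' @keywords internal
signif_report <- function(x, digits = 2) signif(x, digits)

#' Derive a toxicological reference value from a reference point
#'
#' The toxicological reference value (TRV) for a compound in an assessment
#' group is the reference point divided by the composed assessment factors.
#' Internal values keep full precision; the `reported` field rounds to two
#' significant figures for display, matching regulatory practice.
#'
#' @param rp A [reference_point()].
#' @param afs An `af_set` from [compose_assessment_factors()].
#'
#' @return An object of class `trv`: list with `compound`, `group`, `value`
#'   (ug/kg bw/d, full precision), `reported` (2 significant figures),
#'   `source` (`"rp_over_af"`), `rp` and `afs`.
#'
#' @examples
#' rp <- reference_point("CIT", "kidney", 20, "NOAEL", "rat", "subchronic")
#' derive_trv(rp, compose_assessment_factors("NOAEL", "rat", "subchronic"))
#' @export
derive_trv <- function(rp, afs) {
  stopifnot(inherits(rp, "reference_point"), inherits(afs, "af_set"))
  if (afs$composed < 1) stop("composed assessment factor must be >= 1", call. = FALSE)
  value <- rp$value / afs$composed
  structure(
    list(
      compound = rp$compound, group = rp$group, value = value,
      reported = signif_report(value), source = "rp_over_af",
      rp = rp, afs = afs
    ),
    class = "trv"
  )
}

#' Wrap an existing health-based guidance value as a TRV
#'
#' When an assessment group corresponds to a compound's critical effect and
#' a health-based guidance value (HBGV, e.g. a TDI) already exists, that
#' value is used verbatim as the group TRV instead of re-deriving one.
#'
#' @param compound,group Identifiers.
#' @param hbgv The guidance value in ug/kg bw/d.
#' @return A `trv` object with `source = "hbgv"`.
#' @export
trv_from_hbgv <- function(compound, group, hbgv) {
  stopifnot(is.numeric(hbgv), hbgv > 0)
  structure(
    list(
      compound = compound, group = group, value = hbgv,
      reported = signif_report(hbgv), source = "hbgv",
      rp = NULL, afs = NULL
    ),
    class = "trv"
  )
}

#' @export
print.trv <- function(x, ...) {
  cat(sprintf("TRV %s [%s]: %s ug/kg bw/d (%s)\n",
              x$compound, x$group, format(x$reported), x$source))
  invisible(x)
}

#' Build an assessment group from effect-evidence rows
#'
#' Compounds with evidence of an effect on the group's target organ or
#' phenomenon are grouped; genotoxic/carcinogenic compounds are excluded
#' (they require a margin-of-exposure approach, not dose addition), as are
#' compounds for which no reference point could be obtained. Exclusions are
#' recorded with a reason.
#'
#' @param evidence A data frame with columns `compound`,
#'   `has_effect_evidence` (logical), `genotoxic` (logical) and
#'   `has_reference_point` (logical).
#' @param id Group id.
#' @param level `"organ"` or `"phenomenon"`.
#' @param target Free-text target description.
#' @param parent Optional parent organ-level group id (for phenomenon
#'   groups).
#'
#' @return An `assessment_group`: list with `id`, `level`, `target`,
#'   `members` (character), `excluded` (tibble of compound + reason) and
#'   `parent`.
#' @export
build_assessment_group <- function(evidence, id, level = "organ",
                                   target = id, parent = NULL) {
  stopifnot(is.data.frame(evidence))
  needed <- c("compound", "has_effect_evidence", "genotoxic",
              "has_reference_point")
  missing_cols <- setdiff(needed, names(evidence))
  if (length(missing_cols)) {
    stop("evidence table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!level %in% c("organ", "phenomenon")) {
    stop("level must be 'organ' or 'phenomenon'", call. = FALSE)
  }

  ev <- tibble::as_tibble(evidence)
  reason <- dplyr::case_when(
    !ev$has_effect_evidence ~ "no effect evidence for this target",
    ev$genotoxic ~ "carcinogenic/mutagenic; excluded from dose addition",
    !ev$has_reference_point ~ "not possible to obtain/derive a reference point",
    TRUE ~ NA_character_
  )
  members <- sort(ev$compound[is.na(reason)])
  excluded <- tibble::tibble(
    compound = ev$compound[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  if (length(members) == 0L) {
    stop("no compounds qualify for assessment group '", id,
         "': no assessment possible", call. = FALSE)
  }
  structure(
    list(id = id, level = level, target = target, members = members,
         excluded = excluded, parent = parent),
    class = "assessment_group"
  )
}

#' @export
print.assessment_group <- function(x, ...) {
  cat(sprintf("Assessment group '%s' (%s: %s): %s\n", x$id, x$level,
              x$target, paste(x$members, collapse = ", ")))
  if (nrow(x$excluded)) {
    cat("  excluded:", paste(x$excluded$compound, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Derive the TRV table for a set of reference-point records
#'
#' Applies the precedence rule used throughout the assessment: when the
#' group matches the compound's critical effect and an HBGV is recorded,
#' the HBGV is the TRV; otherwise the TRV is derived as RP divided by the
#' composed assessment factors. Read-across rows (e.g. one fumonisin record
#' applied to FB1, FB2 and FB3) are expanded via `applies_to`.
#'
#' @param records A data frame shaped like [mycotoxin_reference_points()]:
#'   columns `compound`, `group`, `rp_value`, `rp_type`, `species`,
#'   `duration_class`, `extra_af`, `is_critical`, `hbgv`, `applies_to`
#'   (comma-separated compound ids covered by the record; defaults to the
#'   record's own compound).
#'
#' @return A tibble with one row per (compound, group): `compound`,
#'   `group`, `trv`, `trv_reported`, `source`, `record_compound`.
#' @export
derive_trv_table <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"applies_to" %in% names(records)) records$applies_to <- NA_character_
  if (!"extra_af" %in% names(records)) records$extra_af <- NA_real_

  rows <- purrr::pmap(records, function(compound, group, rp_value, rp_type,
                                        species, duration_class, extra_af,
                                        is_critical, hbgv, applies_to, ...) {
    if (isTRUE(is_critical) && !is.na(hbgv)) {
      value <- hbgv
      source <- "hbgv"
    } else {
      extra <- if (is.na(extra_af)) numeric() else extra_af
      afs <- compose_assessment_factors(rp_type, species, duration_class, extra)
      rp <- reference_point(compound, group, rp_value, rp_type, species,
                            duration_class, is_critical_effect = is_critical)
      value <- derive_trv(rp, afs)$value
      source <- "rp_over_af"
    }
    targets <- if (is.na(applies_to)) compound else {
      trimws(strsplit(applies_to, ",")[[1]])
    }
    tibble::tibble(
      compound = targets, group = group, trv = value,
      trv_reported = signif_report(value), source = source,
      record_compound = compound
    )
  })
  dplyr::bind_rows(rows)
}

#' Built-in mycotoxin reference points for the worked assessment
#'
#' The reference points, assessment-factor metadata and (where applicable)
#' health-based guidance values for the three worked assessment groups:
#' nephrotoxicity (kidney), liver toxicity and haematological effects, plus
#' the phenomenon-level reduced-white-blood-cell-count subgroup of the
#' haematological group. Values are points of departure identified in EFSA
#' scientific opinions and related regulatory reviews, in ug/kg bw/d.
#'
#' Notes on individual records: the fumonisin records cover FB1-FB3 by
#' read-across (structural similarity and a group HBGV); T2 and HT2 toxin
#' share one record (`T2HT2`) with a group TDI; the nivalenol record in the
#' WBC group omits the additional 1.5 data-limitation factor EFSA used for
#' its TDI, because that factor reflects reproductive/developmental data
#' gaps, not the haematological effect assessed here.
#'
#' @return A tibble, one row per (record, group), with columns `compound`,
#'   `group`, `rp_value`, `rp_type`, `species`, `duration_class`,
#'   `extra_af`, `is_critical`, `hbgv`, `applies_to`.
#' @export
mycotoxin_reference_points <- function() {
  tibble::tribble(
    ~compound, ~group,     ~rp_value, ~rp_type,  ~species, ~duration_class,       ~extra_af, ~is_critical, ~hbgv,  ~applies_to,
    "CIT",     "kidney",       20,    "NOAEL",   "rat",    "subchronic",          NA,        TRUE,         NA,     NA,
    "FB1",     "kidney",      200,    "NOAEL",   "rat",    "chronic",             NA,        FALSE,        2,      "FB1,FB2,FB3",
    "NIV",     "kidney",      660,    "NOAEL",   "mouse",  "chronic",             NA,        FALSE,        NA,     NA,
    "OTA",     "kidney",        4.73, "BMDL10",  "pig",    "subchronic",          NA,        TRUE,         NA,     NA,
    "PAT",     "kidney",      800,    "NOAEL",   "rat",    "subchronic",          NA,        FALSE,        NA,     NA,
    "FB1",     "liver",       100,    "BMDL10",  "mouse",  "chronic",             NA,        TRUE,         1,      "FB1,FB2,FB3",
    "ZEN",     "liver",      1000,    "LOEL",    "rat",    "chronic",             NA,        FALSE,        NA,     NA,
    "DAS",     "haematological", 65,  "NOAEL",   "human",  "clinical_nonchronic", NA,        TRUE,         0.65,   NA,
    "NIV",     "haematological", 350, "BMDL05",  "rat",    "subchronic",          NA,        TRUE,         NA,     NA,
    "MON",     "haematological", 200, "BMDL05",  "pig",    "subchronic",          NA,        TRUE,         1,      NA,
    "T2HT2",   "haematological", 3.33, "BMDL10", "rat",    "subchronic",          NA,        TRUE,         0.02,   NA,
    "DAS",     "wbc",          65,    "NOAEL",   "human",  "clinical_nonchronic", NA,        TRUE,         0.65,   NA,
    "NIV",     "wbc",         350,    "BMDL05",  "rat",    "subchronic",          NA,        TRUE,         NA,     NA,
    "T2HT2",   "wbc",           3.33, "BMDL10",  "rat",    "subchronic",          NA,        TRUE,         0.02,   NA
  )
}
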