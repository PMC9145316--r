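#' tieredmix: tiered mixture risk assessment
#'
#' @importFrom rlang .data %||%
#' @keywords internal
"_PACKAGE"

.read_checked <- function(path, needed, types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         locale = readr::locale(decimal_mark = "."))
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop(basename(path), " lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab
}

.row_errors <- function(tab, checks, path) {
  msgs <- character()
  for (nm in names(checks)) {
    bad <- which(!checks[[nm]])
    if (length(bad)) {
      msgs <- c(msgs, paste0(nm, " (rows ",
                             paste(utils::head(bad, 10), collapse = ", "),
                             if (length(bad) > 10) ", ..." else "", ")"))
    }
  }
  if (length(msgs)) {
    stop("validation of ", basename(path), " failed: ",
         paste(msgs, collapse = "; "), call. = FALSE)
  }
  invisible(tab)
}

#' Read a consumption survey from CSV files
#'
#' @param consumption_path CSV with `individual_id`, `day`, `food_code`,
#'   `amount_g`.
#' @param individuals_path CSV with `individual_id`, `body_weight_kg`,
#'   `age_group`.
#' @return A survey list (`individuals`, `records`) as used by
#'   [oim_exposure()].
#' @export
read_survey <- function(consumption_path, individuals_path) {
  rec <- .read_checked(consumption_path,
                       c("individual_id", "day", "food_code", "amount_g"))
  ind <- .read_checked(individuals_path,
                       c("individual_id", "body_weight_kg", "age_group"))
  .row_errors(ind, list(
    "body weight must be positive" = ind$body_weight_kg > 0,
    "duplicate individual id" = !duplicated(ind$individual_id)
  ), individuals_path)
  .row_errors(rec, list(
    "amount must be non-negative" = rec$amount_g >= 0,
    "unknown individual id" = rec$individual_id %in% ind$individual_id
  ), consumption_path)
  list(individuals = ind, records = rec)
}

#' Read a food-to-composite-sample conversion table
#'
#' @param path CSV with `food_code`, `sample_code`, `proportion`.
#' @return Validated tibble (proportions in (0, 1], summing to <= 1 per
#'   food).
#' @export
read_conversion <- function(path) {
  tab <- .read_checked(path, c("food_code", "sample_code", "proportion"))
  .row_errors(tab, list(
    "proportion must lie in (0, 1]" =
      tab$proportion > 0 & tab$proportion <= 1
  ), path)
  sums <- tapply(tab$proportion, tab$food_code, sum)
  over <- names(sums)[sums > 1 + 1e-9]
  if (length(over)) {
    stop("proportions sum above 1 for foods: ",
         paste(over, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Read per-sample per-compound concentration measurements
#'
#' @param path CSV with `sample_code`, `compound`, `value`, `censored`,
#'   `censor_flag`, `lod`, `loq` (ug/kg).
#' @return Validated tibble.
#' @export
read_concentrations <- function(path) {
  tab <- .read_checked(path, c("sample_code", "compound", "value",
                               "censored", "censor_flag", "lod", "loq"))
  tab$censored <- as.logical(tab$censored)
  .row_errors(tab, list(
    "censored rows need an LOD or LOQ" =
      !tab$censored | !is.na(tab$lod) | !is.na(tab$loq),
    "censored rows must not carry a value" =
      !tab$censored | is.na(tab$value),
    "uncensored rows need a non-negative value" =
      tab$censored | (!is.na(tab$value) & tab$value >= 0),
    "lod must not exceed loq" =
      is.na(tab$lod) | is.na(tab$loq) | tab$lod <= tab$loq
  ), path)
  tab
}

#' Read a reference-point table
#'
#' @param path CSV shaped like [mycotoxin_reference_points()].
#' @return Validated tibble suitable for [derive_trv_table()].
#' @export
read_reference_points <- function(path) {
  tab <- .read_checked(path, c("compound", "group", "rp_value", "rp_type",
                               "species", "duration_class", "extra_af",
                               "is_critical", "hbgv", "applies_to"))
  .row_errors(tab, list(
    "rp_value must be positive" = tab$rp_value > 0,
    "unknown rp_type" = tab$rp_type %in% .rp_types,
    "unknown species" = tab$species %in% .rp_species,
    "unknown duration_class" = tab$duration_class %in% .rp_durations
  ), path)
  tab
}

#' Read continuous dose-response summary data
#'
#' @param path CSV with `compound`, `endpoint`, `dose`, `mean`,
#'   `dispersion`, `dispersion_type`, `n`, `direction`.
#' @return Named list of `dr_data` objects, one per compound.
#' @export
read_dose_response <- function(path) {
  tab <- .read_checked(path, c("compound", "endpoint", "dose", "mean",
                               "dispersion", "dispersion_type", "n",
                               "direction"))
  .row_errors(tab, list(
    "dose must be non-negative" = tab$dose >= 0,
    "mean must be positive" = tab$mean > 0,
    "n must be a positive integer" = tab$n >= 1 & tab$n == round(tab$n),
    "dispersion_type must be SD or SEM" =
      tab$dispersion_type %in% c("SD", "SEM")
  ), path)
  split(tab, tab$compound) |>
    lapply(function(d) {
      dose_response_dataset(
        compound = d$compound[1], endpoint = d$endpoint[1],
        dose = d$dose, mean = d$mean, dispersion = d$dispersion,
        dispersion_type = d$dispersion_type, n = d$n,
        direction = d$direction[1]
      )
    })
}

#' Write a survey bundle to the CSV schemas
#'
#' @param fixture A bundle like [mycotoxin_study_fixture()] output (elements
#'   `survey`, `conversion`, `concentrations`; others ignored).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_study_csvs <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    consumption = file.path(dir, "consumption.csv"),
    individuals = file.path(dir, "individuals.csv"),
    conversion = file.path(dir, "conversion.csv"),
    concentrations = file.path(dir, "concentrations.csv")
  )
  readr::write_csv(fixture$survey$records, paths[["consumption"]])
  readr::write_csv(fixture$survey$individuals, paths[["individuals"]])
  readr::write_csv(fixture$conversion, paths[["conversion"]])
  readr::write_csv(fixture$concentrations, paths[["concentrations"]])
  invisible(paths)
}

#' Write a risk report as CSV, JSON and a readable summary
#'
#' Numbers in the CSV and text summary are shown at two significant
#' figures, the convention of the assessment tables; the JSON retains
#' full precision so that metrics round-trip exactly.
#'
#' @param metrics Tibble of combined metrics (and per-compound quotients),
#'   e.g. rows from [mrpi_sum()] and [risk_characterisation()].
#' @param trail Optional decision trail from [tiered_assessment()].
#' @param dir Output directory.
#' @param name Base file name (default "risk_report").
#' @return Invisibly, the written paths.
#' @export
write_report <- function(metrics, trail = NULL, dir, name = "risk_report") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(dir, paste0(name, ".csv"))
  json_path <- file.path(dir, paste0(name, ".json"))
  txt_path <- file.path(dir, paste0(name, ".txt"))

  disp <- metrics
  if (nrow(disp)) {
    num <- vapply(disp, is.numeric, logical(1)) &
      !names(disp) %in% c("percentile")
    disp[num] <- lapply(disp[num], signif, 2)
  }
  readr::write_csv(disp, csv_path)
  jsonlite::write_json(
    list(metrics = metrics, trail = trail),
    json_path, digits = NA, auto_unbox = TRUE, na = "null"
  )
  lines <- c("Combined risk report", strrep("-", 60))
  if (nrow(metrics)) {
    lines <- c(lines, utils::capture.output(print(as.data.frame(disp))))
  } else {
    lines <- c(lines, "(no metrics)")
  }
  if (!is.null(trail)) {
    lines <- c(lines, "", "Tier decisions:",
               utils::capture.output(print(as.data.frame(trail))))
  }
  writeLines(lines, txt_path)
  invisible(c(csv = csv_path, json = json_path, txt = txt_path))
}

#' Read a risk report back from its JSON form
#' @param path JSON path written by [write_report()].
#' @return List with `metrics` (tibble) and `trail`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$metrics <- tibble::as_tibble(obj$metrics)
  if (!is.null(obj$trail)) obj$trail <- tibble::as_tibble(obj$trail)
  obj
}

#' Write the derived TRV table
#'
#' Emits a table mirroring the hazard-characterisation summaries:
#' reference point, type, species, duration, composed assessment factor
#' and the TRV at two significant figures.
#'
#' @param records Reference-point records ([mycotoxin_reference_points()]
#'   shape).
#' @param path Output CSV path.
#' @return Invisibly, the written tibble.
#' @export
write_trv_table <- function(records, path) {
  trvs <- derive_trv_table(records)
  meta <- tibble::as_tibble(records) |>
    dplyr::select("compound", "group", "rp_value", "rp_type", "species",
                  "duration_class")
  out <- trvs |>
    dplyr::left_join(meta, by = c(record_compound = "compound",
                                  group = "group")) |>
    dplyr::select("compound", "group", "rp_value", "rp_type", "species",
                  "duration_class", "source", "trv", "trv_reported")
  readr::write_csv(out, path)
  invisible(out)
}
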