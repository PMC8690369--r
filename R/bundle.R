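#' Registry bundles
#'
#' A registry bundle is the pipeline's sole input: the four raw event tables
#' of a patient registry plus the study window. Tables and their fixed column
#' schema:
#'
#' * `patients`: `patient_id` (chr), `sex` ("F"/"M"), `birth_date` (Date),
#'   `death_date` (Date, `NA` if alive at extraction)
#' * `hospitalisations`: `patient_id`, `admission_date`, `discharge_date`
#'   (Dates), `diagnosis_code` (chr), `code_system` ("ICD10"/"ICD9")
#' * `outpatient_visits`: `patient_id`, `visit_date` (Date),
#'   `diagnosis_code`, `code_system`
#' * `dispensations`: `patient_id`, `dispense_date` (Date), `atc_code` (chr)
#'
#' All dates are day-precision. A contact with several diagnosis codes is
#' several rows. The same schema is documented in
#' `system.file("extdata", "registry-schema.tsv", package = "relapsetraj")`.
#'
#' @param patients,hospitalisations,outpatient_visits,dispensations Data
#'   frames conforming to the schema above.
#' @param study_start,study_end Dates delimiting the study window.
#' @param validate Run schema validation (default `TRUE`).
#' @return An object of class `registry_bundle`: a list of the four tibbles
#'   plus `study_start` and `study_end`.
#' @export
registry_bundle <- function(patients, hospitalisations, outpatient_visits,
                            dispensations, study_start, study_end,
                            validate = TRUE) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (is.na(study_start) || is.na(study_end) || study_start >= study_end) {
    abort("`study_start` must be a date strictly before `study_end`.")
  }
  bundle <- structure(
    list(
      patients = as_tibble(patients),
      hospitalisations = as_tibble(hospitalisations),
      outpatient_visits = as_tibble(outpatient_visits),
      dispensations = as_tibble(dispensations),
      study_start = study_start,
      study_end = study_end
    ),
    class = "registry_bundle"
  )
  if (validate) validate_bundle(bundle)
  bundle
}

.registry_schema <- list(
  patients = c(patient_id = "character", sex = "character",
               birth_date = "Date", death_date = "Date"),
  hospitalisations = c(patient_id = "character", admission_date = "Date",
                       discharge_date = "Date", diagnosis_code = "character",
                       code_system = "character"),
  outpatient_visits = c(patient_id = "character", visit_date = "Date",
                        diagnosis_code = "character", code_system = "character"),
  dispensations = c(patient_id = "character", dispense_date = "Date",
                    atc_code = "character")
)

#' Validate a registry bundle against the fixed schema
#'
#' Checks column presence and types, date sanity (admission on or before
#' discharge) and known code-system tags. Errors name the offending table,
#' row and column.
#'
#' @param bundle A `registry_bundle`.
#' @return `bundle`, invisibly.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "registry_bundle"))
  for (tab in names(.registry_schema)) {
    df <- bundle[[tab]]
    want <- .registry_schema[[tab]]
    missing <- setdiff(names(want), names(df))
    if (length(missing)) {
      abort(sprintf("table '%s': missing column(s) %s",
                    tab, paste(missing, collapse = ", ")))
    }
    for (col in names(want)) {
      if (want[[col]] == "Date" && !inherits(df[[col]], "Date")) {
        abort(sprintf("table '%s': column '%s' must be a Date", tab, col))
      }
    }
  }
  h <- bundle$hospitalisations
  if (nrow(h)) {
    bad <- which(!is.na(h$admission_date) & !is.na(h$discharge_date) &
                   h$admission_date > h$discharge_date)
    if (length(bad)) {
      abort(sprintf(
        "table 'hospitalisations': row %d: column 'admission_date' after 'discharge_date'",
        bad[1L]))
    }
  }
  for (tab in c("hospitalisations", "outpatient_visits")) {
    df <- bundle[[tab]]
    if (!nrow(df)) next
    sys <- toupper(gsub("[-\\s]", "", df$code_system, perl = TRUE))
    bad <- which(!sys %in% c("ICD10", "ICD9"))
    if (length(bad)) {
      abort(sprintf("table '%s': row %d: column 'code_system': unknown code system '%s'",
                    tab, bad[1L], df$code_system[bad[1L]]))
    }
  }
  invisible(bundle)
}

#' @export
print.registry_bundle <- function(x, ...) {
  cat("<registry_bundle> study window", format(x$study_start), "to",
      format(x$study_end), "\n")
  for (tab in names(.registry_schema)) {
    cat(sprintf("  %-17s %6d rows\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}

#' Write / read a registry bundle as CSV files
#'
#' `write_bundle()` writes the four tables as RFC 4180 CSV files (ISO-8601
#' dates) plus a `study_window.csv` holding the study dates; `read_bundle()`
#' reads them back. The round trip is an identity, including day precision of
#' all dates. Reading validates the schema; an unparseable date or an
#' admission after its discharge is reported with table, row and column.
#'
#' @param bundle A `registry_bundle`.
#' @param path Directory to write to / read from (created if absent).
#' @return `write_bundle()`: `path` invisibly. `read_bundle()`: a
#'   `registry_bundle`.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "registry_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (tab in names(.registry_schema)) {
    readr::write_csv(bundle[[tab]], file.path(path, paste0(tab, ".csv")), na = "")
  }
  readr::write_csv(
    tibble(key = c("study_start", "study_end"),
           value = c(format(bundle$study_start), format(bundle$study_end))),
    file.path(path, "study_window.csv")
  )
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  tabs <- list()
  for (tab in names(.registry_schema)) {
    file <- file.path(path, paste0(tab, ".csv"))
    if (!file.exists(file)) abort(sprintf("table '%s': file not found at %s", tab, file))
    want <- .registry_schema[[tab]]
    df <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_character()),
                          na = "", progress = FALSE)
    missing <- setdiff(names(want), names(df))
    if (length(missing)) {
      abort(sprintf("table '%s': missing column(s) %s",
                    tab, paste(missing, collapse = ", ")))
    }
    for (col in names(want)) {
      if (want[[col]] == "Date") {
        raw <- df[[col]]
        parsed <- as.Date(raw, format = "%Y-%m-%d")
        bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
        if (length(bad)) {
          abort(sprintf("table '%s': row %d: column '%s': unparseable date '%s'",
                        tab, bad[1L], col, raw[bad[1L]]))
        }
        df[[col]] <- parsed
      }
    }
    tabs[[tab]] <- df[names(want)]
  }
  meta <- readr::read_csv(file.path(path, "study_window.csv"),
                          col_types = "cc", progress = FALSE)
  window <- setNames(meta$value, meta$key)
  registry_bundle(tabs$patients, tabs$hospitalisations, tabs$outpatient_visits,
                  tabs$dispensations,
                  study_start = window[["study_start"]],
                  study_end = window[["study_end"]])
}
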