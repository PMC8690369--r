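#' Diagnosis and drug code classifiers
#'
#' Pure, vectorised classifiers for the code ranges that define the study:
#' schizophrenia diagnoses (ICD-10 F20.0--F20.9; ICD-9 295.0--295.9 excluding
#' 295.7, schizoaffective disorder), psychiatric diagnoses (ICD-10 F01--F69 and
#' F90--F98; ICD-9 290--316), and antipsychotic drugs (ATC class N05A).
#'
#' Codes are normalised before matching: case-insensitive, dots and blanks
#' optional, so `"F20.5"`, `"f205"` and `" F20.5 "` are equivalent. Matching
#' works on the root category (first three characters of an ICD-10 code, first
#' three digits of an ICD-9 code) plus the optional decimal subcode. Codes that
#' do not parse under the stated system classify as `FALSE` rather than
#' erroring; registries contain stray local codes and a classifier that aborts
#' on them is unusable.
#'
#' @param code Character vector of diagnosis codes.
#' @param system Character vector (recycled), `"ICD10"` or `"ICD9"`.
#' @return Logical vector the length of `code`.
#' @examples
#' is_schizophrenia_dx(c("F20.5", "F25.1"), "ICD10")
#' is_schizophrenia_dx("295.7", "ICD9") # schizoaffective: excluded
#' is_psychiatric_dx(c("F32.1", "F80.0"), "ICD10")
#' @name code_classifiers
NULL

normalise_code <- function(code) {
  toupper(gsub("[.\\s]", "", as.character(code), perl = TRUE))
}

normalise_code_system <- function(system, n) {
  sys <- toupper(gsub("[-\\s]", "", as.character(system), perl = TRUE))
  if (length(sys) == 1L) sys <- rep(sys, n)
  if (length(sys) != n) {
    abort("`system` must have length 1 or the length of `code`.")
  }
  bad <- !is.na(sys) & !sys %in% c("ICD10", "ICD9")
  if (any(bad)) {
    abort(sprintf("unknown code system: %s", paste(unique(sys[bad]), collapse = ", ")))
  }
  sys
}

icd10_root_num <- function(nc) {
  # numeric part of an F-chapter root, NA when not an F code of >= 3 chars
  ok <- grepl("^F[0-9]{2}([0-9A-Z]{0,2})?$", nc)
  out <- rep(NA_integer_, length(nc))
  out[ok] <- as.integer(substr(nc[ok], 2L, 3L))
  out
}

icd9_root_num <- function(nc) {
  ok <- grepl("^[0-9]{3}[0-9]{0,2}$", nc)
  out <- rep(NA_integer_, length(nc))
  out[ok] <- as.integer(substr(nc[ok], 1L, 3L))
  out
}

#' @rdname code_classifiers
#' @export
is_schizophrenia_dx <- function(code, system) {
  nc <- normalise_code(code)
  sys <- normalise_code_system(system, length(nc))
  out <- logical(length(nc))

  i10 <- sys == "ICD10" & !is.na(nc)
  out[i10] <- grepl("^F20[0-9]?$", nc[i10])

  i9 <- sys == "ICD9" & !is.na(nc)
  # 295.x with optional subcode; 295.7 (any further digits) excluded
  ok9 <- grepl("^295[0-9]{0,2}$", nc[i9]) & substr(nc[i9], 4L, 4L) != "7"
  out[i9] <- ok9

  out[is.na(code)] <- FALSE
  out
}

#' @rdname code_classifiers
#' @export
is_psychiatric_dx <- function(code, system) {
  nc <- normalise_code(code)
  sys <- normalise_code_system(system, length(nc))
  out <- logical(length(nc))

  i10 <- sys == "ICD10" & !is.na(nc)
  r10 <- icd10_root_num(nc[i10])
  out[i10] <- !is.na(r10) & ((r10 >= 1L & r10 <= 69L) | (r10 >= 90L & r10 <= 98L))

  i9 <- sys == "ICD9" & !is.na(nc)
  r9 <- icd9_root_num(nc[i9])
  out[i9] <- !is.na(r9) & r9 >= 290L & r9 <= 316L

  out[is.na(code)] <- FALSE
  out
}

#' @rdname code_classifiers
#' @param atc_code Character vector of ATC codes.
#' @export
is_antipsychotic <- function(atc_code) {
  startsWith(toupper(trimws(as.character(atc_code))), "N05A") & !is.na(atc_code)
}
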