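#' Therapeutic drug classes used by the pipeline
#'
#' The medication rules operate on therapeutic classes, never on raw codes.
#' `drug_classes()` lists all recognised classes; `respiratory_classes()` is
#' the subset whose prescription or dispensation qualifies a patient towards
#' cohort entry (SABA, single-agent LABA, single-agent ICS, fixed-dose
#' ICS+LABA combination, leukotriene receptor antagonists, xanthines).
#'
#' @return character vector of class labels.
#' @export
drug_classes <- function() {
  c("SABA", "LABA_MONO", "ICS_MONO", "FDC_ICS_LABA", "LTRA", "XANTHINE",
    "OCS", "OMALIZUMAB", "TIOTROPIUM", "INDACATEROL", "OTHER")
}

#' @rdname drug_classes
#' @export
respiratory_classes <- function() {
  c("SABA", "LABA_MONO", "ICS_MONO", "FDC_ICS_LABA", "LTRA", "XANTHINE")
}

#' Condition labels recognised in diagnosis / long-term-condition events
#'
#' Six conditions are exclusion-side (COPD, cystic fibrosis, lung cancer,
#' bronchiectasis, tuberculosis, sarcoidosis); asthma is inclusion-side and
#' only consulted in the prescription (UK-like) dialect.
#'
#' @return character vector of condition labels.
#' @export
condition_labels <- function() {
  c("COPD", "CYSTIC_FIBROSIS", "LUNG_CANCER", "BRONCHIECTASIS",
    "TUBERCULOSIS", "SARCOIDOSIS", "ASTHMA", "OTHER")
}

#' @rdname condition_labels
#' @export
exclusion_condition_labels <- function() {
  c("COPD", "CYSTIC_FIBROSIS", "LUNG_CANCER", "BRONCHIECTASIS",
    "TUBERCULOSIS", "SARCOIDOSIS")
}

#' Source dialects
#'
#' The pipeline handles two claims dialects under one schema: a
#' prescription-style source with physician diagnosis codes
#' (`PRESCRIPTION_UK_LIKE`) and a dispensation-style source without
#' diagnoses but with long-term-condition flags and hospital-discharge
#' codes (`DISPENSATION_FR_LIKE`).
#'
#' @return character vector of the two dialect labels.
#' @export
dialects <- function() {
  c("PRESCRIPTION_UK_LIKE", "DISPENSATION_FR_LIKE")
}

validate_terminology <- function(term, label_col, labels, path = "<in memory>") {
  required <- c("code", "dialect", label_col, "human_name")
  missing <- setdiff(required, names(term))
  if (length(missing) > 0) {
    abort(sprintf("terminology '%s' is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  bad_lab <- setdiff(unique(term[[label_col]]), labels)
  if (length(bad_lab) > 0) {
    abort(sprintf("terminology '%s' has unknown %s value(s): %s",
                  path, label_col, paste(bad_lab, collapse = ", ")))
  }
  bad_dia <- setdiff(unique(term$dialect), dialects())
  if (length(bad_dia) > 0) {
    abort(sprintf("terminology '%s' has unknown dialect value(s): %s",
                  path, paste(bad_dia, collapse = ", ")))
  }
  # a code may be listed twice only if every listing agrees on the class
  conflicts <- term %>%
    distinct(.data$code, .data$dialect, .data[[label_col]]) %>%
    dplyr::count(.data$code, .data$dialect) %>%
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(sprintf(
      "terminology '%s' maps code(s) to more than one class: %s",
      path, paste(unique(conflicts$code), collapse = ", ")))
  }
  distinct(term, .data$code, .data$dialect, .keep_all = TRUE)
}

#' Load a drug terminology file
#'
#' A terminology is a CSV with columns `code, dialect, class_label,
#' human_name` mapping opaque drug codes (ATC-like or Read-like strings; the
#' pipeline never parses code internals) to therapeutic classes. Loading
#' fails if a code is mapped to two different classes within one dialect.
#'
#' @param path CSV file path.
#' @return a tibble with one row per (code, dialect).
#' @seealso [default_terminology()], [classify_drug()]
#' @export
load_terminology <- function(path) {
  term <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_terminology(term, "class_label", drug_classes(), path)
}

#' Write a terminology table back to CSV
#'
#' @param terminology a drug or condition terminology tibble.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_terminology <- function(terminology, path) {
  readr::write_csv(terminology, path)
  invisible(path)
}

#' Built-in miniature terminologies
#'
#' The package ships a small drug and condition terminology per dialect, with
#' at least two codes per class so synthetic data exercises the many-to-one
#' code-to-class mapping. These are deliberately miniature registries, not
#' reproductions of real ATC or Read dictionaries.
#'
#' @param dialect one of [dialects()], or `NULL` for both.
#' @return a terminology tibble.
#' @export
default_terminology <- function(dialect = NULL) {
  path <- system.file("extdata", "drug_terminology.csv", package = "asthmaclaims")
  term <- load_terminology(path)
  if (!is.null(dialect)) {
    dialect <- match.arg(dialect, dialects())
    term <- filter(term, .data$dialect == !!dialect)
  }
  term
}

#' @rdname default_terminology
#' @export
default_condition_codes <- function(dialect = NULL) {
  path <- system.file("extdata", "condition_terminology.csv", package = "asthmaclaims")
  term <- load_condition_codes(path)
  if (!is.null(dialect)) {
    dialect <- match.arg(dialect, dialects())
    term <- filter(term, .data$dialect == !!dialect)
  }
  term
}

#' Load a condition-code table
#'
#' CSV with columns `code, dialect, condition_label, human_name` mapping
#' diagnosis / long-term-condition / hospital-discharge codes to condition
#' labels.
#'
#' @param path CSV file path.
#' @return a tibble with one row per (code, dialect).
#' @export
load_condition_codes <- function(path) {
  term <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_terminology(term, "condition_label", condition_labels(), path)
}

#' Map drug codes to therapeutic classes
#'
#' Total function: every code yields exactly one class. Codes absent from the
#' terminology map to `OTHER`; each distinct unmapped code is reported once
#' per call via a condition of class `asthmaclaims_unmapped_code` (silence
#' with `suppressMessages()`).
#'
#' @param code character vector of drug codes.
#' @param terminology a drug terminology tibble (see [load_terminology()]).
#' @return character vector of class labels, same length as `code`.
#' @export
classify_drug <- function(code, terminology) {
  map <- setNames(terminology$class_label, terminology$code)
  cls <- unname(map[code])
  unmapped <- unique(code[is.na(cls)])
  if (length(unmapped) > 0) {
    inform(sprintf("unmapped drug code(s) treated as OTHER: %s",
                   paste(unmapped, collapse = ", ")),
           class = "asthmaclaims_unmapped_code")
  }
  cls[is.na(cls)] <- "OTHER"
  cls
}

#' @rdname classify_drug
#' @param condition_codes a condition-code tibble (see [load_condition_codes()]).
#' @export
classify_condition <- function(code, condition_codes) {
  map <- setNames(condition_codes$condition_label, condition_codes$code)
  cls <- unname(map[code])
  unmapped <- unique(code[is.na(cls)])
  if (length(unmapped) > 0) {
    inform(sprintf("unmapped condition code(s) treated as OTHER: %s",
                   paste(unmapped, collapse = ", ")),
           class = "asthmaclaims_unmapped_code")
  }
  cls[is.na(cls)] <- "OTHER"
  cls
}

#' Is a drug class cohort-qualifying ("respiratory")?
#'
#' Cohort entry requires three distinct dates bearing a qualifying
#' respiratory-drug event. Oral corticosteroids, omalizumab, tiotropium and
#' indacaterol are *not* qualifying even though they act on the airways: the
#' first marks severity, the last three are exclusion drugs.
#'
#' @param class character vector of class labels.
#' @return logical vector.
#' @export
is_respiratory <- function(class) {
  class %in% respiratory_classes()
}
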