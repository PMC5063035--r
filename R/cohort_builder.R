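#' Cohort construction configuration
#'
#' @param dialect one of [dialects()].
#' @param cohort_year calendar year in which the three qualifying
#'   respiratory-drug dates must fall.
#' @param data_end_date last date covered by the database extract; patients
#'   whose entry date is not followed by 12 full months of data coverage are
#'   excluded. `NULL` (default) uses the latest event date seen.
#' @param ocs_min_prescriptions_uk minimum number of oral-corticosteroid
#'   prescriptions for the chronic-OCS exclusion in the prescription
#'   dialect. The printed rule ">4 prescriptions ... at >=4 different dates"
#'   is read strictly, so the default is 5; set 4 for the inclusive reading.
#' @param require_asthma_diagnosis require at least one asthma diagnosis
#'   code on or before the entry date. Defaults to `TRUE` for the
#'   prescription (UK-like) dialect and is forced `FALSE` for the
#'   dispensation dialect, which carries no diagnoses.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(dialect, cohort_year, data_end_date = NULL,
                          ocs_min_prescriptions_uk = 5,
                          require_asthma_diagnosis = NULL) {
  dialect <- match.arg(dialect, dialects())
  stopifnot(is.numeric(cohort_year), cohort_year == as.integer(cohort_year))
  if (!is.null(data_end_date)) data_end_date <- as.Date(data_end_date)
  if (is.null(require_asthma_diagnosis)) {
    require_asthma_diagnosis <- dialect == "PRESCRIPTION_UK_LIKE"
  }
  if (dialect == "DISPENSATION_FR_LIKE") require_asthma_diagnosis <- FALSE
  structure(list(dialect = dialect,
                 cohort_year = as.integer(cohort_year),
                 data_end_date = data_end_date,
                 ocs_min_prescriptions_uk = ocs_min_prescriptions_uk,
                 require_asthma_diagnosis = require_asthma_diagnosis),
            class = "cohort_config")
}

#' Exclusion outcomes, in evaluation order
#'
#' One outcome is reported per candidate; rules are evaluated in this fixed
#' order and the first failure wins, so reason attribution is reproducible.
#' `NO_ASTHMA_DIAGNOSIS` applies only when the configuration requires an
#' asthma diagnosis (prescription dialect).
#'
#' @return character vector of outcome labels, evaluation order, with
#'   `INCLUDED` last.
#' @export
exclusion_outcomes <- function() {
  c("NOT_ENOUGH_EVENTS", "NO_ASTHMA_DIAGNOSIS", "AGE_OUT_OF_RANGE",
    "OMALIZUMAB", "CHRONIC_OCS", "COPD_OR_COPD_DRUG", "CF", "LUNG_CANCER",
    "BRONCHIECTASIS", "TB", "SARCOIDOSIS", "INSUFFICIENT_FOLLOWUP",
    "INCLUDED")
}

# condition label -> outcome label for the five non-COPD conditions
condition_outcome_map <- c(
  CYSTIC_FIBROSIS = "CF", LUNG_CANCER = "LUNG_CANCER",
  BRONCHIECTASIS = "BRONCHIECTASIS", TUBERCULOSIS = "TB",
  SARCOIDOSIS = "SARCOIDOSIS")

# core: third distinct calendar date within `year` bearing >=1 qualifying
# respiratory event; multiple events on one date count once
find_entry_date_core <- function(dates, classes, year) {
  keep <- is_respiratory(classes) & year(dates) == year
  d <- sort(unique(dates[keep]))
  if (length(d) < 3) as.Date(NA) else d[3]
}

#' Entry date: third distinct respiratory-drug date in the cohort year
#'
#' Cohort entry is anchored at the date of the third prescription or
#' dispensation of a qualifying respiratory drug within the cohort year,
#' counting distinct calendar dates (several qualifying events on one day
#' count as one date). Returns `NA` when fewer than three such dates exist.
#'
#' @param events one patient's medication events: a data frame with columns
#'   `date` and `drug_code`.
#' @param terminology drug terminology tibble.
#' @param year cohort year.
#' @return a `Date` (possibly `NA`).
#' @export
find_entry_date <- function(events, terminology, year) {
  if (nrow(events) == 0) return(as.Date(NA))
  find_entry_date_core(as.Date(events$date),
                       classify_drug(events$drug_code, terminology),
                       year)
}

#' Chronic oral-corticosteroid use in the lookback window
#'
#' Dialect-specific severity marker. Prescription (UK-like) dialect: at
#' least `min_prescriptions_uk` OCS prescription events falling on at least
#' 4 distinct dates. Dispensation (FR-like) dialect: at least 4 distinct OCS
#' dispensation dates spanning at least 2 distinct civil calendar quarters
#' (Jan-Mar, Apr-Jun, Jul-Sep, Oct-Dec).
#'
#' @param ocs_dates `Date` vector of the patient's OCS events already
#'   restricted to the 12-month lookback window; one element per event, so
#'   repeated prescriptions on one date appear repeatedly.
#' @param dialect one of [dialects()].
#' @param min_prescriptions_uk see [cohort_config()].
#' @return logical flag.
#' @export
chronic_ocs_flag <- function(ocs_dates, dialect, min_prescriptions_uk = 5) {
  dialect <- match.arg(dialect, dialects())
  ocs_dates <- as.Date(ocs_dates)
  n_dates <- length(unique(ocs_dates))
  if (dialect == "PRESCRIPTION_UK_LIKE") {
    length(ocs_dates) >= min_prescriptions_uk && n_dates >= 4
  } else {
    n_dates >= 4 && length(unique(quarter_index(unique(ocs_dates)))) >= 2
  }
}

#' Evaluate the exclusion cascade for one candidate
#'
#' Rules are evaluated in the order of [exclusion_outcomes()]: age band at
#' entry (6-40 completed years); any omalizumab event in the lookback;
#' chronic OCS (dialect-specific, see [chronic_ocs_flag()]); COPD, meaning a
#' COPD condition code in the lookback or any tiotropium/indacaterol event
#' without any ICS-containing (single ICS or fixed-dose combination) event
#' in the lookback; the five remaining exclusion conditions; and finally
#' data coverage (`data_end_date >= entry + 12 months`). All exclusion
#' windows are the half-open lookback `[entry - 12 months, entry)`; the
#' entry date itself belongs to follow-up.
#'
#' @param entry_date the candidate's entry date (not `NA`).
#' @param birth_date the candidate's birth date.
#' @param med_dates,med_classes the candidate's medication event dates and
#'   therapeutic classes (parallel vectors).
#' @param dx_dates,dx_conditions the candidate's diagnosis/LTC event dates
#'   and condition labels (parallel vectors).
#' @param data_end_date last covered date of the extract.
#' @param config a [cohort_config()].
#' @return list with `outcome` (one of [exclusion_outcomes()]),
#'   `age_at_entry`, `age_group` (`NA` unless age is in band).
#' @export
apply_exclusions <- function(entry_date, birth_date, med_dates, med_classes,
                             dx_dates, dx_conditions, data_end_date, config) {
  if (is.na(entry_date)) {
    abort("apply_exclusions() requires a non-missing entry date")
  }
  age <- age_at(birth_date, entry_date)
  age_group <- if (age >= 6 && age <= 13) "CHILD_6_13"
               else if (age >= 14 && age <= 40) "ADULT_14_40"
               else NA_character_
  done <- function(outcome) list(outcome = outcome, age_at_entry = age,
                                 age_group = age_group)

  if (age < 6 || age > 40) return(done("AGE_OUT_OF_RANGE"))

  lb_start <- add_months(entry_date, -12)
  in_lb <- med_dates >= lb_start & med_dates < entry_date
  lb_classes <- med_classes[in_lb]
  lb_dates <- med_dates[in_lb]

  if (any(lb_classes == "OMALIZUMAB")) return(done("OMALIZUMAB"))

  if (chronic_ocs_flag(lb_dates[lb_classes == "OCS"], config$dialect,
                       config$ocs_min_prescriptions_uk)) {
    return(done("CHRONIC_OCS"))
  }

  dx_in_lb <- dx_dates >= lb_start & dx_dates < entry_date
  lb_conditions <- dx_conditions[dx_in_lb]

  copd_dx <- any(lb_conditions == "COPD")
  copd_drug <- any(lb_classes %in% c("TIOTROPIUM", "INDACATEROL")) &&
    !any(lb_classes %in% c("ICS_MONO", "FDC_ICS_LABA"))
  if (copd_dx || copd_drug) return(done("COPD_OR_COPD_DRUG"))

  for (cond in names(condition_outcome_map)) {
    if (any(lb_conditions == cond)) {
      return(done(condition_outcome_map[[cond]]))
    }
  }

  if (data_end_date < add_months(entry_date, 12)) {
    return(done("INSUFFICIENT_FOLLOWUP"))
  }
  done("INCLUDED")
}

validate_claims_tables <- function(patients, med_events, dx_events) {
  need <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0) {
      abort(sprintf("%s table is missing column(s): %s", what,
                    paste(missing, collapse = ", ")))
    }
  }
  need(patients, c("patient_id", "birth_date", "sex"), "patients")
  need(med_events, c("patient_id", "date", "drug_code", "packs"), "med_events")
  need(dx_events, c("patient_id", "date", "condition_code", "source_kind"), "dx_events")
  bad <- which(!is.finite(med_events$packs) | med_events$packs < 0)
  if (length(bad) > 0) {
    abort(sprintf("med_events has negative or missing pack counts at row(s): %s",
                  paste(head(bad, 20), collapse = ", ")))
  }
  orphans <- setdiff(unique(med_events$patient_id), patients$patient_id)
  if (length(orphans) > 0) {
    abort(sprintf("med_events reference unknown patient_id(s): %s",
                  paste(head(orphans, 20), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Build the asthma cohort from claims tables
#'
#' Applies the full inclusion/exclusion algorithm: entry at the third
#' distinct respiratory-drug date within the cohort year; in the
#' prescription dialect, an asthma diagnosis code on or before entry; then
#' the exclusion cascade of [apply_exclusions()]. Every candidate receives
#' exactly one outcome.
#'
#' @param patients tibble with `patient_id, birth_date, sex` (and optionally
#'   `dialect`).
#' @param med_events tibble with `patient_id, date, drug_code, packs`.
#' @param dx_events tibble with `patient_id, date, condition_code,
#'   source_kind`.
#' @param config a [cohort_config()].
#' @param terminology drug terminology; defaults to the built-in one for the
#'   configured dialect.
#' @param condition_codes condition-code table; same default rule.
#' @return list with
#'   * `cohort`: one row per included member — `patient_id, sex, entry_date,
#'     age_at_entry, age_group, lookback_start, followup_end` (windows are
#'     `[lookback_start, entry_date)` and `[entry_date, followup_end)`);
#'   * `exclusions`: one row per candidate — `patient_id, outcome`;
#'   * `baseline`: the baseline characteristics table, see
#'     [baseline_table()].
#' @export
build_cohort <- function(patients, med_events, dx_events, config,
                         terminology = default_terminology(config$dialect),
                         condition_codes = default_condition_codes(config$dialect)) {
  stopifnot(inherits(config, "cohort_config"))
  patients <- mutate(as_tibble(patients), birth_date = as.Date(.data$birth_date))
  med_events <- mutate(as_tibble(med_events), date = as.Date(.data$date))
  dx_events <- mutate(as_tibble(dx_events), date = as.Date(.data$date))
  validate_claims_tables(patients, med_events, dx_events)

  data_end <- config$data_end_date
  if (is.null(data_end)) {
    data_end <- suppressWarnings(max(c(med_events$date, dx_events$date)))
    if (!is.finite(data_end)) data_end <- as.Date(sprintf("%d-12-31", config$cohort_year))
  }

  med_events$class <- classify_drug(med_events$drug_code, terminology)
  dx_events$condition <- classify_condition(dx_events$condition_code, condition_codes)

  ids <- patients$patient_id
  pf <- factor(ids, levels = ids)
  med_by <- split(med_events[c("date", "class")],
                  factor(med_events$patient_id, levels = ids))
  dx_by <- split(dx_events[c("date", "condition")],
                 factor(dx_events$patient_id, levels = ids))

  n <- length(ids)
  outcome <- character(n)
  entry <- rep(as.Date(NA), n)
  age <- rep(NA_integer_, n)
  age_group <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    me <- med_by[[i]]
    dx <- dx_by[[i]]
    e <- find_entry_date_core(me$date, me$class, config$cohort_year)
    entry[i] <- e
    if (is.na(e)) {
      outcome[i] <- "NOT_ENOUGH_EVENTS"
      next
    }
    if (config$require_asthma_diagnosis &&
        !any(dx$condition == "ASTHMA" & dx$date <= e)) {
      outcome[i] <- "NO_ASTHMA_DIAGNOSIS"
      next
    }
    res <- apply_exclusions(e, patients$birth_date[i], me$date, me$class,
                            dx$date, dx$condition, data_end, config)
    outcome[i] <- res$outcome
    age[i] <- res$age_at_entry
    age_group[i] <- res$age_group
  }

  exclusions <- tibble(patient_id = ids, outcome = outcome)
  keep <- outcome == "INCLUDED"
  cohort <- tibble(
    patient_id = ids[keep],
    sex = patients$sex[keep],
    entry_date = entry[keep],
    age_at_entry = age[keep],
    age_group = age_group[keep],
    lookback_start = add_months(entry[keep], -12),
    followup_end = add_months(entry[keep], 12))

  list(cohort = cohort, exclusions = exclusions,
       baseline = baseline_table(cohort))
}

#' Baseline characteristics table
#'
#' Reports cohort size, mean age with standard deviation, and counts with
#' percentages by age group and sex, in the layout of a standard cohort
#' Table 1. Percentages are rounded half-up to one decimal. An empty cohort
#' yields a table with `n = 0` and missing percentages.
#'
#' @param cohort the `cohort` tibble from [build_cohort()].
#' @return a tibble with columns `characteristic, value, percent`.
#' @export
baseline_table <- function(cohort) {
  n <- nrow(cohort)
  age_stats <- summarize_values(cohort$age_at_entry)
  n_child <- sum(cohort$age_group == "CHILD_6_13")
  n_adult <- sum(cohort$age_group == "ADULT_14_40")
  n_male <- sum(cohort$sex == "M")
  tibble(
    characteristic = c("n", "age_mean", "age_sd", "children_6_13",
                       "adults_14_40", "males"),
    value = c(n, age_stats$mean, age_stats$sd, n_child, n_adult, n_male),
    percent = c(NA, NA, NA,
                percent_of(n_child, n), percent_of(n_adult, n),
                percent_of(n_male, n)))
}
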