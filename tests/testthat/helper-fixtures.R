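# Fixture builders used across test files.

# one patient's medication events from compact vectors
med_tbl <- function(dates, codes, packs = 1, pid = "P1") {
  tibble::tibble(patient_id = pid, date = as.Date(dates),
                 drug_code = codes, packs = rep_len(packs, length(dates)))
}

dx_tbl <- function(dates = character(), codes = character(),
                   source = "DIAGNOSIS", pid = "P1") {
  tibble::tibble(patient_id = rep_len(pid, length(dates)),
                 date = as.Date(dates), condition_code = codes,
                 source_kind = rep_len(source, length(dates)))
}

pat_tbl <- function(birth, sex = "M", pid = "P1") {
  tibble::tibble(patient_id = pid, birth_date = as.Date(birth), sex = sex)
}

# a unit-counts row for the flag functions
counts_row <- function(saba = 0, laba = 0, ics = 0, fdc = 0, ltra = 0, xan = 0) {
  tibble::tibble(saba_units = saba, laba_mono_units = laba,
                 ics_mono_units = ics, fdc_units = fdc,
                 ltra_units = ltra, xanthine_units = xan)
}

# a random micro-database for small-instance oracle checks: unconstrained
# event soup over a window spanning the cohort year, so every rule branch
# (entry finding, lookback windows, quarter spans, rule ordering) gets hit
random_micro_db <- function(n_patients, dialect, year = 2013) {
  term <- asthmaclaims::default_terminology(dialect)
  cond <- asthmaclaims::default_condition_codes(dialect)
  all_days <- seq(as.Date(sprintf("%d-06-01", year - 1)),
                  as.Date(sprintf("%d-06-30", year + 1)), by = "day")
  births <- seq(as.Date(sprintf("%d-01-01", year - 45)),
                as.Date(sprintf("%d-12-31", year - 3)), by = "day")
  # respiratory-heavy code pool so entries happen often; OCS inflated so the
  # distinct-date and quarter-span branches of the chronic-OCS rule get hit
  pool <- c(term$code, rep(term$code[term$class_label %in%
                                       c("SABA", "ICS_MONO", "LTRA")], 4),
            rep(term$code[term$class_label == "OCS"], 6), "ZZ-unmapped")
  patients <- tibble::tibble(
    patient_id = sprintf("M%03d", seq_len(n_patients)),
    birth_date = sample(births, n_patients, replace = TRUE),
    sex = sample(c("M", "F"), n_patients, replace = TRUE))
  med <- lapply(patients$patient_id, function(pid) {
    k <- stats::rpois(1, 8)
    if (k == 0) return(NULL)
    tibble::tibble(patient_id = pid,
                   date = sample(all_days, k, replace = TRUE),
                   drug_code = sample(pool, k, replace = TRUE),
                   packs = sample(1:3, k, replace = TRUE))
  })
  dx <- lapply(patients$patient_id, function(pid) {
    k <- stats::rpois(1, 1.2)
    # frequent asthma codes so the prescription dialect's inclusion rule
    # passes often enough for later rules to be reached
    codes <- c(rep(cond$code[cond$condition_label == "ASTHMA"], 6), cond$code)
    if (k == 0) return(NULL)
    tibble::tibble(patient_id = pid,
                   date = sample(all_days, k, replace = TRUE),
                   condition_code = sample(codes, k, replace = TRUE),
                   source_kind = "DIAGNOSIS")
  })
  empty_dx <- tibble::tibble(patient_id = character(),
                             date = as.Date(character()),
                             condition_code = character(),
                             source_kind = character())
  empty_med <- tibble::tibble(patient_id = character(),
                              date = as.Date(character()),
                              drug_code = character(), packs = numeric())
  list(patients = patients,
       med_events = dplyr::bind_rows(c(list(empty_med), med)),
       dx_events = dplyr::bind_rows(c(list(empty_dx), dx)),
       data_end = sample(seq(as.Date(sprintf("%d-10-01", year)),
                             as.Date(sprintf("%d-12-31", year + 1)),
                             by = "day"), 1))
}
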