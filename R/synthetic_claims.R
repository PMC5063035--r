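#' Simulation configuration for the synthetic claims generator
#'
#' Defines a synthetic two-dialect claims database with known, planted
#' prevalences of the three inappropriate-therapy patterns and of every
#' exclusion channel. Planting is constructive: events are written so that a
#' patient satisfies or violates the cohort rules by construction, which
#' makes downstream cohort tests exact rather than statistical.
#'
#' @param seed integer RNG seed; the same seed and configuration produce
#'   byte-identical output tables.
#' @param n_patients number of patients to generate.
#' @param dialect one of [dialects()].
#' @param cohort_year calendar year anchoring cohort entry.
#' @param age_weights non-negative weights over integer ages 0-60 (length
#'   61); ages are integers at the start of the cohort year and birth dates
#'   are back-computed. Default weights put roughly 27% of the 6-40 band in
#'   the 6-13 child stratum.
#' @param sex_ratio proportion male in \[0, 1\].
#' @param planted_prevalence named list with `saba_overuse`, `laba_no_ics`,
#'   `laba_unbalanced`, each in \[0, 1\]; the two LABA patterns are mutually
#'   exclusive assignments so their sum must be <= 1.
#' @param exclusion_rates named list of per-channel probabilities (see
#'   [default_exclusion_rates()]); their sum must be < 1 and the remainder
#'   is the eligible fraction. `no_asthma_diagnosis` is only meaningful in
#'   the prescription dialect and must be 0 for the dispensation dialect.
#' @param events_per_patient_year Poisson rate of background (class
#'   `OTHER`) events per patient.
#' @param pack_weights sampling weights over pack counts 1, 2, 3.
#' @param data_end_date last covered date of the synthetic extract; default
#'   30 June of `cohort_year + 1`, so a late-entry insufficient-follow-up
#'   channel exists.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 2000L,
                       dialect = "PRESCRIPTION_UK_LIKE",
                       cohort_year = 2013L,
                       age_weights = default_age_weights(),
                       sex_ratio = 0.52,
                       planted_prevalence = list(saba_overuse = 0.085,
                                                 laba_no_ics = 0.003,
                                                 laba_unbalanced = 0.004),
                       exclusion_rates = default_exclusion_rates(dialect),
                       events_per_patient_year = 2,
                       pack_weights = c(0.7, 0.2, 0.1),
                       data_end_date = NULL) {
  dialect <- match.arg(dialect, dialects())
  stopifnot(is.numeric(seed), length(seed) == 1,
            is.numeric(n_patients), n_patients >= 0,
            is.numeric(cohort_year),
            length(age_weights) == 61, all(age_weights >= 0),
            sum(age_weights[7:41]) > 0,
            sex_ratio >= 0, sex_ratio <= 1,
            length(pack_weights) == 3, all(pack_weights >= 0),
            sum(pack_weights) > 0,
            events_per_patient_year >= 0)

  pp <- planted_prevalence
  need_pp <- setdiff(c("saba_overuse", "laba_no_ics", "laba_unbalanced"), names(pp))
  if (length(need_pp) > 0) {
    abort(sprintf("planted_prevalence missing: %s", paste(need_pp, collapse = ", ")))
  }
  ppv <- unlist(pp[c("saba_overuse", "laba_no_ics", "laba_unbalanced")])
  if (any(ppv < 0 | ppv > 1)) {
    abort("planted_prevalence values must lie in [0, 1]")
  }
  if (pp$laba_no_ics + pp$laba_unbalanced > 1) {
    abort("laba_no_ics and laba_unbalanced are mutually exclusive assignments; their sum must be <= 1")
  }

  er <- utils::modifyList(default_exclusion_rates(dialect), as.list(exclusion_rates))
  erv <- unlist(er)
  if (any(erv < 0 | erv > 1)) abort("exclusion_rates must lie in [0, 1]")
  if (sum(erv) >= 1) {
    abort(sprintf("exclusion_rates sum to %.3f; must be < 1 so eligible patients exist",
                  sum(erv)))
  }
  if (dialect == "DISPENSATION_FR_LIKE" && er$no_asthma_diagnosis > 0) {
    abort("no_asthma_diagnosis channel does not exist in the dispensation dialect")
  }

  if (is.null(data_end_date)) {
    data_end_date <- as.Date(sprintf("%d-06-30", as.integer(cohort_year) + 1L))
  }
  data_end_date <- as.Date(data_end_date)
  cutoff <- add_months(data_end_date, -12)
  year_start <- as.Date(sprintf("%d-01-01", as.integer(cohort_year)))
  year_end <- as.Date(sprintf("%d-12-31", as.integer(cohort_year)))
  if (cutoff < year_start + 2) {
    abort("data_end_date leaves no room for eligible entries (need >= 12 months after the third qualifying date)")
  }
  if (er$insufficient_followup > 0 && cutoff >= year_end) {
    abort("data_end_date covers 12 months past every possible entry; the insufficient_followup channel cannot be planted")
  }

  structure(list(seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 dialect = dialect,
                 cohort_year = as.integer(cohort_year),
                 age_weights = as.numeric(age_weights),
                 sex_ratio = sex_ratio,
                 planted_prevalence = pp,
                 exclusion_rates = er,
                 events_per_patient_year = events_per_patient_year,
                 pack_weights = as.numeric(pack_weights) / sum(pack_weights),
                 data_end_date = data_end_date),
            class = "sim_config")
}

#' Default channel rates of the synthetic generator
#'
#' `default_age_weights()` gives sampling weights over integer ages 0-60
#' whose restriction to the 6-40 band yields about 27% children (6-13) and
#' 73% adults (14-40). `default_exclusion_rates()` gives modest per-channel
#' probabilities summing to about 0.13.
#'
#' @return named numeric vector (`default_age_weights()`) or named list
#'   (`default_exclusion_rates()`).
#' @export
default_age_weights <- function() {
  w <- c(rep(0.4, 6),    # 0-5
         rep(2.5, 8),    # 6-13
         rep(2.0, 27),   # 14-40
         rep(0.4, 20))   # 41-60
  setNames(w, 0:60)
}

#' @rdname default_age_weights
#' @param dialect one of [dialects()]; the `no_asthma_diagnosis` channel is
#'   zero for the dispensation dialect.
#' @export
default_exclusion_rates <- function(dialect = "PRESCRIPTION_UK_LIKE") {
  dialect <- match.arg(dialect, dialects())
  list(not_enough_events = 0.05,
       age_out_of_range = 0.03,
       no_asthma_diagnosis = if (dialect == "PRESCRIPTION_UK_LIKE") 0.01 else 0,
       omalizumab = 0.005,
       chronic_ocs = 0.01,
       copd_diagnosis = 0.01,
       copd_drug = 0.005,
       cystic_fibrosis = 0.002,
       lung_cancer = 0.002,
       bronchiectasis = 0.003,
       tuberculosis = 0.002,
       sarcoidosis = 0.002,
       insufficient_followup = 0.03)
}

# channel -> ExclusionReport outcome
fate_outcome_map <- c(
  not_enough_events = "NOT_ENOUGH_EVENTS",
  age_out_of_range = "AGE_OUT_OF_RANGE",
  no_asthma_diagnosis = "NO_ASTHMA_DIAGNOSIS",
  omalizumab = "OMALIZUMAB",
  chronic_ocs = "CHRONIC_OCS",
  copd_diagnosis = "COPD_OR_COPD_DRUG",
  copd_drug = "COPD_OR_COPD_DRUG",
  cystic_fibrosis = "CF",
  lung_cancer = "LUNG_CANCER",
  bronchiectasis = "BRONCHIECTASIS",
  tuberculosis = "TB",
  sarcoidosis = "SARCOIDOSIS",
  insufficient_followup = "INSUFFICIENT_FOLLOWUP",
  eligible = "INCLUDED")

#' Generate a synthetic claims database
#'
#' Draws one pseudo-random stream seeded with `config$seed` and consumes it
#' in a fixed per-patient order (sex, fate channel, age, pattern
#' assignment, event realisation), so identical seed and configuration give
#' identical tables.
#'
#' Constructive guarantees: a patient planted eligible carries three
#' qualifying respiratory-drug events on three distinct dates inside the
#' cohort year, is aged 6-40 at the third date, has 12 months of data after
#' it and triggers no exclusion; a patient planted on an exclusion channel
#' is eligible-like except for exactly that channel's trigger; a patient
#' planted with a pattern carries follow-up events realising exactly that
#' pattern. Qualifying events use the leukotriene-antagonist class and
#' background noise uses class `OTHER`, so neither interferes with the
#' pattern counts.
#'
#' @param config a [sim_config()].
#' @return list of class `claims_db` with tibbles `patients` (`patient_id,
#'   birth_date, sex, dialect`), `med_events` (`patient_id, date,
#'   drug_code, packs`), `dx_events` (`patient_id, date, condition_code,
#'   source_kind`), `truth` (`patient_id, should_be_included, reason,
#'   entry_date, age_at_entry, saba_overuse, laba_no_ics,
#'   laba_unbalanced`), and the `config`.
#' @export
generate_claims <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  term <- default_terminology(config$dialect)
  cond <- default_condition_codes(config$dialect)
  codes_of <- function(class) term$code[term$class_label == class]
  cond_codes_of <- function(label) cond$code[cond$condition_label == label]

  year <- config$cohort_year
  year_start <- as.Date(sprintf("%d-01-01", year))
  year_end <- as.Date(sprintf("%d-12-31", year))
  data_end <- config$data_end_date
  cutoff <- min(add_months(data_end, -12), year_end)  # latest eligible entry
  elig_days <- as.integer(cutoff - year_start)        # offsets 0..elig_days

  rates <- config$exclusion_rates
  fates <- c(names(rates), "eligible")
  fate_prob <- c(unlist(rates), 1 - sum(unlist(rates)))

  draw_packs <- function(n) sample(1:3, n, replace = TRUE, prob = config$pack_weights)
  draw_age <- function(in_band) {
    ages <- 0:60
    w <- config$age_weights
    keep <- if (in_band) ages >= 6 & ages <= 40 else ages < 6 | ages > 40
    w <- w * keep
    if (sum(w) == 0) w <- as.numeric(keep)  # fallback: uniform on the band
    sample(ages, 1, prob = w)
  }
  dx_source <- function() {
    if (config$dialect == "PRESCRIPTION_UK_LIKE") "DIAGNOSIS"
    else sample(c("LTC_FLAG", "HOSPITAL_DISCHARGE"), 1)
  }

  n <- config$n_patients
  pat_sex <- character(n)
  pat_birth <- rep(as.Date(NA), n)
  med_rows <- vector("list", n)
  dx_rows <- vector("list", n)
  tr_reason <- character(n)
  tr_entry <- rep(as.Date(NA), n)
  tr_age <- rep(NA_integer_, n)
  tr_saba <- logical(n)
  tr_cat <- character(n)

  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    sex <- if (runif(1) < config$sex_ratio) "M" else "F"
    fate <- sample(fates, 1, prob = fate_prob)
    age <- draw_age(in_band = fate != "age_out_of_range")
    birth <- as.Date(sprintf("%d-01-01", year - age))

    pp <- config$planted_prevalence
    want_saba <- runif(1) < pp$saba_overuse
    laba_cat <- sample(c("laba_no_ics", "laba_unbalanced", "none"), 1,
                       prob = c(pp$laba_no_ics, pp$laba_unbalanced,
                                1 - pp$laba_no_ics - pp$laba_unbalanced))

    med_date <- as.Date(integer(0), origin = "1970-01-01")
    med_code <- character(0)
    med_packs <- numeric(0)
    dx_date <- as.Date(integer(0), origin = "1970-01-01")
    dx_code <- character(0)
    dx_src <- character(0)
    add_med <- function(dates, code, packs) {
      med_date <<- c(med_date, dates)
      med_code <<- c(med_code, rep_len(code, length(dates)))
      med_packs <<- c(med_packs, rep_len(packs, length(dates)))
    }
    add_dx <- function(dates, code, source) {
      dx_date <<- c(dx_date, dates)
      dx_code <<- c(dx_code, rep_len(code, length(dates)))
      dx_src <<- c(dx_src, rep_len(source, length(dates)))
    }

    # --- qualifying respiratory events (LTRA class) ------------------------
    if (fate == "not_enough_events") {
      qual_dates <- year_start + sample.int(elig_days + 1L, 2) - 1L
      entry <- as.Date(NA)
    } else if (fate == "insufficient_followup") {
      late_days <- as.integer(year_end - cutoff)  # offsets 1..late_days past cutoff
      d3 <- cutoff + sample.int(late_days, 1)
      # minimal forward shift if month-end clamping makes 12 months still covered
      while (add_months(d3, 12) <= data_end && d3 < year_end) d3 <- d3 + 1L
      earlier <- as.integer(d3 - year_start)      # days strictly before d3
      d12 <- year_start + sample.int(earlier, 2) - 1L
      qual_dates <- c(sort(d12), d3)
      entry <- d3
    } else {
      qual_dates <- sort(year_start + sample.int(elig_days + 1L, 3) - 1L)
      entry <- qual_dates[3]
    }
    add_med(qual_dates, sample(codes_of("LTRA"), length(qual_dates), replace = TRUE),
            draw_packs(length(qual_dates)))

    # --- asthma diagnosis (prescription dialect only) ----------------------
    if (config$dialect == "PRESCRIPTION_UK_LIKE" && fate != "no_asthma_diagnosis") {
      anchor <- if (is.na(entry)) qual_dates[1] else entry
      add_dx(anchor - sample.int(300, 1), sample(cond_codes_of("ASTHMA"), 1),
             "DIAGNOSIS")
    }

    # --- exclusion trigger -------------------------------------------------
    if (!is.na(entry)) {
      lb_day <- function() entry - sample.int(360, 1)  # always inside lookback
      if (fate == "omalizumab") {
        add_med(lb_day(), sample(codes_of("OMALIZUMAB"), 1), 1)
      } else if (fate == "chronic_ocs") {
        dates4 <- entry - c(30L, 90L, 180L, 270L)      # 4 dates, >=2 quarters apart
        ocs_dates <- if (config$dialect == "PRESCRIPTION_UK_LIKE") {
          c(dates4, dates4[1])                         # 5 prescriptions, 4 dates
        } else dates4
        add_med(ocs_dates, sample(codes_of("OCS"), length(ocs_dates), replace = TRUE),
                rep(1, length(ocs_dates)))
      } else if (fate == "copd_drug") {
        code <- sample(c(codes_of("TIOTROPIUM"), codes_of("INDACATEROL")), 1)
        add_med(lb_day(), code, 1)
      } else if (fate == "copd_diagnosis") {
        add_dx(lb_day(), sample(cond_codes_of("COPD"), 1), dx_source())
      } else if (fate %in% c("cystic_fibrosis", "lung_cancer", "bronchiectasis",
                             "tuberculosis", "sarcoidosis")) {
        label <- c(cystic_fibrosis = "CYSTIC_FIBROSIS", lung_cancer = "LUNG_CANCER",
                   bronchiectasis = "BRONCHIECTASIS", tuberculosis = "TUBERCULOSIS",
                   sarcoidosis = "SARCOIDOSIS")[[fate]]
        add_dx(lb_day(), sample(cond_codes_of(label), 1), dx_source())
      }
    }

    # --- pattern realisation over follow-up --------------------------------
    if (!is.na(entry)) {
      fu_end <- add_months(entry, 12)
      fu_len <- as.integer(fu_end - entry)             # offsets 0..fu_len-1
      fu_day <- function(k) entry + (sample.int(fu_len, k, replace = TRUE) - 1L)

      if (want_saba) {
        target <- 12L + sample.int(4, 1) - 1L          # 12..15 packs
        packs <- integer(0)
        while (sum(packs) < target) packs <- c(packs, draw_packs(1))
        add_med(fu_day(length(packs)), sample(codes_of("SABA"), length(packs),
                                              replace = TRUE), packs)
      } else {
        k <- sample.int(5, 1) - 1L                     # 0..4 reliever events
        if (k > 0) {
          packs <- draw_packs(k)
          while (sum(packs) >= 12) packs[k] <- packs[k] - 1L  # keep below the bar
          packs <- packs[packs > 0]
          if (length(packs) > 0) {
            add_med(fu_day(length(packs)), sample(codes_of("SABA"), length(packs),
                                                  replace = TRUE), packs)
          }
        }
      }

      if (laba_cat == "laba_no_ics") {
        k <- sample.int(2, 1)
        add_med(fu_day(k), sample(codes_of("LABA_MONO"), k, replace = TRUE),
                draw_packs(k))
      } else if (laba_cat == "laba_unbalanced") {
        ics_total <- sample.int(2, 1)
        laba_total <- 2L * ics_total + sample.int(3, 1) - 1L
        add_med(fu_day(ics_total), sample(codes_of("ICS_MONO"), ics_total,
                                          replace = TRUE), rep(1L, ics_total))
        add_med(fu_day(laba_total), sample(codes_of("LABA_MONO"), laba_total,
                                           replace = TRUE), rep(1L, laba_total))
      } else {
        u <- runif(1)
        if (u < 0.6) {                                 # controller on FDC
          k <- sample.int(4, 1)
          add_med(fu_day(k), sample(codes_of("FDC_ICS_LABA"), k, replace = TRUE),
                  draw_packs(k))
        } else if (u < 0.8) {                          # controller on single ICS
          k <- sample.int(3, 1)
          add_med(fu_day(k), sample(codes_of("ICS_MONO"), k, replace = TRUE),
                  draw_packs(k))
        }
      }
    }

    # --- background noise (class OTHER, affects nothing) --------------------
    n_bg <- rpois(1, config$events_per_patient_year)
    if (n_bg > 0) {
      bg_dates <- year_start + sample.int(365, n_bg, replace = TRUE) - 1L
      add_med(bg_dates, sample(codes_of("OTHER"), n_bg, replace = TRUE),
              draw_packs(n_bg))
    }

    pat_sex[i] <- sex
    pat_birth[i] <- birth
    med_rows[[i]] <- list(date = med_date, code = med_code, packs = med_packs)
    dx_rows[[i]] <- list(date = dx_date, code = dx_code, src = dx_src)
    tr_reason[i] <- fate_outcome_map[[fate]]
    tr_entry[i] <- entry
    tr_age[i] <- if (is.na(entry)) NA_integer_ else age_at(birth, entry)
    tr_saba[i] <- !is.na(entry) && want_saba
    tr_cat[i] <- if (is.na(entry)) "none" else laba_cat
  }

  pids <- sprintf("P%05d", seq_len(n))
  flatten <- function(rows, field, template = numeric(0)) {
    vals <- unlist(lapply(rows, `[[`, field), use.names = FALSE)
    if (is.null(vals)) template else vals
  }
  lens_med <- vapply(med_rows, function(r) length(r$date), integer(1))
  lens_dx <- vapply(dx_rows, function(r) length(r$date), integer(1))
  med_events <- tibble(
    patient_id = rep(pids, lens_med),
    date = as.Date(flatten(med_rows, "date"), origin = "1970-01-01"),
    drug_code = flatten(med_rows, "code", character(0)),
    packs = flatten(med_rows, "packs"))
  dx_events <- tibble(
    patient_id = rep(pids, lens_dx),
    date = as.Date(flatten(dx_rows, "date"), origin = "1970-01-01"),
    condition_code = flatten(dx_rows, "code", character(0)),
    source_kind = flatten(dx_rows, "src", character(0)))
  structure(
    list(patients = tibble(patient_id = pids, birth_date = pat_birth,
                           sex = pat_sex, dialect = rep_len(config$dialect, n)),
         med_events = arrange(med_events, .data$patient_id, .data$date,
                              .data$drug_code),
         dx_events = arrange(dx_events, .data$patient_id, .data$date,
                             .data$condition_code),
         truth = tibble(patient_id = pids,
                        should_be_included = tr_reason == "INCLUDED",
                        reason = tr_reason,
                        entry_date = tr_entry,
                        age_at_entry = tr_age,
                        saba_overuse = tr_saba,
                        laba_no_ics = tr_cat == "laba_no_ics",
                        laba_unbalanced = tr_cat == "laba_unbalanced"),
         config = config),
    class = "claims_db")
}

#' @export
print.claims_db <- function(x, ...) {
  cat(sprintf("synthetic claims database: %d patients, %d medication events, %d dx/LTC events (%s, %d)\n",
              nrow(x$patients), nrow(x$med_events), nrow(x$dx_events),
              x$config$dialect, x$config$cohort_year))
  invisible(x)
}

#' Write / read a claims database as CSV files
#'
#' Writes `patients.csv`, `med_events.csv`, `dx_events.csv` and `truth.csv`
#' with deterministic row order (patient id, then date, then code) and
#' ISO-8601 dates, so two runs with the same seed produce byte-identical
#' files. `read_claims_tables()` is the inverse.
#'
#' @param db a `claims_db` from [generate_claims()], or any list holding
#'   the four tables.
#' @param directory output directory, created if needed.
#' @return `write_claims_tables()`: named character vector of file paths,
#'   invisibly; `read_claims_tables()`: a list with the four tibbles.
#' @export
write_claims_tables <- function(db, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patients = file.path(directory, "patients.csv"),
             med_events = file.path(directory, "med_events.csv"),
             dx_events = file.path(directory, "dx_events.csv"),
             truth = file.path(directory, "truth.csv"))
  for (nm in names(paths)) {
    readr::write_csv(db[[nm]], paths[[nm]], na = "")
  }
  invisible(paths)
}

#' @rdname write_claims_tables
#' @export
read_claims_tables <- function(directory) {
  rd <- function(file, types) {
    readr::read_csv(file.path(directory, file), col_types = types, na = "")
  }
  list(
    patients = rd("patients.csv", readr::cols(
      patient_id = readr::col_character(), birth_date = readr::col_date(),
      sex = readr::col_character(), dialect = readr::col_character())),
    med_events = rd("med_events.csv", readr::cols(
      patient_id = readr::col_character(), date = readr::col_date(),
      drug_code = readr::col_character(), packs = readr::col_double())),
    dx_events = rd("dx_events.csv", readr::cols(
      patient_id = readr::col_character(), date = readr::col_date(),
      condition_code = readr::col_character(), source_kind = readr::col_character())),
    truth = rd("truth.csv", readr::cols(
      patient_id = readr::col_character(), should_be_included = readr::col_logical(),
      reason = readr::col_character(), entry_date = readr::col_date(),
      age_at_entry = readr::col_integer(), saba_overuse = readr::col_logical(),
      laba_no_ics = readr::col_logical(), laba_unbalanced = readr::col_logical())))
}

#' Read a simulation configuration from YAML
#'
#' The YAML fields mirror the arguments of [sim_config()]; absent fields
#' take the defaults.
#'
#' @param path YAML file path.
#' @return a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown sim_config field(s) in '%s': %s",
                  path, paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$age_weights)) raw$age_weights <- unlist(raw$age_weights)
  if (!is.null(raw$pack_weights)) raw$pack_weights <- unlist(raw$pack_weights)
  do.call(sim_config, raw)
}
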