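#' Pack-unit counts by therapeutic class over follow-up
#'
#' A treatment unit is one prescribed/dispensed pack. For each cohort member
#' the packs of each class are summed over the half-open follow-up window
#' `[entry_date, entry_date + 12 months)`; events outside the window or of
#' class `OTHER`/non-counted classes contribute nothing. The entry-date
#' events themselves are follow-up exposure.
#'
#' @param member one row of the cohort tibble (needs `entry_date` and
#'   `followup_end`).
#' @param events the member's medication events (`date, drug_code, packs`).
#' @param terminology drug terminology tibble.
#' @return a one-row tibble with columns `saba_units, laba_mono_units,
#'   ics_mono_units, fdc_units, ltra_units, xanthine_units`.
#' @export
count_units <- function(member, events, terminology) {
  counts <- count_units_core(
    as.Date(events$date),
    classify_drug(events$drug_code, terminology),
    events$packs,
    member$entry_date, member$followup_end)
  as_tibble(as.list(counts))
}

counted_classes <- c(SABA = "saba_units", LABA_MONO = "laba_mono_units",
                     ICS_MONO = "ics_mono_units", FDC_ICS_LABA = "fdc_units",
                     LTRA = "ltra_units", XANTHINE = "xanthine_units")

count_units_core <- function(dates, classes, packs, start, end) {
  in_fu <- dates >= start & dates < end
  out <- setNames(numeric(length(counted_classes)), unname(counted_classes))
  for (cl in names(counted_classes)) {
    out[counted_classes[[cl]]] <- sum(packs[in_fu & classes == cl])
  }
  out
}

#' The three inappropriate-therapy flags
#'
#' Applied to follow-up pack-unit counts:
#' * `flag_saba_overuse()` — 12 or more SABA packs over the 12-month
#'   follow-up.
#' * `flag_laba_no_ics()` — at least one single-agent LABA pack with no ICS
#'   at all, neither single-agent ICS nor fixed-dose ICS+LABA combination.
#' * `flag_laba_unbalanced()` — at least twice as many single-agent LABA
#'   packs as single-agent ICS packs (ratio LABA/ICS >= 2), requiring at
#'   least one single-ICS pack; fixed-dose combination packs enter neither
#'   side of the ratio.
#'
#' The two LABA flags are mutually exclusive by construction: the zero-ICS
#' ratio case belongs to `flag_laba_no_ics()` when no FDC exists, and to
#' neither flag when FDC packs are present (the ratio is undefined and the
#' patient does have ICS co-therapy).
#'
#' @param counts a tibble of unit counts as returned by [count_units()]
#'   (any number of rows; flags are computed rowwise).
#' @return logical vector, one element per row of `counts`.
#' @export
flag_saba_overuse <- function(counts) {
  counts$saba_units >= 12
}

#' @rdname flag_saba_overuse
#' @export
flag_laba_no_ics <- function(counts) {
  counts$laba_mono_units >= 1 & (counts$ics_mono_units + counts$fdc_units) == 0
}

#' @rdname flag_saba_overuse
#' @export
flag_laba_unbalanced <- function(counts) {
  counts$ics_mono_units >= 1 & counts$laba_mono_units >= 2 * counts$ics_mono_units
}

#' Classify a whole cohort and summarise prevalences
#'
#' Computes follow-up unit counts and the three flags for every cohort
#' member, and tabulates prevalences by age stratum (children 6-13, adults
#' 14-40) and overall, as percentages rounded half-up to one decimal.
#'
#' @param cohort the cohort tibble from [build_cohort()].
#' @param med_events medication events table (all patients; filtered
#'   internally).
#' @param terminology drug terminology tibble.
#' @return list with
#'   * `flags`: one row per member — the unit-count columns plus
#'     `saba_overuse, laba_no_ics, laba_unbalanced`;
#'   * `prevalence`: tibble `stratum, pattern, n, n_flagged, percent`.
#' @export
classify_cohort <- function(cohort, med_events, terminology) {
  med_events <- mutate(as_tibble(med_events), date = as.Date(.data$date))
  med_events$class <- classify_drug(med_events$drug_code, terminology)

  ids <- cohort$patient_id
  ev_by <- split(med_events[c("date", "class", "packs")],
                 factor(med_events$patient_id, levels = ids))
  counts <- matrix(0, nrow = length(ids), ncol = length(counted_classes),
                   dimnames = list(NULL, unname(counted_classes)))
  for (i in seq_along(ids)) {
    ev <- ev_by[[i]]
    counts[i, ] <- count_units_core(ev$date, ev$class, ev$packs,
                                    cohort$entry_date[i], cohort$followup_end[i])
  }
  flags <- dplyr::bind_cols(
    cohort[c("patient_id", "age_group")],
    as_tibble(as.data.frame(counts)))
  flags$saba_overuse <- flag_saba_overuse(flags)
  flags$laba_no_ics <- flag_laba_no_ics(flags)
  flags$laba_unbalanced <- flag_laba_unbalanced(flags)

  strata <- list(CHILD_6_13 = flags$age_group == "CHILD_6_13",
                 ADULT_14_40 = flags$age_group == "ADULT_14_40",
                 ALL = rep(TRUE, nrow(flags)))
  patterns <- c("saba_overuse", "laba_no_ics", "laba_unbalanced")
  prevalence <- bind_rows(lapply(names(strata), function(s) {
    sub <- flags[strata[[s]], patterns]
    n_flagged <- unname(vapply(sub, sum, numeric(1)))
    tibble(stratum = s, pattern = patterns,
           n = nrow(sub),
           n_flagged = n_flagged,
           percent = if (nrow(sub) > 0) percent_of(n_flagged, nrow(sub))
                     else NA_real_)
  }))
  list(flags = flags, prevalence = prevalence)
}
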