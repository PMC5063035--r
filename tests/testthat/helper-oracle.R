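# Independent brute-force oracles, written against the printed rule
# definitions with their own date arithmetic. Deliberately naive: per-row
# loops, string-formatted date comparisons, no shared code with R/.

oracle_add_months <- function(d, n) {
  lt <- as.POSIXlt(d)
  m0 <- lt$year * 12L + lt$mon + as.integer(n)
  y <- m0 %/% 12L + 1900L
  m <- m0 %% 12L + 1L
  leap <- (y %% 4 == 0 & (y %% 100 != 0 | y %% 400 == 0))
  dim <- c(31L, 28L + leap, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[m]
  as.Date(sprintf("%04d-%02d-%02d", y, m, min(lt$mday, dim)))
}

oracle_age <- function(birth, at) {
  as.integer(format(at, "%Y")) - as.integer(format(birth, "%Y")) -
    as.integer(format(at, "%m%d") < format(birth, "%m%d"))
}

oracle_resp_classes <- c("SABA", "LABA_MONO", "ICS_MONO", "FDC_ICS_LABA",
                         "LTRA", "XANTHINE")

oracle_one_patient <- function(birth, sex, med, dx, dialect, year, data_end,
                               term, cond, min_ocs_uk = 5) {
  cls <- term$class_label[match(med$drug_code, term$code)]
  cls[is.na(cls)] <- "OTHER"
  cnd <- cond$condition_label[match(dx$condition_code, cond$code)]
  cnd[is.na(cnd)] <- "OTHER"
  med_dates <- as.Date(med$date)
  dx_dates <- as.Date(dx$date)

  resp_dates <- sort(unique(med_dates[cls %in% oracle_resp_classes &
                                        format(med_dates, "%Y") == as.character(year)]))
  if (length(resp_dates) < 3) return("NOT_ENOUGH_EVENTS")
  entry <- resp_dates[3]

  if (dialect == "PRESCRIPTION_UK_LIKE" &&
      !any(cnd == "ASTHMA" & dx_dates <= entry)) {
    return("NO_ASTHMA_DIAGNOSIS")
  }

  age <- oracle_age(birth, entry)
  if (age < 6 | age > 40) return("AGE_OUT_OF_RANGE")

  lb_start <- oracle_add_months(entry, -12)
  lb <- med_dates >= lb_start & med_dates < entry
  if (any(cls[lb] == "OMALIZUMAB")) return("OMALIZUMAB")

  ocs <- med_dates[lb & cls == "OCS"]
  chronic <- if (dialect == "PRESCRIPTION_UK_LIKE") {
    length(ocs) >= min_ocs_uk && length(unique(ocs)) >= 4
  } else {
    qtr <- paste(format(ocs, "%Y"), (as.integer(format(ocs, "%m")) + 2) %/% 3)
    length(unique(ocs)) >= 4 && length(unique(qtr)) >= 2
  }
  if (chronic) return("CHRONIC_OCS")

  dxlb <- dx_dates >= lb_start & dx_dates < entry
  copd_drug <- any(cls[lb] %in% c("TIOTROPIUM", "INDACATEROL")) &&
    !any(cls[lb] %in% c("ICS_MONO", "FDC_ICS_LABA"))
  if (any(cnd[dxlb] == "COPD") || copd_drug) return("COPD_OR_COPD_DRUG")
  if (any(cnd[dxlb] == "CYSTIC_FIBROSIS")) return("CF")
  if (any(cnd[dxlb] == "LUNG_CANCER")) return("LUNG_CANCER")
  if (any(cnd[dxlb] == "BRONCHIECTASIS")) return("BRONCHIECTASIS")
  if (any(cnd[dxlb] == "TUBERCULOSIS")) return("TB")
  if (any(cnd[dxlb] == "SARCOIDOSIS")) return("SARCOIDOSIS")

  if (data_end < oracle_add_months(entry, 12)) return("INSUFFICIENT_FOLLOWUP")
  "INCLUDED"
}

oracle_outcomes <- function(patients, med_events, dx_events, dialect, year,
                            data_end, term, cond, min_ocs_uk = 5) {
  vapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    oracle_one_patient(as.Date(patients$birth_date[i]), patients$sex[i],
                       med_events[med_events$patient_id == pid, ],
                       dx_events[dx_events$patient_id == pid, ],
                       dialect, year, data_end, term, cond, min_ocs_uk)
  }, character(1))
}

# brute-force transcription of the printed pattern definitions
oracle_flags <- function(saba, laba, ics, fdc) {
  saba_overuse <- saba >= 12
  laba_no_ics <- laba >= 1 && ics == 0 && fdc == 0
  unbalanced <- ics >= 1 && laba / ics >= 2
  c(saba_overuse = saba_overuse, laba_no_ics = laba_no_ics,
    laba_unbalanced = unbalanced)
}

# Pearson chi-squared by the closed form sum((O - E)^2 / E)
oracle_chisq <- function(a, na, b, nb) {
  o <- matrix(c(a, na - a, b, nb - b), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}
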