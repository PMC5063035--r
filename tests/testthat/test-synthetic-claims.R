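test_that("impossible configurations are rejected before generation", {
  expect_error(sim_config(planted_prevalence = list(
    saba_overuse = 0.1, laba_no_ics = 0.6, laba_unbalanced = 0.6)),
    "mutually exclusive")
  expect_error(sim_config(planted_prevalence = list(
    saba_overuse = 1.2, laba_no_ics = 0, laba_unbalanced = 0)),
    "\\[0, 1\\]")
  heavy <- as.list(setNames(rep(0.2, 13), names(default_exclusion_rates())))
  expect_error(sim_config(exclusion_rates = heavy), "must be < 1")
  expect_error(sim_config(dialect = "DISPENSATION_FR_LIKE",
                          exclusion_rates = list(no_asthma_diagnosis = 0.1)),
               "dispensation dialect")
})

test_that("generation is deterministic per seed and writes byte-identical files", {
  cfg <- sim_config(seed = 99, n_patients = 40)
  db1 <- generate_claims(cfg)
  db2 <- generate_claims(cfg)
  expect_identical(db1$med_events, db2$med_events)
  expect_identical(db1$truth, db2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_claims_tables(db1, d1)
  write_claims_tables(db2, d2)
  for (f in c("patients.csv", "med_events.csv", "dx_events.csv", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # different seed, different data
  db3 <- generate_claims(sim_config(seed = 100, n_patients = 40))
  expect_false(identical(db1$med_events, db3$med_events))
})

test_that("tables round-trip through CSV, including the empty database", {
  cfg <- sim_config(seed = 4, n_patients = 25)
  db <- generate_claims(cfg)
  dir <- withr::local_tempdir()
  write_claims_tables(db, dir)
  back <- read_claims_tables(dir)
  for (nm in c("patients", "med_events", "dx_events", "truth")) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(db[[nm]]))
  }

  db0 <- generate_claims(sim_config(seed = 1, n_patients = 0))
  expect_equal(nrow(db0$patients), 0)
  dir0 <- withr::local_tempdir()
  write_claims_tables(db0, dir0)
  expect_equal(length(readLines(file.path(dir0, "med_events.csv"))), 1)  # header only
  back0 <- read_claims_tables(dir0)
  expect_equal(nrow(back0$truth), 0)
})

test_that("every patient appears exactly once in the truth table", {
  db <- generate_claims(sim_config(seed = 12, n_patients = 120))
  expect_equal(sort(db$truth$patient_id), sort(db$patients$patient_id))
  expect_equal(anyDuplicated(db$truth$patient_id), 0)
})

test_that("forced planting is realised by construction", {
  # everything zeroed: downstream flags nobody
  none <- sim_config(seed = 5, n_patients = 50,
                     planted_prevalence = list(saba_overuse = 0, laba_no_ics = 0,
                                               laba_unbalanced = 0),
                     exclusion_rates = as.list(setNames(
                       rep(0, 13), names(default_exclusion_rates()))))
  db <- generate_claims(none)
  expect_true(all(db$truth$should_be_included))
  cc <- cohort_config(none$dialect, none$cohort_year,
                      data_end_date = none$data_end_date)
  res <- build_cohort(db$patients, db$med_events, db$dx_events, cc)
  cl <- classify_cohort(res$cohort, db$med_events,
                        default_terminology(none$dialect))
  expect_equal(sum(cl$flags$saba_overuse), 0)
  expect_equal(sum(cl$flags$laba_no_ics), 0)
  expect_equal(sum(cl$flags$laba_unbalanced), 0)

  # saba_overuse = 1: every included patient carries >= 12 SABA packs
  all_saba <- sim_config(seed = 6, n_patients = 20,
                         planted_prevalence = list(saba_overuse = 1,
                                                   laba_no_ics = 0,
                                                   laba_unbalanced = 0),
                         exclusion_rates = as.list(setNames(
                           rep(0, 13), names(default_exclusion_rates()))))
  db <- generate_claims(all_saba)
  cc <- cohort_config(all_saba$dialect, all_saba$cohort_year,
                      data_end_date = all_saba$data_end_date)
  res <- build_cohort(db$patients, db$med_events, db$dx_events, cc)
  expect_equal(nrow(res$cohort), 20)
  cl <- classify_cohort(res$cohort, db$med_events,
                        default_terminology(all_saba$dialect))
  expect_true(all(cl$flags$saba_units >= 12))
  expect_true(all(cl$flags$saba_overuse))
})

test_that("both dialects plant every exclusion channel recoverably", {
  for (d in dialects()) {
    rates <- default_exclusion_rates(d)
    rates[] <- lapply(names(rates), function(nm) {
      if (nm == "no_asthma_diagnosis" && d == "DISPENSATION_FR_LIKE") 0 else 0.06
    })
    cfg <- sim_config(seed = 31, n_patients = 400, dialect = d,
                      exclusion_rates = rates)
    db <- generate_claims(cfg)
    cc <- cohort_config(d, cfg$cohort_year, data_end_date = cfg$data_end_date)
    res <- build_cohort(db$patients, db$med_events, db$dx_events, cc)
    expect_identical(res$exclusions$outcome, db$truth$reason)
    # all channels actually drawn at these rates
    planted <- setdiff(unique(db$truth$reason), "INCLUDED")
    expect_gte(length(planted), 10)
  }
})

test_that("YAML configuration mirrors sim_config arguments", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 7", "n_patients: 15",
               "dialect: DISPENSATION_FR_LIKE", "cohort_year: 2007",
               "planted_prevalence:", "  saba_overuse: 0.2",
               "  laba_no_ics: 0.05", "  laba_unbalanced: 0.05"), tmp)
  cfg <- read_sim_config(tmp)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$cohort_year, 2007L)
  expect_equal(cfg$planted_prevalence$saba_overuse, 0.2)
  expect_identical(generate_claims(cfg)$med_events,
                   generate_claims(cfg)$med_events)

  writeLines(c("seed: 7", "bogus_field: 1"), tmp)
  expect_error(read_sim_config(tmp), "unknown sim_config field")
})
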