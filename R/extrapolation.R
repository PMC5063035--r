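#' National inputs for burden extrapolation
#'
#' Direct standardisation scales a cohort prevalence to a national count
#' using externally supplied figures: the national resident population aged
#' 6-40 and the asthma prevalence in that band. These are configuration
#' inputs (census / registry figures), never fetched or hard-coded.
#'
#' @param country label, e.g. `"UK"`.
#' @param year calendar year.
#' @param population_6_40 national resident count aged 6-40.
#' @param asthma_prevalence_6_40 proportion in \[0, 1\].
#' @param rounding_granularity positive integer; extrapolated counts are
#'   rounded to this granularity (default 10, matching burden tables
#'   reported to the nearest ten).
#' @return a validated list of class `national_inputs`.
#' @export
national_inputs <- function(country, year, population_6_40,
                            asthma_prevalence_6_40, rounding_granularity = 10) {
  required <- c(population_6_40 = missing(population_6_40),
                asthma_prevalence_6_40 = missing(asthma_prevalence_6_40))
  if (any(required)) {
    abort(sprintf("national_inputs missing field(s): %s",
                  paste(names(required)[required], collapse = ", ")))
  }
  stopifnot(is.numeric(population_6_40), population_6_40 > 0,
            is.numeric(asthma_prevalence_6_40),
            asthma_prevalence_6_40 >= 0, asthma_prevalence_6_40 <= 1,
            rounding_granularity >= 1)
  structure(list(country = country, year = year,
                 population_6_40 = population_6_40,
                 asthma_prevalence_6_40 = asthma_prevalence_6_40,
                 rounding_granularity = rounding_granularity),
            class = "national_inputs")
}

#' Extrapolate a cohort pattern prevalence to a national count
#'
#' `count = pattern_prevalence * asthma_prevalence_6_40 * population_6_40`,
#' rounded to the configured granularity. The product of the last two
#' factors is the estimated national asthma population aged 6-40; the
#' pattern prevalence is then applied to it.
#'
#' @param pattern_prevalence proportion of cohort members flagged, in \[0, 1\].
#' @param inputs a [national_inputs()] object.
#' @return a single extrapolated count.
#' @examples
#' uk <- national_inputs("UK", 2013, population_6_40 = 1e6,
#'                       asthma_prevalence_6_40 = 0.10)
#' extrapolate_pattern(0.10, uk) # 10000
#' @export
extrapolate_pattern <- function(pattern_prevalence, inputs) {
  if (!inherits(inputs, "national_inputs")) {
    abort("inputs must be created with national_inputs()")
  }
  stopifnot(pattern_prevalence >= 0, pattern_prevalence <= 1)
  raw <- pattern_prevalence * inputs$asthma_prevalence_6_40 * inputs$population_6_40
  g <- inputs$rounding_granularity
  round_half_up(raw / g, 0) * g
}

#' Total national burden across the three patterns
#'
#' The total is the exact sum of the three per-pattern counts; no further
#' rounding is applied, so a total computed from already-rounded components
#' reproduces published component-sum totals exactly.
#'
#' @param saba_overuse,laba_no_ics,laba_unbalanced per-pattern national
#'   counts. Alternatively pass a single numeric vector of length 3 as the
#'   first argument.
#' @return the integer total.
#' @examples
#' total_burden(158560, 7040, 11520) # 177120
#' @export
total_burden <- function(saba_overuse, laba_no_ics, laba_unbalanced) {
  if (missing(laba_no_ics) && length(saba_overuse) == 3) {
    components <- saba_overuse
  } else {
    components <- c(saba_overuse, laba_no_ics, laba_unbalanced)
  }
  stopifnot(length(components) == 3, !anyNA(components))
  sum(components)
}

#' Pool stratum prevalences into one cohort prevalence
#'
#' Combines the child and adult stratum prevalences as a convex combination
#' weighted by the stratum shares of the cohort.
#'
#' @param child_prev,adult_prev stratum prevalences in \[0, 1\].
#' @param child_share,adult_share stratum shares; must sum to 1 within 1e-9.
#' @return the pooled prevalence.
#' @examples
#' weighted_cohort_prevalence(0.10, 0.20, 0.5, 0.5) # 0.15
#' @export
weighted_cohort_prevalence <- function(child_prev, adult_prev,
                                       child_share, adult_share) {
  if (abs(child_share + adult_share - 1) > 1e-9) {
    abort("stratum shares must sum to 1")
  }
  child_share * child_prev + adult_share * adult_prev
}

#' Extrapolate all three patterns and their total for one country-year
#'
#' @param prevalences named list or vector with elements `saba_overuse`,
#'   `laba_no_ics`, `laba_unbalanced`, each a cohort proportion in \[0, 1\].
#' @param inputs a [national_inputs()] object.
#' @return a tibble with one row per pattern plus a `total` row, columns
#'   `country, year, pattern, national_count`.
#' @export
extrapolate_burden <- function(prevalences, inputs) {
  patterns <- c("saba_overuse", "laba_no_ics", "laba_unbalanced")
  missing_p <- setdiff(patterns, names(prevalences))
  if (length(missing_p) > 0) {
    abort(sprintf("prevalences missing pattern(s): %s",
                  paste(missing_p, collapse = ", ")))
  }
  counts <- unname(vapply(patterns,
                          function(p) extrapolate_pattern(prevalences[[p]], inputs),
                          numeric(1)))
  tibble(country = inputs$country, year = inputs$year,
         pattern = c(patterns, "total"),
         national_count = c(counts, total_burden(unname(counts))))
}
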