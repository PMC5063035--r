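#' Compare two proportions with a Pearson chi-squared test
#'
#' The cross-country and cross-period comparisons of pattern percentages use
#' a Pearson chi-squared test on the 2x2 table of flagged vs not-flagged
#' counts, df = 1. Continuity correction is off by default (cohort sizes in
#' this setting are in the thousands) but can be switched on.
#'
#' @param flagged_a,n_a flagged count and total in group A.
#' @param flagged_b,n_b flagged count and total in group B.
#' @param groups length-2 character vector of group labels.
#' @param correct apply the Yates continuity correction? Default `FALSE`.
#' @return an object of class `proportion_comparison`: a list with `groups`,
#'   `counts` (2x2 matrix), `proportions`, `statistic`, `df`, `p_value`,
#'   `correct`.
#' @details The test is undefined when a table margin is zero (all or none
#'   flagged in both groups pooled), because an expected cell count is then
#'   zero; this raises an error rather than returning `NaN`.
#' @examples
#' compare_proportions(20, 100, 10, 100)
#' @export
compare_proportions <- function(flagged_a, n_a, flagged_b, n_b,
                                groups = c("A", "B"), correct = FALSE) {
  stopifnot(n_a >= 1, n_b >= 1,
            flagged_a >= 0, flagged_b >= 0,
            flagged_a <= n_a, flagged_b <= n_b)
  tab <- matrix(c(flagged_a, n_a - flagged_a,
                  flagged_b, n_b - flagged_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = groups, outcome = c("flagged", "not_flagged")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort(paste0(
      "chi-squared test undefined: a margin of the 2x2 table is zero ",
      "(an expected cell count would be zero)"))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  structure(
    list(groups = groups,
         counts = tab,
         proportions = c(flagged_a / n_a, flagged_b / n_b),
         statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = unname(ht$p.value),
         correct = correct),
    class = "proportion_comparison")
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat(sprintf("Pearson chi-squared comparison of proportions (%s)\n",
              if (x$correct) "with continuity correction" else "no continuity correction"))
  cat(sprintf("  %s: %d/%d (%.1f%%)  vs  %s: %d/%d (%.1f%%)\n",
              x$groups[1], x$counts[1, 1], sum(x$counts[1, ]), 100 * x$proportions[1],
              x$groups[2], x$counts[2, 1], sum(x$counts[2, ]), 100 * x$proportions[2]))
  cat(sprintf("  X-squared = %.4f, df = %d, p = %.4g\n", x$statistic, x$df, x$p_value))
  invisible(x)
}

# exact two-sided Mann-Whitney p by enumeration of all C(N, n1) group
# labelings of the pooled midranks; symmetric-deviation definition,
# which coincides with 2*min(tail) for the symmetric null distribution
mw_exact_p <- function(ranks_a_sum, pooled_ranks, n1) {
  n2 <- length(pooled_ranks) - n1
  mu <- n1 * (n1 + n2 + 1) / 2   # null mean of the rank sum of group A
  obs_dev <- abs(ranks_a_sum - mu)
  idx <- combn(length(pooled_ranks), n1)
  sums <- colSums(matrix(pooled_ranks[idx], nrow = n1))
  mean(abs(sums - mu) >= obs_dev - 1e-9)
}

#' Mann-Whitney U comparison of two samples
#'
#' U is computed from midranks over the pooled sample. The p-value comes
#' from exhaustive enumeration of all group labelings when `n1 * n2 <= 64`
#' (so ties are handled exactly), and otherwise from the normal
#' approximation with tie-corrected variance and continuity correction (the
#' correction keeps the approximation within about 0.01 of the exact p even
#' at small group sizes).
#'
#' @param sample_a,sample_b numeric vectors, both non-empty.
#' @param groups length-2 character vector of labels.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` uses the `n1 * n2 <= 64` rule. Forcing exact on large
#'   samples is refused above `choose(n, n1) > 1e6` labelings.
#' @return an object of class `rank_comparison`: list with `groups`,
#'   `n`, `u_statistic` (U for `sample_a`), `p_value`, `method`,
#'   `tie_correction_applied`.
#' @examples
#' compare_ranks(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_ranks <- function(sample_a, sample_b, groups = c("A", "B"), exact = NULL) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort("compare_ranks() requires two non-empty samples")
  }
  n1 <- length(sample_a)
  n2 <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)  # midranks
  r1 <- sum(r[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2
  has_ties <- any(duplicated(pooled))

  use_exact <- if (is.null(exact)) n1 * n2 <= 64 else isTRUE(exact)
  if (use_exact && choose(n1 + n2, n1) > 1e6) {
    abort("exact enumeration refused: more than 1e6 labelings")
  }

  if (use_exact) {
    p <- mw_exact_p(r1, r, n1)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    tie_sizes <- table(pooled)
    tie_term <- sum(tie_sizes^3 - tie_sizes) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    dev <- u - n1 * n2 / 2
    z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie-corrected variance"
  }
  structure(
    list(groups = groups, n = c(n1, n2),
         u_statistic = u,
         p_value = min(p, 1),
         method = method,
         tie_correction_applied = has_ties),
    class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat("Mann-Whitney U comparison\n")
  cat(sprintf("  n = %d vs %d, U(%s) = %g, p = %.4g (%s)\n",
              x$n[1], x$n[2], x$groups[1], x$u_statistic, x$p_value, x$method))
  invisible(x)
}

#' Descriptive statistics for report tables
#'
#' `summarize_values()` gives mean, standard deviation (n - 1 denominator;
#' reported as `NA` for a single value, never as 0) and count.
#' `tabulate_labels()` gives counts and percentages (half-up, 1 decimal) per
#' level.
#'
#' @param values numeric vector.
#' @return `summarize_values()`: a one-row tibble `mean, sd, n`;
#'   `tabulate_labels()`: a tibble `label, n, percent`.
#' @examples
#' summarize_values(c(2, 4, 6)) # mean 4, sd 2
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  tibble(mean = if (length(values) > 0) mean(values) else NA_real_,
         sd = if (length(values) >= 2) sd(values) else NA_real_,
         n = length(values))
}

#' @rdname summarize_values
#' @param labels a character or factor vector.
#' @export
tabulate_labels <- function(labels) {
  tab <- table(labels)
  tibble(label = names(tab),
         n = as.integer(tab),
         percent = percent_of(as.integer(tab), sum(tab)))
}
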