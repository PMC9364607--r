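# Matched comparison of the two strategies: 2x2 paired decision tables,
# McNemar tests on the discordant cells, paired marginal differences with
# confidence intervals, and stratified rate summaries.

#' Paired 2x2 decision table
#'
#' Cell layout (rows: observation strategy, columns: risk calculator):
#' `a` both negative, `b` SCO negative / NSC positive, `c` SCO positive /
#' NSC negative, `d` both positive.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return a list of class `paired_table` with the four cells and `n`.
#' @export
paired_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("paired-table cells must be non-negative counts")
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "paired_table")
}

#' @export
print.paired_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2L, 2L,
              dimnames = list(SCO = c("no", "yes"), NSC = c("no", "yes")))
  print(m)
  cat(sprintf("n = %d; SCO positive = %d (%.1f%%); NSC positive = %d (%.1f%%)\n",
              x$n, x$c + x$d, 100 * (x$c + x$d) / x$n,
              x$b + x$d, 100 * (x$b + x$d) / x$n))
  invisible(x)
}

#' Build a paired decision table from per-record outcomes
#'
#' @param outcomes_sco,outcomes_nsc data frames with an `id` column and the
#'   logical decision column named by `field`; both must contain the same
#'   set of ids (an id mismatch is a pairing error).
#' @param field the decision compared: `"antibiotics"` or `"evaluated"`.
#' @param ids optional subset of record ids (e.g. a late-preterm stratum)
#'   applied before counting.
#' @return a [paired_table()].
#' @export
build_paired_table <- function(outcomes_sco, outcomes_nsc,
                               field = c("antibiotics", "evaluated"),
                               ids = NULL) {
  field <- match.arg(field)
  if (!setequal(outcomes_sco$id, outcomes_nsc$id) ||
      nrow(outcomes_sco) != nrow(outcomes_nsc))
    stop("pairing error: outcome lists are not keyed by the same record ids")
  if (!is.null(ids)) {
    outcomes_sco <- outcomes_sco[outcomes_sco$id %in% ids, , drop = FALSE]
    outcomes_nsc <- outcomes_nsc[outcomes_nsc$id %in% ids, , drop = FALSE]
  }
  nsc <- outcomes_nsc[[field]][match(outcomes_sco$id, outcomes_nsc$id)]
  sco <- outcomes_sco[[field]]
  paired_table(a = sum(!sco & !nsc), b = sum(!sco & nsc),
               c = sum(sco & !nsc), d = sum(sco & nsc))
}

#' McNemar test on a paired table
#'
#' Only the discordant cells enter the test. The default is the exact
#' binomial variant, `p = min(1, 2 P(X <= min(b, c)))` for
#' `X ~ Binomial(b + c, 1/2)` — appropriate here because discordant counts
#' as small as 5 and 0 occur in the published tables, where the chi-square
#' asymptotics are unreliable. The chi-square variants (with and without
#' continuity correction) are provided for comparison.
#'
#' @param table a [paired_table()].
#' @param variant `"exact_binomial"`, `"chi2"`, or `"chi2_continuity"`.
#' @return a list of class `mcnemar_result`: `variant`, `statistic`
#'   (`NA` for the exact variant), `p_value`, `b`, `c`.
#' @export
mcnemar_test <- function(table, variant = c("exact_binomial", "chi2",
                                            "chi2_continuity")) {
  variant <- match.arg(variant)
  b <- table$b
  c <- table$c
  m <- b + c
  if (variant == "exact_binomial") {
    p <- if (m == 0L) 1 else min(1, 2 * stats::pbinom(min(b, c), m, 0.5))
    stat <- NA_real_
  } else {
    if (m == 0L) {
      stat <- NA_real_
      p <- 1
    } else {
      stat <- if (variant == "chi2") (b - c)^2 / m else
        (abs(b - c) - 1)^2 / m
      p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
    }
  }
  structure(list(variant = variant, statistic = stat, p_value = p,
                 b = b, c = c),
            class = "mcnemar_result")
}

#' Marginal decision rates of a paired table
#'
#' @param table a [paired_table()].
#' @return named list with `sco_pct` (= `(c + d)/n * 100`) and `nsc_pct`
#'   (= `(b + d)/n * 100`).
#' @export
marginal_rates <- function(table) {
  list(sco_pct = 100 * (table$c + table$d) / table$n,
       nsc_pct = 100 * (table$b + table$d) / table$n)
}

wilson_interval <- function(x, n, z) {
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Paired difference of marginal proportions
#'
#' The absolute difference between the two strategies' decision rates,
#' `diff = (b - c)/n * 100` percentage points (positive when the risk
#' calculator recommends the decision more often). Confidence intervals by
#' the paired Wald method or by Newcombe's square-and-add method based on
#' Wilson score intervals for the two marginals with a phi correction for
#' their correlation.
#'
#' @param table a [paired_table()].
#' @param method `"wald_paired"` or `"newcombe_paired"`.
#' @param conf_level confidence level (default 0.95).
#' @return a list of class `paired_difference`: `diff_pct`, `ci_low_pct`,
#'   `ci_high_pct`, `method`.
#' @export
paired_difference <- function(table,
                              method = c("wald_paired", "newcombe_paired"),
                              conf_level = 0.95) {
  method <- match.arg(method)
  n <- table$n
  if (n == 0L) stop("paired difference undefined for an empty table")
  b <- table$b
  c <- table$c
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  diff <- (b - c) / n
  if (method == "wald_paired") {
    se <- sqrt(max(0, b + c - (b - c)^2 / n)) / n
    lo <- diff - z * se
    hi <- diff + z * se
  } else {
    a <- table$a
    d <- table$d
    p1 <- (b + d) / n  # NSC marginal
    p2 <- (c + d) / n  # SCO marginal
    ci1 <- wilson_interval(b + d, n, z)
    ci2 <- wilson_interval(c + d, n, z)
    m1 <- (a + b) * (c + d) * (a + c) * (b + d)
    phi <- if (m1 == 0) 0 else {
      num <- a * d - b * c
      num <- if (num > 0) max(num - n / 2, 0) else num
      num / sqrt(m1)
    }
    dl <- sqrt(max(0, (p1 - ci1[1L])^2 -
                     2 * phi * (p1 - ci1[1L]) * (ci2[2L] - p2) +
                     (ci2[2L] - p2)^2))
    du <- sqrt(max(0, (ci1[2L] - p1)^2 -
                     2 * phi * (ci1[2L] - p1) * (p2 - ci2[1L]) +
                     (p2 - ci2[1L])^2))
    lo <- diff - dl
    hi <- diff + du
  }
  structure(list(diff_pct = 100 * diff,
                 ci_low_pct = 100 * lo,
                 ci_high_pct = 100 * hi,
                 method = method),
            class = "paired_difference")
}

#' Difference of rounded marginal rates
#'
#' Some published tables present the difference between the two strategies
#' as the difference of the marginal percentages after each has been
#' rounded (e.g. 27.0% - 8.4% = 18.6%), which can differ in the last digit
#' from rounding the exact difference. This helper reproduces that
#' presentation.
#'
#' @param table a [paired_table()].
#' @param digits decimal places for the marginal rounding (default 1).
#' @return numeric difference in percentage points.
#' @export
rounded_marginal_difference <- function(table, digits = 1) {
  m <- marginal_rates(table)
  round(m$nsc_pct, digits) - round(m$sco_pct, digits)
}

#' Stratified decision-rate summary
#'
#' Counts and percentages of symptomatic infants, evaluations, antibiotic
#' decisions (per strategy), triage levels, and risk-calculator stratum
#' occupancy, per stratum: the whole cohort, late-preterm (gestational age
#' below 37 weeks), full-term, and the maternal-fever subgroup (highest
#' intrapartum temperature at or above 37.5 °C). An empty stratum yields a
#' row of zeros.
#'
#' @param cohort an `eos_cohort`.
#' @param sco outcomes from [run_sco_cohort()].
#' @param nsc outcomes from [run_nsc()].
#' @param strata subset of
#'   `c("all", "late_preterm", "term", "maternal_fever")`.
#' @return data frame with one row per stratum.
#' @export
summarize_rates <- function(cohort, sco, nsc,
                            strata = c("all", "late_preterm", "term",
                                       "maternal_fever")) {
  rec <- cohort$records
  members <- list(
    all = rep(TRUE, nrow(rec)),
    late_preterm = rec$gestational_age_weeks < 37,
    term = rec$gestational_age_weeks >= 37,
    maternal_fever = rec$max_intrapartum_temp_c >= 37.5
  )
  sco <- sco[match(rec$id, sco$id), , drop = FALSE]
  nsc <- nsc[match(rec$id, nsc$id), , drop = FALSE]
  rows <- lapply(strata, function(s) {
    keep <- members[[s]]
    n <- sum(keep)
    pct <- function(x) if (n == 0L) 0 else 100 * sum(x[keep]) / n
    cnt <- function(x) sum(x[keep])
    data.frame(
      stratum = s, n = n,
      symptomatic_n = cnt(sco$symptomatic),
      symptomatic_pct = pct(sco$symptomatic),
      sco_evaluated_n = cnt(sco$evaluated),
      sco_evaluated_pct = pct(sco$evaluated),
      sco_antibiotics_n = cnt(sco$antibiotics),
      sco_antibiotics_pct = pct(sco$antibiotics),
      nsc_evaluated_n = cnt(nsc$evaluated),
      nsc_evaluated_pct = pct(nsc$evaluated),
      nsc_antibiotics_n = cnt(nsc$antibiotics),
      nsc_antibiotics_pct = pct(nsc$antibiotics),
      nicu_n = cnt(sco$triage == "NICU"),
      intermediate_care_n = cnt(sco$triage == "intermediate_care"),
      rooming_in_n = cnt(sco$triage == "rooming_in"),
      nsc_stratum_low_n = cnt(nsc$stratum == "low"),
      nsc_stratum_middle_n = cnt(nsc$stratum == "middle"),
      nsc_stratum_high_n = cnt(nsc$stratum == "high"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
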