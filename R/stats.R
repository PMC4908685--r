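#' Chi-squared goodness-of-fit test
#'
#' Pearson chi-squared statistic `sum((O - E)^2 / E)` against expected
#' proportions, with `df = k - 1` and the p-value from the chi-squared
#' survival function. Used for the strand-bias test of sense vs antisense
#' transcript-gene overlaps against an equal split.
#'
#' @param observed Non-negative counts (length k, total > 0).
#' @param expected_proportions Proportions summing to 1 (default equal
#'   split).
#' @return List: `observed`, `expected`, `statistic`, `df`, `p_value`.
#' @examples
#' chi2_gof(c(2134, 182))
#' @export
chi2_gof <- function(observed,
                     expected_proportions = rep(1 / length(observed),
                                                length(observed))) {
  if (any(observed < 0) || sum(observed) <= 0) {
    stop("observed counts must be non-negative with positive total")
  }
  if (abs(sum(expected_proportions) - 1) > 1e-8) {
    stop("expected proportions must sum to 1")
  }
  expected <- sum(observed) * expected_proportions
  if (any(expected == 0)) stop("zero expected count in some category")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(observed = observed, expected = expected, statistic = stat,
       df = df, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure with monotonicity enforcement
#' (via [stats::p.adjust()]); order-preserving.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' One-decimal percentage
#' @param num,den Numerator and denominator counts.
#' @return `round(100 * num / den, 1)`.
#' @export
percent1 <- function(num, den) round(100 * num / den, 1)

#' Fraction table for a report
#'
#' @param label Character labels.
#' @param num,den Counts.
#' @return Data frame with `label`, `num`, `den`, `percent` (1 decimal,
#'   the reporting convention throughout).
#' @export
fraction_table <- function(label, num, den) {
  data.frame(label = label, num = num, den = den,
             percent = percent1(num, den), stringsAsFactors = FALSE)
}

#' Cohort summary report
#'
#' Aggregates the headline fractions of a screen: sense/antisense split of
#' transcript-gene overlaps (with the strand-bias chi-squared test),
#' subfamily age-class composition, multi-alignment fraction, and (when
#' sequences are supplied) the coding fraction.
#'
#' @param res An `l1asp_screen` object.
#' @param coding Optional result of [coding_fraction()] over the accepted
#'   transcripts.
#' @param extra Optional [fraction_table()] rows to append (e.g. external
#'   validation counts).
#' @return List of class `l1asp_report`: `fractions` (a
#'   [fraction_table()]), `strand_test` (a [chi2_gof()] result or `NULL`
#'   when there are no overlaps), `tally`.
#' @export
cohort_report <- function(res, coding = NULL, extra = NULL) {
  tl <- tally(res)
  n_acc <- tl$n_accepted
  ori <- tl$orientation
  n_pairs <- sum(ori)
  fr <- fraction_table(
    c("sense_overlaps", "antisense_overlaps",
      paste0("class_", names(tl$per_class)), "multi_alignment"),
    c(ori[["sense"]], ori[["antisense"]], as.integer(tl$per_class),
      tl$n_multi_alignment),
    c(n_pairs, n_pairs, rep(n_acc, length(tl$per_class)), n_acc)
  )
  if (!is.null(coding)) {
    fr <- rbind(fr, fraction_table("coding", coding$n_coding, coding$n))
  }
  if (!is.null(extra)) fr <- rbind(fr, extra)
  strand_test <- if (n_pairs > 0) chi2_gof(as.integer(ori)) else NULL
  structure(list(fractions = fr, strand_test = strand_test, tally = tl),
            class = "l1asp_report")
}

#' @export
print.l1asp_report <- function(x, ...) {
  cat("L1 ASP cohort report\n")
  print(x$fractions, row.names = FALSE)
  if (!is.null(x$strand_test)) {
    cat(sprintf("strand bias: chi2 = %.1f (df = %d), p %s\n",
                x$strand_test$statistic, x$strand_test$df,
                if (x$strand_test$p_value < 2.2e-16) "< 2.2e-16"
                else sprintf("= %.3g", x$strand_test$p_value)))
  }
  invisible(x)
}
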