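# Demographic group comparisons: Welch two-sample t (from raw data or from
# printed summary statistics), paired t across matched pairs, and
# continuity-corrected two-proportion tests.

group_comparison <- function(variable, summary1, summary2, statistic, df,
                             p_value, test_kind, flag = NA_character_) {
  structure(
    list(variable = variable, mean_sd_per_group = list(summary1, summary2),
         statistic = statistic, df = df, p_value = p_value,
         test_kind = test_kind, flag = flag),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s [%s]: stat = %.4g, df = %.2f, p = %.4g\n", x$variable,
              x$test_kind, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Welch two-sample t-test from summary statistics
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Satterthwaite degrees of
#' freedom and a two-tailed p-value. Useful when only printed means and SDs
#' are available.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param variable Label for the report.
#' @return A `group_comparison`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               variable = "variable") {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      return(group_comparison(variable, c(mean1, sd1, n1), c(mean2, sd2, n2),
                              0, n1 + n2 - 2, 1, "welch_t",
                              flag = "zero variance in both groups"))
    }
    stop("zero variance in both groups with unequal means")
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tstat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  group_comparison(variable, c(mean = mean1, sd = sd1, n = n1),
                   c(mean = mean2, sd = sd2, n = n2), tstat, df, p, "welch_t")
}

#' Welch two-sample t-test from raw vectors
#'
#' @param x,y Numeric vectors.
#' @param variable Label for the report.
#' @return A `group_comparison`, identical to [ttest_from_summary()] applied
#'   to the computed summaries.
#' @export
ttest_welch <- function(x, y, variable = "variable") {
  ttest_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                     variable)
}

#' Two-proportion test with continuity correction
#'
#' Chi-squared test on the 2x2 table, with the Yates continuity correction by
#' default (matching `prop.test`).
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param continuity Apply the Yates correction?
#' @param variable Label for the report.
#' @return A `group_comparison` with `test_kind = "two_proportion_cc"`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, continuity = TRUE,
                                variable = "proportion") {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2, n1 >= 1, n2 >= 1)
  degenerate <- (k1 + k2 == 0) || (k1 + k2 == n1 + n2)
  if (degenerate) {
    return(group_comparison(variable, c(k = k1, n = n1), c(k = k2, n = n2),
                            0, 1, 1, "two_proportion_cc",
                            flag = "degenerate margins"))
  }
  ht <- suppressWarnings(prop.test(c(k1, k2), c(n1, n2), correct = continuity))
  group_comparison(variable, c(k = k1, n = n1, prop = k1 / n1),
                   c(k = k2, n = n2, prop = k2 / n2),
                   unname(ht$statistic), unname(ht$parameter), ht$p.value,
                   "two_proportion_cc")
}

#' Paired t-test
#'
#' One-sample t on the within-pair differences, two-tailed.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @param variable Label for the report.
#' @return A `group_comparison` with `test_kind = "paired_t"`.
#' @export
paired_ttest <- function(x, y, variable = "variable") {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) == 0) {
    return(group_comparison(variable, c(mean = mean(x)), c(mean = mean(y)),
                            if (mean(d) == 0) 0 else Inf, length(d) - 1,
                            if (mean(d) == 0) 1 else 0, "paired_t",
                            flag = "zero-variance differences"))
  }
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  df <- length(d) - 1
  group_comparison(variable, c(mean = mean(x), sd = sd(x)),
                   c(mean = mean(y), sd = sd(y)), tstat, df,
                   2 * pt(-abs(tstat), df), "paired_t")
}

#' Demographic comparison report for two anxiety groups
#'
#' Assembles the standard before/after-matching comparison table: Welch
#' two-sample t-tests for the continuous variables (age, education, MADRS
#' sum, each MADRS item, BAI sum) before matching, a continuity-corrected
#' two-proportion test for sex, and - when a `match_result` is supplied -
#' paired t-tests across the matched pairs plus the post-matching sex
#' proportion test.
#'
#' @param low,high `cohort_table`s for the low/high anxiety groups.
#' @param matched Optional `match_result` from [match_cohort()] fitted on the
#'   combined cohort.
#' @param cohort The combined labeled cohort behind `matched` (required with
#'   `matched`).
#' @return A data frame with one row per variable and phase (`before` /
#'   `after`), columns for group means/SDs, statistic, df, p-value, test.
#' @export
table2_report <- function(low, high, matched = NULL, cohort = NULL) {
  stopifnot(inherits(low, "cohort_table"), inherits(high, "cohort_table"))
  vars <- c(age = "age", education_years = "education_years")
  row_of <- function(gc, phase, m1, s1, m2, s2) {
    data.frame(variable = gc$variable, phase = phase,
               mean_low = m1, sd_low = s1, mean_high = m2, sd_high = s2,
               statistic = gc$statistic, df = gc$df, p_value = gc$p_value,
               test = gc$test_kind, stringsAsFactors = FALSE)
  }
  value_of <- function(g, v) {
    if (v == "madrs_sum") madrs_sum(g)
    else if (grepl("^item_", v)) as.numeric(g[[sub("item_", "m", v)]])
    else if (v == "bai_sum") as.numeric(g$bai_sum)
    else as.numeric(g[[v]])
  }
  continuous <- c("age", "education_years", "madrs_sum",
                  paste0("item_", 1:10), "bai_sum")
  before <- lapply(continuous, function(v) {
    xl <- value_of(low, v)
    xh <- value_of(high, v)
    row_of(ttest_welch(xl, xh, v), "before", mean(xl), sd(xl), mean(xh),
           sd(xh))
  })
  sex_b <- two_proportion_test(sum(low$sex == "female"), nrow(low),
                               sum(high$sex == "female"), nrow(high),
                               variable = "sex_female")
  before[[length(before) + 1]] <-
    row_of(sex_b, "before", sum(low$sex == "female") / nrow(low), NA,
           sum(high$sex == "female") / nrow(high), NA)
  out <- do.call(rbind, before)
  if (!is.null(matched)) {
    if (is.null(cohort)) stop("supply the combined cohort with the match result")
    mg <- matched_groups(cohort, matched)
    after <- lapply(continuous, function(v) {
      xl <- value_of(mg$low, v)
      xh <- value_of(mg$high, v)
      row_of(paired_ttest(xl, xh, v), "after", mean(xl), sd(xl), mean(xh),
             sd(xh))
    })
    sex_a <- two_proportion_test(sum(mg$low$sex == "female"), nrow(mg$low),
                                 sum(mg$high$sex == "female"), nrow(mg$high),
                                 variable = "sex_female")
    after[[length(after) + 1]] <-
      row_of(sex_a, "after", sum(mg$low$sex == "female") / nrow(mg$low), NA,
             sum(mg$high$sex == "female") / nrow(mg$high), NA)
    out <- rbind(out, do.call(rbind, after))
  }
  rownames(out) <- NULL
  out
}
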