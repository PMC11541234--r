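# Group comparisons of demographics and desire ratings: independent
# two-sample t-tests gated by Levene's test for equality of variances
# (pooled when Levene p >= 0.05, Welch otherwise), and a
# summary-statistics mode for recomputing printed table rows.

#' Levene-gated independent two-sample t-test
#'
#' Levene's test (center = mean) decides between the pooled-variance and
#' Welch variants at the 0.05 level; the returned p-value is two-tailed.
#' Two constant, equal groups give `t = 0, p = 1`.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param levene_gate apply the Levene gate (default); otherwise pooled.
#' @return one-row data.frame of class `ttest_result`: `t`, `df`, `p`,
#'   `variant`, `levene_p`.
#' @export
independent_t <- function(a, b, levene_gate = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(.ttest_row(0, length(a) + length(b) - 2, 1, "pooled", NA_real_))
    stop("zero variance in both groups with different means")
  }
  lev_p <- NA_real_
  pooled <- TRUE
  if (levene_gate) {
    # Levene (center = mean): one-way ANOVA on absolute deviations
    dev <- c(abs(a - mean(a)), abs(b - mean(b)))
    g <- factor(rep(c("a", "b"), c(length(a), length(b))))
    lev_p <- stats::anova(stats::lm(dev ~ g))[["Pr(>F)"]][1L]
    pooled <- lev_p >= 0.05
  }
  tt <- stats::t.test(a, b, var.equal = pooled)
  .ttest_row(unname(tt$statistic), unname(tt$parameter), tt$p.value,
             if (pooled) "pooled" else "welch", lev_p)
}

#' t-test from printed summary statistics
#'
#' Recomputes the independent two-sample t from group means, SDs and sizes
#' alone, in either the pooled-variance or the Welch (Satterthwaite df)
#' variant.  Agrees exactly with [independent_t()] fed the samples behind
#' the summaries.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries.
#' @param variant `"pooled"` or `"welch"`.
#' @return a `ttest_result` row.
#' @export
t_from_summary <- function(meanA, sdA, nA, meanB, sdB, nB,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (nA < 2L || nB < 2L) stop("n must be >= 2")
  if (sdA < 0 || sdB < 0) stop("sd must be non-negative")
  if (sdA == 0 && sdB == 0) {
    if (meanA == meanB)
      return(.ttest_row(0, nA + nB - 2, 1, variant, NA_real_))
    stop("zero variance in both groups with different means")
  }
  if (variant == "pooled") {
    df <- nA + nB - 2
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
  } else {
    vA <- sdA^2 / nA; vB <- sdB^2 / nB
    se <- sqrt(vA + vB)
    df <- (vA + vB)^2 / (vA^2 / (nA - 1) + vB^2 / (nB - 1))
  }
  t <- (meanA - meanB) / se
  .ttest_row(t, df, 2 * stats::pt(-abs(t), df), variant, NA_real_)
}

.ttest_row <- function(t, df, p, variant, levene_p) {
  out <- data.frame(t = t, df = df, p = p, variant = variant,
                    levene_p = levene_p, stringsAsFactors = FALSE)
  class(out) <- c("ttest_result", "data.frame")
  out
}

#' Group comparisons across a cohort table
#'
#' Runs the Levene-gated independent t-test AN vs HC for every numeric
#' variable, separately per age class.
#'
#' @param cohort a `cohort_table` (see
#'   [simulate_ratings_demographics()]): needs `diagnosis`, `age_class`
#'   and numeric variable columns.
#' @param variables variables to test (default: all numeric columns).
#' @return tidy data.frame: variable, age_class, group means, t, df, p,
#'   variant.
#' @export
cohort_stats <- function(cohort, variables = NULL) {
  num <- vapply(cohort, is.numeric, logical(1))
  num[names(num) %in% c("session")] <- FALSE
  if (is.null(variables)) variables <- names(cohort)[num]
  out <- list()
  for (ac in unique(cohort$age_class)) {
    sub <- cohort[cohort$age_class == ac, , drop = FALSE]
    for (v in variables) {
      a <- sub[[v]][sub$diagnosis == "AN"]
      h <- sub[[v]][sub$diagnosis == "HC"]
      if (length(a) < 2L || length(h) < 2L) next
      tt <- independent_t(h, a)   # HC minus AN, as in printed tables
      out[[length(out) + 1L]] <- data.frame(
        variable = v, age_class = ac,
        mean_HC = mean(h), sd_HC = stats::sd(h),
        mean_AN = mean(a), sd_AN = stats::sd(a),
        t = tt$t, df = tt$df, p = tt$p, variant = tt$variant,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
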