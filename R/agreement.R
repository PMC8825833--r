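# Inter-method agreement: two-way random-effects consistency ICC for the
# mean of k = 2 ratings (McGraw & Wong ICC(C,k)), with the F-distribution
# 95% confidence interval, and Bland-Altman mean/SD of paired differences.

#' Paired ratings of the same subjects by two methods
#'
#' @param method1,method2 numeric vectors (mm), aligned by subject.
#' @return an object of class `paired_ratings`.
#' @export
paired_ratings <- function(method1, method2) {
  method1 <- as.numeric(method1)
  method2 <- as.numeric(method2)
  if (length(method1) != length(method2)) {
    stop("rating vectors must have equal length")
  }
  if (anyNA(method1) || anyNA(method2)) stop("ratings must not contain NA")
  structure(list(method1 = method1, method2 = method2, n = length(method1)),
            class = "paired_ratings")
}

# two-way (subjects x raters) ANOVA mean squares for k = 2 raters
two_way_mean_squares <- function(r) {
  y <- cbind(r$method1, r$method2)
  n <- nrow(y)
  k <- ncol(y)
  grand <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Consistency ICC for the mean of two ratings, ICC(C,k)
#'
#' Two-way random-effects, consistency type, average-measures intraclass
#' correlation ("two-way random, consistency, average measures"):
#' `ICC(C,k) = (MS_subjects - MS_error) / MS_subjects` from the two-way
#' ANOVA decomposition, with the 95% confidence interval from F-distribution
#' bounds on `MS_subjects / MS_error`. Consistency-type agreement ignores
#' fixed offsets between the methods.
#'
#' @param ratings a [paired_ratings()]; at least 3 subjects.
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `ci_low`, `ci_high`, `n`. Degenerate inputs
#'   (no between-subject and no error variance) give `NA` with a warning.
#' @export
icc_consistency_k <- function(ratings, conf = 0.95) {
  stopifnot(inherits(ratings, "paired_ratings"))
  if (ratings$n < 3L) stop("ICC needs at least 3 subjects")
  ms <- two_way_mean_squares(ratings)
  if (ms$msr < 1e-300 && ms$mse < 1e-300) {
    warning("zero between-subject and error variance: ICC undefined")
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n = ms$n))
  }
  icc <- (ms$msr - ms$mse) / ms$msr
  df1 <- ms$n - 1
  df2 <- (ms$n - 1) * (ms$k - 1)
  alpha <- 1 - conf
  if (ms$mse < 1e-300) {
    # perfect consistency: the F statistic is infinite
    return(list(icc = 1, ci_low = 1, ci_high = 1, n = ms$n))
  }
  fobs <- ms$msr / ms$mse
  fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
  fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
  list(icc = icc, ci_low = 1 - 1 / fl, ci_high = 1 - 1 / fu, n = ms$n)
}

#' Bland-Altman agreement summary
#'
#' Differences `d_i = method1_i - method2_i`; reports their mean, sample
#' (n-1) standard deviation and the 95% limits of agreement
#' `mean +/- 1.96 SD`.
#'
#' @param ratings a [paired_ratings()].
#' @return list with `mean_difference`, `sd_difference`, `limits`
#'   (length 2), `n`.
#' @export
bland_altman <- function(ratings) {
  stopifnot(inherits(ratings, "paired_ratings"))
  d <- ratings$method1 - ratings$method2
  m <- mean(d)
  s <- if (length(d) > 1L) stats::sd(d) else 0
  list(mean_difference = m, sd_difference = s,
       limits = c(m - 1.96 * s, m + 1.96 * s), n = length(d))
}

#' Compare two sweep summaries
#'
#' Joins two DD-by-ML summary tables (two tool runs, or a run and an
#' external rig table) on `ml_mm`, drops MLs where either method found no
#' dislocation in range, and reports the agreement statistics.
#'
#' @param summary_a,summary_b data frames with columns `ml_mm`, `dd_mm`
#'   (see [read_sweep_summary()]).
#' @return an `agreement_report`: `icc`, `ci_low`, `ci_high`,
#'   `mean_difference`, `sd_difference`, `limits`, `n`.
#' @export
compare_sweeps <- function(summary_a, summary_b) {
  for (s in list(summary_a, summary_b)) {
    if (!all(c("ml_mm", "dd_mm") %in% names(s))) {
      stop("summaries need columns 'ml_mm' and 'dd_mm'")
    }
  }
  miss_a <- setdiff(summary_b$ml_mm, summary_a$ml_mm)
  miss_b <- setdiff(summary_a$ml_mm, summary_b$ml_mm)
  if (length(miss_a) || length(miss_b)) {
    stop(sprintf(
      "ML keys do not match: missing in first (%s); missing in second (%s)",
      paste(format(miss_a), collapse = ", "),
      paste(format(miss_b), collapse = ", ")))
  }
  m <- merge(summary_a[, c("ml_mm", "dd_mm")],
             summary_b[, c("ml_mm", "dd_mm")], by = "ml_mm",
             suffixes = c("_a", "_b"))
  m <- m[!is.na(m$dd_mm_a) & !is.na(m$dd_mm_b), ]
  if (nrow(m) < 3L) stop("fewer than 3 ML values with DD in both summaries")
  r <- paired_ratings(m$dd_mm_a, m$dd_mm_b)
  icc <- icc_consistency_k(r)
  ba <- bland_altman(r)
  structure(c(icc[c("icc", "ci_low", "ci_high")],
              ba[c("mean_difference", "sd_difference", "limits")],
              list(n = nrow(m))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement over %d paired DD values:\n", x$n))
  cat(sprintf("  ICC(C,k=2) %.4f (95%% CI %.4f-%.4f)\n", x$icc, x$ci_low,
              x$ci_high))
  cat(sprintf("  mean difference %.4f mm (SD %.4f), limits [%.4f, %.4f]\n",
              x$mean_difference, x$sd_difference, x$limits[1], x$limits[2]))
  invisible(x)
}
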