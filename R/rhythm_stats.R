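#' Incidence as a percentage
#'
#' Expresses an event count as a percentage of the animals examined, rounded
#' half-up to one decimal place as in screening tables (e.g. 4 of 7 fish with
#' sinus arrest -> 57.1).
#'
#' @param k Number of animals with the event (non-negative integer).
#' @param n Total number of animals examined (positive integer).
#' @return Percentage, a single number rounded to one decimal.
#' @examples
#' incidence_percent(4, 7)   # 57.1
#' incidence_percent(15, 44) # 34.1
#' @export
incidence_percent <- function(k, n) {
  stopifnot(length(k) == 1L, length(n) == 1L, is.finite(k), is.finite(n))
  if (n <= 0) stop("total count n must be positive")
  if (k < 0 || k > n) stop("event count k must satisfy 0 <= k <= n")
  # round() is round-half-even; table formatting is half-up
  floor(100 * k / n * 10 + 0.5) / 10
}

#' Pearson chi-square test on a 2x2 incidence table
#'
#' Compares event incidence between two groups (rows) with the Pearson
#' chi-square statistic on 1 degree of freedom. The Yates continuity
#' correction is off by default: the small-sample screening comparisons this
#' package targets reach significance only under the uncorrected statistic,
#' which is therefore the convention adopted here; set `correction = TRUE`
#' for the conservative corrected version.
#'
#' @param table 2x2 matrix of non-negative integer counts, rows = groups,
#'   columns = event / no-event.
#' @param correction Logical; apply the Yates continuity correction.
#' @return List with `statistic` (chi-square), `df` (always 1) and `p`
#'   (upper-tail probability).
#' @examples
#' chi2_2x2(matrix(c(1, 19, 15, 29), nrow = 2, byrow = TRUE))
#' @export
chi2_2x2 <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(!is.finite(table))) stop("counts must be finite and non-negative")
  if (any(rowSums(table) == 0)) stop("a row sum is zero")
  if (any(colSums(table) == 0)) stop("a column sum is zero")
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  dev <- abs(table - expected)
  if (correction) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Unpaired Student's t-test from group summaries
#'
#' Pooled-variance two-sided t-test computed from per-group mean, dispersion
#' and sample size, as needed when only table summaries (mean +/- SD or
#' mean +/- SEM) are available rather than raw measurements. SEM inputs are
#' converted to SD by multiplying by sqrt(n) before pooling.
#'
#' @param mean_a,mean_b Group means.
#' @param disp_a,disp_b Group dispersions (both of kind `kind`).
#' @param n_a,n_b Group sizes (>= 2).
#' @param kind Either "sd" or "sem", the meaning of the dispersion values.
#' @return List with `t`, `df` and two-sided `p`.
#' @examples
#' ttest_from_summary(481, 16, 6, 447, 11, 6, kind = "sd")
#' @export
ttest_from_summary <- function(mean_a, disp_a, n_a, mean_b, disp_b, n_b,
                               kind = c("sd", "sem")) {
  kind <- match.arg(kind)
  if (n_a < 2 || n_b < 2) stop("each group needs n >= 2")
  if (disp_a < 0 || disp_b < 0) stop("dispersions must be non-negative")
  sd_a <- if (kind == "sem") disp_a * sqrt(n_a) else disp_a
  sd_b <- if (kind == "sem") disp_b * sqrt(n_b) else disp_b
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  t <- (mean_a - mean_b) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Nonparametric comparison of two independent samples. When the smaller
#' sample has at most `exact_max` observations and there are no ties, the
#' two-sided p-value comes from the exact null distribution of the rank-sum
#' statistic; otherwise a normal approximation with midranks, a tie-corrected
#' variance and a continuity correction is used (the correction vanishes at
#' the null centre, so identical samples give p = 1 exactly).
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max Largest size of the smaller sample for which the exact
#'   distribution is used (both samples must also be at most 50).
#' @return List with `statistic` (Mann-Whitney U of `x`), two-sided `p`, and
#'   `method` ("exact" or "approximate").
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p  # exact 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2    # Mann-Whitney U for x
  ties <- any(duplicated(c(x, y)))
  if (!ties && min(m, n) <= exact_max && max(m, n) <= 50L) {
    # exact two-sided p: double the smaller tail of the null U distribution
    p <- if (u > m * n / 2) {
      stats::pwilcox(u - 1, m, n, lower.tail = FALSE)
    } else {
      stats::pwilcox(u, m, n)
    }
    return(list(statistic = u, p = min(1, 2 * p), method = "exact"))
  }
  # normal approximation: midranks, tie-corrected variance, continuity
  # correction toward the null centre
  nt <- m + n
  tab <- table(r)
  tiecor <- sum(tab^3 - tab) / (nt * (nt - 1))
  sigma2 <- m * n / 12 * ((nt + 1) - tiecor)
  d <- u - m * n / 2
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  list(statistic = u, p = min(1, 2 * stats::pnorm(-abs(z))), method = "approximate")
}

#' Boxplot notch interval for a median
#'
#' The approximate 95% confidence band for a sample median drawn as the notch
#' of a boxplot: q50 +/- 1.57 (q75 - q25) / sqrt(n). Two groups whose notches
#' do not overlap can be taken to differ in median at roughly the 0.05 level.
#' Quartiles use linear interpolation between order statistics
#' (\code{\link[stats]{quantile}} type 7), the convention of the plotting
#' environments this display originates from.
#'
#' @param values Non-empty numeric sample.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' notch_interval(1:9)  # c(2.9067, 7.0933)
#' @export
notch_interval <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) stop("empty sample")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  half <- 1.57 * (q[3] - q[1]) / sqrt(n)
  c(lower = q[2] - half, upper = q[2] + half)
}
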