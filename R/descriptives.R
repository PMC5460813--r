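# Univariate and bivariate descriptives: Spearman correlation, the 'N-1'
# chi-squared test for 2x2 tables, the Mann-Whitney test, medians with IQR,
# and per-zone VAS summaries.

#' Spearman rank correlation with t-approximation p-value
#'
#' Midranks are assigned to ties; rho is the Pearson correlation of the rank
#' vectors, and the two-sided p-value comes from the t approximation with
#' n - 2 degrees of freedom. Pairs with a missing member are dropped.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return A list of class `correlation_result` with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  rho <- suppressWarnings(stats::cor(rank(x), rank(y)))
  if (is.na(rho)) stop("correlation undefined (a rank vector is constant)",
                       call. = FALSE)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n),
            class = "correlation_result")
}

#' 'N-1' chi-squared test for a 2x2 table
#'
#' The Pearson chi-squared statistic multiplied by (N-1)/N, the small-sample
#' correction recommended for 2x2 comparative trials; p-value from the
#' chi-squared distribution with 1 df.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return A list of class `test_result` with `statistic`, `p_value`,
#'   `method = "n1_chi2"`.
#' @export
n1_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2", call. = FALSE)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(table)
  if (n < 2) stop("need N >= 2", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("both margins must be positive", call. = FALSE)
  }
  pearson <- suppressWarnings(
    stats::chisq.test(table, correct = FALSE)$statistic
  )
  stat <- unname(pearson) * (n - 1) / n
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = "n1_chi2"),
            class = "test_result")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midranks for ties. Above a combined sample
#' size of 12 the p-value uses the normal approximation with tie correction
#' and continuity correction; at or below 12 it is computed by exhaustive
#' enumeration of all group assignments (exact even under ties).
#'
#' @param a,b Numeric vectors, both non-empty, combined length >= 3.
#' @param exact_limit Combined size at or below which enumeration is used.
#' @return A list of class `test_result` with `statistic` (U for group `a`),
#'   `p_value`, `method = "mann_whitney"`.
#' @export
mann_whitney <- function(a, b, exact_limit = 12L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n < 3L) stop("need combined n >= 3", call. = FALSE)

  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n <= exact_limit) {
    p <- mw_exact_p(c(a, b), n1)
  } else {
    suppressWarnings(
      p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
  }
  structure(list(statistic = unname(u), p_value = p, method = "mann_whitney"),
            class = "test_result")
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of n1 of
# the pooled values to the first group; correct under ties. Two-sided p is
# the probability of a |U - mu| at least as large as observed.
mw_exact_p <- function(pooled, n1) {
  r <- rank(pooled)
  n <- length(pooled)
  n2 <- n - n1
  mu <- n1 * n2 / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %s\n",
              x$method, x$statistic, format_p(x$p_value)))
  invisible(x)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.2f (n = %d), p = %s\n",
              x$rho, x$n, format_p(x$p_value)))
  invisible(x)
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7, the inclusive spreadsheet convention).
#'
#' @param x Non-empty numeric vector (missing values dropped).
#' @return A list of class `median_iqr` with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty input", call. = FALSE)
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(median = q[2], q1 = q[1], q3 = q[3]), class = "median_iqr")
}

#' @export
print.median_iqr <- function(x, ...) {
  cat(sprintf("%.1f [%.1f-%.1f]\n", x$median, x$q1, x$q3))
  invisible(x)
}

#' Per-zone VAS mean and SD
#'
#' Splits the cohort's VAS scores into the three zones induced by a gray
#' zone — \[0, lower), \[lower, upper\], (upper, 10\] — and returns mean and
#' sample SD per zone. An empty zone is flagged (`n = 0`, `NA` moments)
#' rather than raising an error.
#'
#' @param x A [cohort].
#' @param zone A [gray_zone()] or numeric `c(lower, upper)`.
#' @return A data frame with one row per zone: `zone`, `n`, `mean`, `sd`.
#' @export
zone_mean_sd <- function(x, zone) {
  stopifnot(is_cohort(x))
  b <- zone_bounds(zone)
  lab <- classify_workers(x$vas, zone)
  out <- do.call(rbind, lapply(zone_labels(), function(z) {
    v <- x$vas[lab == z]
    data.frame(zone = z, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_)
  }))
  attr(out, "bounds") <- b
  out
}

format_p <- function(p, alpha = 0.05, strong = 0.001) {
  if (p < strong) "<0.001" else if (p < alpha) "<0.05" else sprintf("%.2f", p)
}
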