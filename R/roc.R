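# Empirical ROC construction, Mann-Whitney AUC, DeLong confidence interval,
# and single cut-point estimation under three criteria.

#' Build the empirical ROC curve of VAS against the PSS14 reference
#'
#' Workers are dichotomized at the reference cut-off (positive =
#' `pss14 >= pss_cutoff`) and a worker tests positive when `vas >= t`.
#' Candidate thresholds are the distinct observed VAS values plus one
#' sentinel below the minimum (at which Se = 1, Sp = 0); sensitivity is
#' non-increasing and specificity non-decreasing along the curve.
#'
#' @param x A [cohort].
#' @param pss_cutoff Reference cut-off (default 7.2).
#' @return An object of class `roc_curve`: a list with `points` (data frame
#'   `threshold`, `tp`, `tn`, `se`, `sp`), `n_pos`, `n_neg`, `pss_cutoff`.
#' @export
build_roc <- function(x, pss_cutoff = 7.2) {
  stopifnot(is_cohort(x))
  pos <- x$pss14 >= pss_cutoff - SCORE_TOL
  roc_from_scores(x$vas, pos, pss_cutoff = pss_cutoff)
}

# Internal fast path shared with the bootstrap: builds the curve from a
# score vector and a positivity indicator without revalidating the cohort.
roc_from_scores <- function(scores, pos, pss_cutoff = NA_real_) {
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC undefined: both reference classes must be non-empty",
         call. = FALSE)
  }
  v <- sort(unique(scores))
  thr <- c(v[1] - 1, v)          # sentinel below the minimum: se = 1, sp = 0
  # tp(t) = #positives with vas >= t; counts via reverse cumulated tabulation
  idx <- findInterval(scores + SCORE_TOL, thr)
  pos_at <- tabulate(idx[pos], nbins = length(thr))
  neg_at <- tabulate(idx[!pos], nbins = length(thr))
  tp <- rev(cumsum(rev(pos_at)))
  fp <- rev(cumsum(rev(neg_at)))
  structure(list(points = data.frame(threshold = thr,
                                     tp = tp,
                                     tn = n_neg - fp,
                                     se = tp / n_pos,
                                     sp = (n_neg - fp) / n_neg),
                 n_pos = n_pos, n_neg = n_neg, pss_cutoff = pss_cutoff),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, %d positives / %d negatives\n",
              nrow(x$points), x$n_pos, x$n_neg))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The all-pairs probability that a random positive outscores a random
#' negative, with ties half-weighted; computed from midranks.
#'
#' @inheritParams build_roc
#' @return An `auc_estimate` with the point estimate only (`ci_low`/`ci_high`
#'   are `NA`); see [delong_ci()] for the interval.
#' @export
roc_auc <- function(x, pss_cutoff = 7.2) {
  stopifnot(is_cohort(x))
  pos <- x$pss14 >= pss_cutoff - SCORE_TOL
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC undefined: both reference classes must be non-empty",
         call. = FALSE)
  }
  r <- rank(x$vas)
  a <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  new_auc_estimate(a, NA_real_, NA_real_, NA_real_)
}

new_auc_estimate <- function(auc, lo, hi, level) {
  structure(list(auc = auc, ci_low = lo, ci_high = hi, level = level),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  if (is.na(x$ci_low)) {
    cat(sprintf("AUC = %.2f\n", x$auc))
  } else {
    cat(sprintf("AUC = %.2f (%.0f%% CI: %.2f-%.2f)\n",
                x$auc, 100 * x$level, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance from the DeLong structural components: the
#' placement value of each positive against all negatives and vice versa;
#' `var(AUC) = S10/n_pos + S01/n_neg` with sample variances of the placement
#' vectors, and a normal-theory interval truncated to \[0, 1\].
#'
#' @inheritParams build_roc
#' @param level Confidence level (default 0.95).
#' @return An `auc_estimate` with `auc`, `ci_low`, `ci_high`, `level`.
#' @export
delong_ci <- function(x, pss_cutoff = 7.2, level = 0.95) {
  stopifnot(is_cohort(x), level > 0, level < 1)
  pos <- x$pss14 >= pss_cutoff - SCORE_TOL
  vx <- x$vas[pos]; vy <- x$vas[!pos]
  m <- length(vx); n <- length(vy)
  if (m < 2L || n < 2L) {
    stop("DeLong variance undefined: each class needs >= 2 workers",
         call. = FALSE)
  }
  # placement values via midranks: V10_i = placement of positive i among
  # negatives, V01_j likewise for negatives among positives
  r_all <- rank(c(vx, vy))
  v10 <- (r_all[seq_len(m)] - rank(vx)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(vy)) / m
  auc <- mean(v10)                       # = mean(v01)
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(var_auc)
  new_auc_estimate(auc, max(0, auc - half), min(1, auc + half), level)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,trials Counts with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"clopper_pearson"`.
#' @return Numeric `c(low, high)`.
#' @export
wilson_ci <- function(successes, trials, level = 0.95,
                      method = c("wilson", "clopper_pearson")) {
  method <- match.arg(method)
  if (trials < 1L) stop("trials must be >= 1", call. = FALSE)
  if (successes < 0L || successes > trials) {
    stop("successes must be between 0 and trials", call. = FALSE)
  }
  if (method == "clopper_pearson") {
    alpha <- 1 - level
    lo <- if (successes == 0) 0 else
      stats::qbeta(alpha / 2, successes, trials - successes + 1)
    hi <- if (successes == trials) 1 else
      stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
    return(c(lo, hi))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Optimal single cut-point on a ROC curve
#'
#' Scans every candidate threshold and optimizes the requested criterion:
#' `youden` maximizes J = Se + Sp - 1, `product` maximizes Se * Sp, and
#' `closest01` minimizes the Euclidean distance to the perfect corner
#' (0, 1) in ROC space. Ties are broken by the highest threshold
#' (specificity-favouring) unless `tie` says otherwise. Se/Sp confidence
#' intervals are Wilson score intervals on the underlying counts.
#'
#' @param roc A `roc_curve` from [build_roc()].
#' @param criterion One of `"youden"`, `"product"`, `"closest01"`.
#' @param level Confidence level for the Se/Sp intervals.
#' @param tie `"highest"` (default) or `"lowest"` threshold among optima.
#' @return A `threshold_estimate`: `value`, `criterion`, `se`, `sp`,
#'   `se_ci`, `sp_ci`, `j`.
#' @export
optimal_threshold <- function(roc,
                              criterion = c("youden", "product", "closest01"),
                              level = 0.95,
                              tie = c("highest", "lowest")) {
  stopifnot(inherits(roc, "roc_curve"))
  criterion <- match.arg(criterion)
  tie <- match.arg(tie)
  p <- roc$points
  score <- switch(criterion,
    youden = p$se + p$sp - 1,
    product = p$se * p$sp,
    closest01 = -sqrt((1 - p$se)^2 + (1 - p$sp)^2)
  )
  best <- which(score >= max(score) - 1e-12)
  pick <- if (tie == "highest") max(best) else min(best)
  structure(list(value = p$threshold[pick],
                 criterion = criterion,
                 se = p$se[pick],
                 sp = p$sp[pick],
                 se_ci = wilson_ci(p$tp[pick], roc$n_pos, level),
                 sp_ci = wilson_ci(p$tn[pick], roc$n_neg, level),
                 j = p$se[pick] + p$sp[pick] - 1),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "cut-point %.1f (%s): se = %.2f (%.2f-%.2f), sp = %.2f (%.2f-%.2f), J = %.2f\n",
    x$value, x$criterion, x$se, x$se_ci[1], x$se_ci[2],
    x$sp, x$sp_ci[1], x$sp_ci[2], x$j))
  invisible(x)
}
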