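# Two-threshold construction: bootstrap distribution of optimal cut-points,
# the TG-ROC inconclusive zone, and their merge into a single gray zone.

#' Bootstrap configuration
#'
#' @param n_boot Number of bootstrap replicates (>= 100; default 1000).
#' @param level Percentile-interval level (default 0.95).
#' @param stratified Resample within reference classes, so every replicate
#'   keeps the original prevalence of positives (default `TRUE`).
#' @param seed RNG seed for the resampling.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 1000L, level = 0.95,
                             stratified = TRUE, seed = NULL) {
  if (n_boot < 100L) stop("n_boot must be >= 100", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  structure(list(n_boot = as.integer(n_boot), level = level,
                 stratified = isTRUE(stratified), seed = seed),
            class = "bootstrap_config")
}

#' Bootstrap distribution of the optimal cut-point
#'
#' Draws `n_boot` resamples of the cohort (with replacement, same total size
#' as the original), rebuilds the ROC on each, and records the optimal
#' threshold under `criterion`. With `stratified = TRUE` each reference
#' class is resampled to its original size, so every replicate has the
#' original prevalence of positives. Unstratified replicates that lose a
#' whole class (no ROC exists) are redrawn; the redraw count is attached as
#' an attribute.
#'
#' @param x A [cohort].
#' @param pss_cutoff Reference cut-off (default 7.2).
#' @param criterion Cut-point criterion passed to [optimal_threshold()].
#' @param config A [bootstrap_config()].
#' @param tie Tie-break passed to [optimal_threshold()].
#' @return Numeric vector of `n_boot` cut-points, with attribute `redraws`.
#' @export
bootstrap_thresholds <- function(x, pss_cutoff = 7.2,
                                 criterion = c("youden", "product", "closest01"),
                                 config = bootstrap_config(),
                                 tie = "highest") {
  stopifnot(is_cohort(x), inherits(config, "bootstrap_config"))
  criterion <- match.arg(criterion)
  pos <- x$pss14 >= pss_cutoff - SCORE_TOL
  if (!any(pos) || all(pos)) {
    stop("ROC undefined: both reference classes must be non-empty",
         call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  v <- x$vas
  idx_pos <- which(pos)
  idx_neg <- which(!pos)
  n <- length(v)
  redraws <- 0L

  out <- vapply(seq_len(config$n_boot), function(b) {
    repeat {
      take <- if (config$stratified) {
        c(sample(idx_pos, length(idx_pos), replace = TRUE),
          sample(idx_neg, length(idx_neg), replace = TRUE))
      } else {
        sample.int(n, n, replace = TRUE)
      }
      p <- pos[take]
      if (any(p) && !all(p)) break
      redraws <<- redraws + 1L
    }
    roc <- roc_from_scores(v[take], p)
    optimal_threshold(roc, criterion, tie = tie)$value
  }, numeric(1))
  attr(out, "redraws") <- redraws
  out
}

#' Percentile confidence interval
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` with
#' linear interpolation between order statistics.
#'
#' @param values Numeric vector (>= 2 values).
#' @param level Interval level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
percentile_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  alpha <- (1 - level) / 2
  unname(stats::quantile(values, probs = c(alpha, 1 - alpha), type = 7))
}

#' TG-ROC configuration
#'
#' @param goal Performance goal for both sensitivity and specificity
#'   (default 0.90; must be in (0.5, 1)).
#' @param smoother Monotone estimate of the Se/Sp curves:
#'   `"monotone_spline"` (Hyman-filtered monotone cubic spline through the
#'   empirical step points, the default), `"isotonic"` (right-continuous
#'   step interpolation of the empirical curves), or `"none"` (linear
#'   interpolation between step points).
#' @param grid_step Evaluation grid spacing on the score axis (default 0.1).
#' @return A list of class `tgroc_config`.
#' @export
tgroc_config <- function(goal = 0.90,
                         smoother = c("monotone_spline", "isotonic", "none"),
                         grid_step = 0.1) {
  if (goal <= 0.5 || goal >= 1) stop("goal must be in (0.5, 1)", call. = FALSE)
  if (grid_step <= 0) stop("grid_step must be positive", call. = FALSE)
  structure(list(goal = goal, smoother = match.arg(smoother),
                 grid_step = grid_step),
            class = "tgroc_config")
}

# Continuous monotone estimates of Se(t) (non-increasing) and Sp(t)
# (non-decreasing) evaluated on a grid; returns a data frame
# (threshold, se, sp).
tgroc_curves <- function(roc, config = tgroc_config(), bounds = c(0, 10)) {
  p <- roc$points
  grid <- seq(bounds[1], bounds[2], by = config$grid_step)
  fit <- function(xs, ys) {
    if (length(xs) < 2L) return(rep(ys[1], length(grid)))
    est <- switch(config$smoother,
      monotone_spline = stats::splinefun(xs, ys, method = "hyman")(grid),
      # right-continuous steps: a cut-point t between observed scores
      # classifies exactly like the next observed score above it
      isotonic = stats::approx(xs, ys, xout = grid, method = "constant",
                               rule = 2, f = 1)$y,
      none = stats::approx(xs, ys, xout = grid, rule = 2)$y
    )
    pmin(pmax(est, 0), 1)
  }
  # drop the sentinel row and anchor the step curves just outside the score
  # range, at (se=1, sp=0) on the left and (se=0, sp=1) on the right, so the
  # monotone fit spans the whole grid
  emp <- p[-1L, , drop = FALSE]
  xs <- c(min(bounds[1], emp$threshold[1]) - config$grid_step,
          emp$threshold,
          max(bounds[2], emp$threshold[nrow(emp)]) + config$grid_step)
  se_y <- c(1, emp$se, 0)
  sp_y <- c(0, emp$sp, 1)
  data.frame(threshold = grid,
             se = fit(xs, se_y),
             sp = fit(xs, sp_y))
}

#' Two-Graph ROC inconclusive zone
#'
#' Plots (conceptually) sensitivity and specificity against the cut-point
#' and finds the interval of cut-points where neither curve exceeds the
#' performance goal: continuous monotone estimates of Se(t) and Sp(t) are
#' evaluated on a grid, and the zone is
#' `{t : Se(t) <= goal and Sp(t) <= goal}` ("greater than" the goal read
#' strictly, so values equal to the goal stay inconclusive). If the set is
#' empty the zone degenerates to the single grid point where the two curves
#' cross.
#'
#' @param roc A `roc_curve`.
#' @param config A [tgroc_config()].
#' @param bounds Score support (default `c(0, 10)`).
#' @return Numeric `c(low, high)` with attribute `curves` (the smoothed
#'   grid, a data frame `threshold`, `se`, `sp`).
#' @export
tgroc_zone <- function(roc, config = tgroc_config(), bounds = c(0, 10)) {
  stopifnot(inherits(roc, "roc_curve"))
  cur <- tgroc_curves(roc, config, bounds)
  inconclusive <- cur$se <= config$goal + SCORE_TOL &
                  cur$sp <= config$goal + SCORE_TOL
  if (any(inconclusive)) {
    zone <- range(cur$threshold[inconclusive])
  } else {
    cross <- which.min(abs(cur$se - cur$sp))
    zone <- rep(cur$threshold[cross], 2L)
  }
  attr(zone, "curves") <- cur
  zone
}

#' Merge the bootstrap interval and the TG-ROC zone into a gray zone
#'
#' The two constructions are complementary, so the gray zone is the largest
#' interval: the hull of the two (minimum of the lower bounds, maximum of
#' the upper bounds). Disjoint inputs still merge to their hull, with a
#' warning, since that case means the two methods disagree about where the
#' indeterminate scores live.
#'
#' @param bootstrap_ci Numeric `c(low, high)` from
#'   [bootstrap_thresholds()] + [percentile_ci()].
#' @param tgroc Numeric `c(low, high)` from [tgroc_zone()].
#' @return A [gray_zone()].
#' @export
merge_gray_zone <- function(bootstrap_ci, tgroc) {
  stopifnot(length(bootstrap_ci) == 2L, length(tgroc) == 2L,
            bootstrap_ci[1] <= bootstrap_ci[2] + SCORE_TOL,
            tgroc[1] <= tgroc[2] + SCORE_TOL)
  if (bootstrap_ci[2] < tgroc[1] - SCORE_TOL ||
      tgroc[2] < bootstrap_ci[1] - SCORE_TOL) {
    warning("bootstrap and TG-ROC intervals are disjoint; ",
            "gray zone is their hull", call. = FALSE)
  }
  gray_zone(lower = min(bootstrap_ci[1], tgroc[1]),
            upper = max(bootstrap_ci[2], tgroc[2]),
            bootstrap_ci = as.numeric(bootstrap_ci),
            tgroc_zone = as.numeric(tgroc),
            merge_rule = "interval_hull")
}

#' Gray zone between the at-risk and intervention thresholds
#'
#' @param lower At-risk threshold (score units): below it a worker needs no
#'   follow-up; at or above it, closer surveillance.
#' @param upper Intervention threshold: above it urgent action is required.
#' @param bootstrap_ci,tgroc_zone Optional source intervals.
#' @param merge_rule Label of the rule that produced the zone.
#' @return An object of class `gray_zone`.
#' @export
gray_zone <- function(lower, upper, bootstrap_ci = NULL, tgroc_zone = NULL,
                      merge_rule = "manual") {
  if (lower > upper + SCORE_TOL) stop("lower must be <= upper", call. = FALSE)
  structure(list(lower = lower, upper = upper,
                 bootstrap_ci = bootstrap_ci, tgroc_zone = tgroc_zone,
                 merge_rule = merge_rule),
            class = "gray_zone")
}

zone_bounds <- function(zone) {
  if (inherits(zone, "gray_zone")) c(zone$lower, zone$upper)
  else if (is.numeric(zone) && length(zone) == 2L) as.numeric(zone)
  else stop("zone must be a gray_zone or c(lower, upper)", call. = FALSE)
}

#' @export
print.gray_zone <- function(x, ...) {
  cat(sprintf("gray zone: %.1f (at-risk) to %.1f (intervention)\n",
              x$lower, x$upper))
  if (!is.null(x$bootstrap_ci)) {
    cat(sprintf("  bootstrap 95%% CI: %.1f-%.1f\n",
                x$bootstrap_ci[1], x$bootstrap_ci[2]))
  }
  if (!is.null(x$tgroc_zone)) {
    cat(sprintf("  TG-ROC zone:      %.1f-%.1f\n",
                x$tgroc_zone[1], x$tgroc_zone[2]))
  }
  invisible(x)
}
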