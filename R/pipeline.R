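# End-to-end analysis: descriptives, ROC, cut-points, gray zone, and
# three-zone classification, collected into a machine-readable report.

#' Analysis configuration
#'
#' @param pss_cutoff Reference cut-off on the PSS14 scale (default 7.2,
#'   strictly inside (0, 10)).
#' @param bootstrap A [bootstrap_config()].
#' @param tgroc A [tgroc_config()].
#' @param criteria Cut-point criteria to report (default all three).
#' @param seed Master seed; per-stage seeds are derived from it so every
#'   stage is individually reproducible.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(pss_cutoff = 7.2,
                            bootstrap = bootstrap_config(),
                            tgroc = tgroc_config(),
                            criteria = c("youden", "product", "closest01"),
                            seed = 1L) {
  if (pss_cutoff <= 0 || pss_cutoff >= 10) {
    stop("pss_cutoff must lie strictly inside (0, 10)", call. = FALSE)
  }
  criteria <- match.arg(criteria, several.ok = TRUE)
  structure(list(pss_cutoff = pss_cutoff, bootstrap = bootstrap,
                 tgroc = tgroc, criteria = criteria, seed = as.integer(seed)),
            class = "analysis_config")
}

zone_labels <- function() c("no_followup", "at_risk", "intervention")

#' Classify workers into the three stress zones
#'
#' `vas < lower` is no-follow-up; `lower <= vas <= upper` (both bounds
#' inclusive) is at-risk; `vas > upper` is intervention.
#'
#' @param vas Numeric VAS score(s) in \[0, 10\].
#' @param zone A [gray_zone()] or numeric `c(lower, upper)`.
#' @return Character vector of zone labels, one per score.
#' @export
classify_workers <- function(vas, zone) {
  b <- zone_bounds(zone)
  if (anyNA(vas) || any(vas < -SCORE_TOL | vas > 10 + SCORE_TOL)) {
    stop("vas scores must be inside [0, 10] and non-missing", call. = FALSE)
  }
  ifelse(vas < b[1] - SCORE_TOL, "no_followup",
         ifelse(vas > b[2] + SCORE_TOL, "intervention", "at_risk"))
}

#' @rdname classify_workers
#' @export
classify_worker <- function(vas, zone) {
  stopifnot(length(vas) == 1L)
  classify_workers(vas, zone)
}

# Stage seeds derived from the master seed by a fixed scheme, kept below
# 2^31 so they are valid R integers.
derive_stage_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("boot_stratified", "boot_unstratified", "smoother", "spare")
  s
}

#' Run the full two-threshold analysis
#'
#' Executes, in order: cohort summary, participant-table descriptives
#' (gender by reference class via the 'N-1' chi-squared test, age and VAS by
#' Mann-Whitney, medians with IQR), Spearman correlation of the two scores,
#' ROC with Mann-Whitney AUC and DeLong CI, optimal single cut-point under
#' each requested criterion, bootstrap cut-point distributions (stratified
#' and unstratified) with percentile intervals, the TG-ROC inconclusive
#' zone, the merged gray zone, and the three-zone classification. Fully
#' deterministic given `config$seed`.
#'
#' @param x A [cohort].
#' @param config An [analysis_config()].
#' @return A list of class `stress_report`; see [render_report()].
#' @export
run_analysis <- function(x, config = analysis_config()) {
  stopifnot(is_cohort(x), inherits(config, "analysis_config"))
  seeds <- derive_stage_seeds(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  cutoff <- config$pss_cutoff
  pos <- x$pss14 >= cutoff - SCORE_TOL

  summary <- stage("summarize", summarize_cohort(x, cutoff))

  table1 <- stage("descriptives", {
    gender_tab <- table(factor(ifelse(pos, "pos", "neg"),
                               levels = c("neg", "pos")),
                        factor(x$gender, levels = .gender_levels))
    list(
      gender_test = if (all(rowSums(gender_tab) > 0) &&
                        all(colSums(gender_tab) > 0))
        n1_chi2(t(gender_tab)) else NULL,
      age_test = if (!all(is.na(x$age)))
        mann_whitney(x$age[!pos], x$age[pos]) else NULL,
      vas_test = mann_whitney(x$vas[!pos], x$vas[pos]),
      vas_by_group = list(negative = median_iqr(x$vas[!pos]),
                          positive = median_iqr(x$vas[pos])),
      age_by_group = if (!all(is.na(x$age)))
        list(negative = median_iqr(x$age[!pos]),
             positive = median_iqr(x$age[pos])) else NULL
    )
  })

  correlation <- stage("correlation", spearman_rho(x$pss14, x$vas))
  roc <- stage("roc", build_roc(x, cutoff))
  auc <- stage("delong", delong_ci(x, cutoff, level = config$bootstrap$level))

  thresholds <- stage("cutpoints", {
    out <- lapply(config$criteria, function(cr) optimal_threshold(roc, cr))
    names(out) <- config$criteria
    out
  })

  boot <- stage("bootstrap", {
    run_boot <- function(stratified, seed) {
      cfg <- bootstrap_config(config$bootstrap$n_boot, config$bootstrap$level,
                              stratified = stratified, seed = seed)
      draws <- lapply(config$criteria, function(cr) {
        bootstrap_thresholds(x, cutoff, cr, cfg)
      })
      names(draws) <- config$criteria
      list(draws = draws,
           ci = lapply(draws, percentile_ci, level = config$bootstrap$level))
    }
    list(stratified = run_boot(TRUE, seeds[["boot_stratified"]]),
         unstratified = run_boot(FALSE, seeds[["boot_unstratified"]]))
  })

  tgroc <- stage("tgroc", tgroc_zone(roc, config$tgroc))

  zone <- stage("merge", {
    primary <- config$criteria[1]
    merge_gray_zone(boot$stratified$ci[[primary]], as.numeric(tgroc))
  })

  classification <- stage("classify", {
    labels <- classify_workers(x$vas, zone)
    counts <- table(factor(labels, levels = zone_labels()))
    single <- thresholds[[1]]$value
    list(labels = labels,
         counts = as.list(counts),
         single_threshold = single,
         single_threshold_count = sum(x$vas >= single - SCORE_TOL),
         missed_by_single = sum(x$vas >= zone$lower - SCORE_TOL &
                                x$vas < single - SCORE_TOL),
         zone_summary = zone_mean_sd(x, zone))
  })

  structure(list(
    cohort_summary = summary,
    correlation = correlation,
    table1 = table1,
    auc = auc,
    thresholds = thresholds,
    bootstrap = boot,
    tgroc_zone = as.numeric(tgroc),
    tgroc_curves = attr(tgroc, "curves"),
    gray_zone = zone,
    classification = classification,
    config = config,
    stage_seeds = as.list(seeds),
    software = list(package = "grayzone",
                    version = as.character(utils::packageVersion("grayzone")))
  ), class = "stress_report")
}

#' @export
print.stress_report <- function(x, ...) {
  s <- x$cohort_summary
  cat(sprintf("Two-threshold stress-screening analysis (n = %d)\n", s$n))
  cat(sprintf("  PSS14 >= %.1f: %d workers (%.1f%%)\n",
              s$pss_cutoff, s$n_positive, 100 * s$prevalence))
  cat(sprintf("  Spearman rho(pss14, vas) = %.2f (p %s)\n",
              x$correlation$rho, format_p(x$correlation$p_value)))
  cat(sprintf("  AUC = %.2f (%.0f%% CI: %.2f-%.2f)\n", x$auc$auc,
              100 * x$auc$level, x$auc$ci_low, x$auc$ci_high))
  for (cr in names(x$thresholds)) {
    t <- x$thresholds[[cr]]
    cat(sprintf("  cut-point (%s): %.1f  se %.2f  sp %.2f\n",
                cr, t$value, t$se, t$sp))
  }
  print(x$gray_zone)
  cc <- x$classification$counts
  cat(sprintf("  zones: %d no-follow-up / %d at-risk / %d intervention\n",
              cc$no_followup, cc$at_risk, cc$intervention))
  invisible(x)
}

#' Render an analysis report
#'
#' `"json"` writes a schema-stable JSON document that round-trips through
#' `jsonlite`; `"text"` writes a human-readable summary following the usual
#' reporting conventions (p-values as `<0.05` / `<0.001`, cut-points to one
#' decimal, AUC to two decimals).
#'
#' @param report A `stress_report` from [run_analysis()].
#' @param format `"json"` or `"text"`.
#' @param path Output path; `NULL` returns the rendered string.
#' @return The rendered string, invisibly if written to `path`.
#' @export
render_report <- function(report, format = c("json", "text"), path = NULL) {
  stopifnot(inherits(report, "stress_report"))
  format <- match.arg(format)
  out <- if (format == "json") render_json(report) else render_text(report)
  if (is.null(path)) return(out)
  writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

render_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "data.frame")) return(as.list(as.data.frame(x)))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  body <- strip(list(
    schema = "grayzone-report/1",
    cohort_summary = report$cohort_summary,
    correlation = report$correlation,
    table1 = report$table1,
    auc = report$auc,
    thresholds = report$thresholds,
    bootstrap = list(
      stratified = list(ci = report$bootstrap$stratified$ci,
                        draws = report$bootstrap$stratified$draws),
      unstratified = list(ci = report$bootstrap$unstratified$ci,
                          draws = report$bootstrap$unstratified$draws)
    ),
    tgroc_zone = report$tgroc_zone,
    gray_zone = report$gray_zone,
    classification = report$classification[c("counts", "single_threshold",
                                             "single_threshold_count",
                                             "missed_by_single")],
    config = list(pss_cutoff = report$config$pss_cutoff,
                  n_boot = report$config$bootstrap$n_boot,
                  level = report$config$bootstrap$level,
                  goal = report$config$tgroc$goal,
                  smoother = report$config$tgroc$smoother,
                  criteria = report$config$criteria,
                  seed = report$config$seed),
    stage_seeds = report$stage_seeds,
    software = report$software
  ))
  jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

render_text <- function(report) {
  s <- report$cohort_summary
  cc <- report$classification$counts
  z <- report$gray_zone
  lines <- c(
    sprintf("Cohort: n = %d (%d men, %d women)", s$n, s$n_male, s$n_female),
    sprintf("PSS14 %.1f +/- %.1f; VAS %.1f +/- %.1f",
            s$pss_mean_sd[["mean"]], s$pss_mean_sd[["sd"]],
            s$vas_mean_sd[["mean"]], s$vas_mean_sd[["sd"]]),
    sprintf("Reference positives (PSS14 >= %.1f): %d (%.1f%%)",
            s$pss_cutoff, s$n_positive, 100 * s$prevalence),
    sprintf("Spearman rho = %.2f (p %s)",
            report$correlation$rho, format_p(report$correlation$p_value)),
    sprintf("AUC = %.2f (%.0f%% CI: %.2f-%.2f)", report$auc$auc,
            100 * report$auc$level, report$auc$ci_low, report$auc$ci_high),
    vapply(names(report$thresholds), function(cr) {
      t <- report$thresholds[[cr]]
      sprintf("Cut-point (%s): %.1f  se = %.2f (%.2f-%.2f)  sp = %.2f (%.2f-%.2f)",
              cr, t$value, t$se, t$se_ci[1], t$se_ci[2],
              t$sp, t$sp_ci[1], t$sp_ci[2])
    }, character(1)),
    sprintf("Bootstrap 95%% CI (stratified, %s): %.1f-%.1f",
            names(report$thresholds)[1],
            report$bootstrap$stratified$ci[[1]][1],
            report$bootstrap$stratified$ci[[1]][2]),
    sprintf("TG-ROC inconclusive zone: %.1f-%.1f",
            report$tgroc_zone[1], report$tgroc_zone[2]),
    sprintf("Gray zone: %.1f (at-risk) to %.1f (intervention)",
            z$lower, z$upper),
    sprintf("Zones: %d no-follow-up / %d at-risk / %d intervention",
            cc$no_followup, cc$at_risk, cc$intervention),
    sprintf("Single cut-point %.1f flags %d workers; %d additional at-risk workers lie in [%.1f, %.1f)",
            report$classification$single_threshold,
            report$classification$single_threshold_count,
            report$classification$missed_by_single,
            z$lower, report$classification$single_threshold)
  )
  paste(lines, collapse = "\n")
}
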