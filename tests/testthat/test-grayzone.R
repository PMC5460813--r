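test_that("percentile_ci equals hand-computed interpolated quantiles", {
  expect_equal(percentile_ci(rep(6.8, 1000)), c(6.8, 6.8))
  # 1..100 at level 0.95: order-statistic interpolation gives
  # 1 + 0.025*99 and 1 + 0.975*99
  expect_equal(percentile_ci(1:100, 0.95), c(3.475, 97.525))
  expect_error(percentile_ci(6.8), "at least 2")
  expect_error(percentile_ci(1:10, 1), "level")
})

test_that("percentile_ci is equivariant under monotone affine rescaling", {
  set.seed(21)
  v <- rnorm(400, 5, 2)
  base <- percentile_ci(v, 0.9)
  expect_equal(percentile_ci(3 * v + 1, 0.9), 3 * base + 1)
})

test_that("bootstrap threshold draws are reproducible and bounded by separation", {
  co <- generate_separable_cohort(30, 8, gap = 3, seed = 22)
  pos <- co$pss14 >= 7.2
  gap_lo <- max(co$vas[!pos])
  gap_hi <- min(co$vas[pos])
  cfg <- bootstrap_config(n_boot = 200, seed = 23, stratified = TRUE)
  d1 <- bootstrap_thresholds(co, 7.2, "youden", cfg)
  d2 <- bootstrap_thresholds(co, 7.2, "youden", cfg)
  expect_identical(d1, d2)
  expect_length(d1, 200L)
  # with a wide gap every replicate's optimum is the lowest positive value
  # present in the replicate: always above every negative, always one of
  # the observed positive scores
  expect_true(all(d1 > gap_lo))
  expect_true(all(d1 %in% co$vas[pos]))
  ci <- percentile_ci(d1)
  expect_lte(ci[2] - ci[1], 3)   # positives span at most the gap's width here
})

test_that("unstratified resampling redraws degenerate replicates", {
  # 2 positives in 12 workers: replicates with no positive are common and
  # must be redrawn, never skipped
  co <- toy_cohort(round(runif(10, 0, 5), 1), c(8, 9))
  cfg <- bootstrap_config(n_boot = 150, seed = 24, stratified = FALSE)
  d <- bootstrap_thresholds(co, 7.2, "youden", cfg)
  expect_length(d, 150L)
  expect_gt(attr(d, "redraws"), 0L)
  # stratified resampling never needs redraws
  d2 <- bootstrap_thresholds(co, 7.2, "youden",
                             bootstrap_config(n_boot = 150, seed = 24))
  expect_equal(attr(d2, "redraws"), 0L)
})

test_that("bootstrap_thresholds validates its input", {
  expect_error(bootstrap_config(n_boot = 50), "n_boot")
  one_class <- cohort(data.frame(id = 1:6, pss14 = rep(2, 6),
                                 vas = round(seq(1, 6, by = 1), 1)))
  expect_error(bootstrap_thresholds(one_class,
                                    config = bootstrap_config(seed = 1)),
               "ROC undefined")
})

test_that("tgroc_zone reads crossings off constructed step curves", {
  # 20 positives with 18 at or above 6.0 (se crosses 0.90 at 6.0) and
  # 20 negatives with 18 below 7.5 (sp crosses 0.90 at 7.5); with the raw
  # step curves ("isotonic") the inconclusive set {se <= 0.9 & sp <= 0.9}
  # is exactly [6.0, 7.5] and can be verified by direct counting
  vas_neg <- round(c(seq(0.5, 5.6, by = 0.3), 7.5, 8.5), 1)
  vas_pos <- round(c(5.0, 5.9, seq(6.0, 9.4, by = 0.2)), 1)
  co <- toy_cohort(vas_neg, vas_pos)
  roc <- build_roc(co)
  zone <- tgroc_zone(roc, tgroc_config(smoother = "isotonic"))
  expect_equal(as.numeric(zone), c(6.0, 7.5))
  grid <- seq(0, 10, by = 0.1)
  se_fun <- function(t) mean(vas_pos >= t - 1e-9)
  sp_fun <- function(t) mean(vas_neg < t - 1e-9)
  keep <- vapply(grid, function(t) se_fun(t) <= 0.9 + 1e-9 &&
                   sp_fun(t) <= 0.9 + 1e-9, logical(1))
  expect_equal(as.numeric(zone), range(grid[keep]))
})

test_that("tgroc endpoints converge to the analytic 0.90 quantiles", {
  # classes drawn from known truncated normals; where the true Se(t) and
  # Sp(t) equal the goal is a closed-form quantile of each marginal
  qtn <- function(p, mean, sd) {
    lo <- pnorm(0, mean, sd); hi <- pnorm(10, mean, sd)
    qnorm(lo + p * (hi - lo), mean, sd)
  }
  set.seed(25)
  n <- 20000
  vas_neg <- round(qtn(runif(n), 3.5, 2), 1)
  vas_pos <- round(qtn(runif(n / 4), 7.5, 1.2), 1)
  co <- toy_cohort(vas_neg, vas_pos)
  roc <- build_roc(co)
  t_se <- qtn(0.10, 7.5, 1.2)     # Se(t) = P(pos >= t) crosses 0.90
  t_sp <- qtn(0.90, 3.5, 2)       # Sp(t) = P(neg < t) crosses 0.90
  for (sm in c("monotone_spline", "isotonic", "none")) {
    zone <- tgroc_zone(roc, tgroc_config(smoother = sm))
    expect_lt(abs(zone[1] - t_se), 0.2)
    expect_lt(abs(zone[2] - t_sp), 0.2)
  }
})

test_that("an empty inconclusive set collapses to the crossing point", {
  co <- generate_separable_cohort(40, 15, gap = 4, seed = 26)
  zone <- tgroc_zone(build_roc(co), tgroc_config(smoother = "isotonic"))
  expect_equal(zone[1], zone[2])
  cur <- attr(zone, "curves")
  expect_true(all(diff(cur$se) <= 1e-9))
  expect_true(all(diff(cur$sp) >= -1e-9))
})

test_that("merge_gray_zone takes the interval hull", {
  z <- merge_gray_zone(c(5.0, 8.2), c(6.0, 7.5))
  expect_equal(c(z$lower, z$upper), c(5.0, 8.2))
  expect_equal(z$bootstrap_ci, c(5.0, 8.2))
  expect_equal(z$tgroc_zone, c(6.0, 7.5))

  same <- merge_gray_zone(c(6.0, 7.5), c(6.0, 7.5))
  expect_equal(c(same$lower, same$upper), c(6.0, 7.5))

  expect_warning(dj <- merge_gray_zone(c(1, 2), c(4, 5)), "disjoint")
  expect_equal(c(dj$lower, dj$upper), c(1, 5))

  expect_error(gray_zone(3, 2), "lower")
})

test_that("the bootstrap interval narrows as the cohort grows", {
  # the stochastic half of the gray zone localizes with n; the TG-ROC half
  # converges to the population inconclusive zone, which has fixed width,
  # so the shrinkage property belongs to the bootstrap interval
  # averaged over replicate cohorts: a single realization is noisy
  width_at <- function(n, seed) {
    co <- generate_cohort(synthetic_config(n = n, seed = seed))
    ci <- percentile_ci(bootstrap_thresholds(
      co, 7.2, "youden", bootstrap_config(n_boot = 300, seed = seed)))
    ci[2] - ci[1]
  }
  w <- vapply(c(500, 2000, 8000), function(n) {
    mean(vapply(61:65, function(s) width_at(n, s), numeric(1)))
  }, numeric(1))
  expect_gt(w[1], w[2])
  expect_gt(w[2], w[3])
})
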