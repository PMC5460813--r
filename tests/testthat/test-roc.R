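test_that("build_roc matches direct counting at every threshold", {
  set.seed(11)
  for (i in 1:10) {
    co <- random_toy_cohort(sample(5:25, 1), sample(2:10, 1))
    roc <- build_roc(co)
    pos <- co$pss14 >= 7.2
    for (k in seq_len(nrow(roc$points))) {
      expected <- oracle_se_sp(co$vas[!pos], co$vas[pos],
                               roc$points$threshold[k])
      expect_equal(roc$points$se[k], expected[["se"]])
      expect_equal(roc$points$sp[k], expected[["sp"]])
    }
    # curve shape: se non-increasing, sp non-decreasing, se = 1 first
    expect_true(all(diff(roc$points$se) <= 0))
    expect_true(all(diff(roc$points$sp) >= 0))
    expect_equal(roc$points$se[1], 1)
    expect_equal(roc$points$sp[1], 0)
  }
})

test_that("a separable cohort has a perfect operating point", {
  co <- generate_separable_cohort(5, 5, gap = 2, seed = 12)
  roc <- build_roc(co)
  expect_true(any(roc$points$se == 1 & roc$points$sp == 1))
  opt <- optimal_threshold(roc, "youden")
  expect_equal(opt$j, 1)
})

test_that("single-class cohorts are rejected", {
  co <- cohort(data.frame(id = 1:4, pss14 = rep(1, 4), vas = 1:4))
  expect_error(build_roc(co), "ROC undefined")
  expect_error(roc_auc(co), "ROC undefined")
})

test_that("roc_auc equals the all-pairs oracle and handles ties", {
  set.seed(13)
  for (i in 1:10) {
    co <- random_toy_cohort(sample(4:12, 1), sample(2:8, 1))
    pos <- co$pss14 >= 7.2
    expect_equal(roc_auc(co)$auc, oracle_auc(co$vas[!pos], co$vas[pos]))
  }
  allties <- toy_cohort(rep(5, 6), rep(5, 4))
  expect_equal(roc_auc(allties)$auc, 0.5)
})

test_that("trapezoidal area under the empirical curve equals the rank AUC", {
  set.seed(14)
  for (i in 1:8) {
    co <- random_toy_cohort(sample(10:40, 1), sample(3:12, 1))
    p <- build_roc(co)$points
    fpr <- c(1 - p$sp, 0)          # descending from 1 to 0 with sentinel end
    tpr <- c(p$se, 0)
    area <- sum((fpr[-length(fpr)] - fpr[-1]) *
                  (tpr[-length(tpr)] + tpr[-1]) / 2)
    expect_equal(area, roc_auc(co)$auc)
  }
})

test_that("AUC is invariant under strictly monotone transforms of vas", {
  set.seed(15)
  co <- random_toy_cohort(20, 6)
  base <- roc_auc(co)$auc
  tr <- co
  tr$vas <- 10 * (exp(tr$vas / 10) - 1) / (exp(1) - 1)   # off-grid on purpose
  tr <- suppressWarnings(cohort(as.data.frame(tr)))
  expect_equal(roc_auc(tr)$auc, base)
})

test_that("delong_ci reproduces the nested-loop placement-value variance", {
  set.seed(16)
  for (i in 1:8) {
    co <- random_toy_cohort(6, 4)
    pos <- co$pss14 >= 7.2
    est <- delong_ci(co, level = 0.95)
    v <- oracle_delong_var(co$vas[!pos], co$vas[pos])
    half <- qnorm(0.975) * sqrt(v)
    expect_equal(est$auc, oracle_auc(co$vas[!pos], co$vas[pos]))
    expect_equal(est$ci_low, max(0, est$auc - half))
    expect_equal(est$ci_high, min(1, est$auc + half))
  }
})

test_that("delong_ci agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  co <- random_toy_cohort(60, 12)
  est <- delong_ci(co)
  ref <- pROC::ci.auc(pROC::roc(response = as.integer(co$pss14 >= 7.2),
                                predictor = co$vas, levels = c(0, 1),
                                direction = "<", quiet = TRUE),
                      method = "delong")
  expect_equal(est$auc, as.numeric(ref[2]))
  expect_equal(est$ci_low, max(0, as.numeric(ref[1])), tolerance = 1e-10)
  expect_equal(est$ci_high, min(1, as.numeric(ref[3])), tolerance = 1e-10)
})

test_that("delong_ci degenerates and narrows as theory says", {
  sep <- generate_separable_cohort(6, 4, gap = 3, seed = 18)
  est <- delong_ci(sep)
  expect_equal(c(est$auc, est$ci_low, est$ci_high), c(1, 1, 1))

  tiny <- toy_cohort(c(1, 2, 3), 5)
  expect_error(delong_ci(tiny), ">= 2")

  set.seed(19)
  width <- vapply(c(100, 800, 6400), function(n) {
    co <- toy_cohort(round(rnorm(n, 4, 2) %% 10, 1),
                     round(rnorm(n / 4, 6, 2) %% 10, 1))
    e <- delong_ci(co)
    e$ci_high - e$ci_low
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})

test_that("optimal_threshold matches an exhaustive independent scan", {
  set.seed(20)
  co <- random_toy_cohort(9, 3)
  roc <- build_roc(co)
  p <- roc$points
  for (cr in c("youden", "product", "closest01")) {
    got <- optimal_threshold(roc, cr)
    score <- switch(cr,
      youden = p$se + p$sp - 1,
      product = p$se * p$sp,
      closest01 = -sqrt((1 - p$se)^2 + (1 - p$sp)^2))
    expect_equal(got$value, max(p$threshold[score == max(score)]))
    # reported optimum is >= the criterion value at every candidate
    at_got <- score[p$threshold == got$value]
    expect_true(all(score <= at_got + 1e-12))
    expect_equal(got$j, got$se + got$sp - 1)
    expect_true(got$value %in% p$threshold)
  }
})

test_that("threshold ties break towards specificity by default", {
  # thresholds 4 and 8 attain the same Youden index; the higher must win
  co <- toy_cohort(c(1, 4), c(4, 8))
  roc <- build_roc(co)
  hi <- optimal_threshold(roc, "youden")
  lo <- optimal_threshold(roc, "youden", tie = "lowest")
  expect_gt(hi$value, lo$value)
  expect_equal(hi$j, lo$j)
})

test_that("wilson_ci reproduces its closed form and boundary behaviour", {
  # the sensitivity count 8/9 gives the interval printed for se = 0.89
  expect_equal(round(wilson_ci(8, 9), 2), c(0.57, 0.98))
  expect_equal(wilson_ci(8, 9), c(0.5650002944, 0.9801091124),
               tolerance = 1e-9)
  # the specificity count 425/491 gives the interval printed for sp = 0.87
  expect_equal(round(wilson_ci(425, 491), 2), c(0.83, 0.89))
  # direct closed-form oracle at another count
  z <- qnorm(0.975); p <- 427 / 491; n <- 491
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  expect_equal(wilson_ci(427, 491), c(centre - half, centre + half))
  # saturated counts pin the boundary exactly
  expect_equal(wilson_ci(9, 9)[2], 1)
  expect_equal(wilson_ci(0, 9)[1], 0)
  expect_error(wilson_ci(1, 0), "trials")
  expect_error(wilson_ci(5, 4), "between")
  # Clopper-Pearson option against the stock exact test
  cp <- wilson_ci(8, 9, method = "clopper_pearson")
  ref <- binom.test(8, 9)$conf.int
  expect_equal(cp, as.numeric(ref))
})
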