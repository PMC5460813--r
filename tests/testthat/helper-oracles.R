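# Brute-force oracles and toy-cohort builders, kept independent of the
# package's own computation paths.

# cohort with explicit class membership: negatives get pss14 = 0,
# positives pss14 = 10, so any cutoff in (0, 10) recovers the classes
toy_cohort <- function(vas_neg, vas_pos) {
  cohort(data.frame(id = seq_len(length(vas_neg) + length(vas_pos)),
                    pss14 = rep(c(0, 10), c(length(vas_neg), length(vas_pos))),
                    vas = c(vas_neg, vas_pos)))
}

random_toy_cohort <- function(n_neg, n_pos) {
  toy_cohort(round(runif(n_neg, 0, 8), 1), round(runif(n_pos, 2, 10), 1))
}

# all-pairs Mann-Whitney AUC: explicit double loop, ties half-weighted
oracle_auc <- function(vas_neg, vas_pos) {
  s <- 0
  for (p in vas_pos) for (q in vas_neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(vas_pos) * length(vas_neg))
}

# DeLong variance via explicit nested loops over placement values
oracle_delong_var <- function(vas_neg, vas_pos) {
  m <- length(vas_pos); n <- length(vas_neg)
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  v10 <- vapply(vas_pos, function(xi) {
    mean(vapply(vas_neg, function(yj) psi(xi, yj), numeric(1)))
  }, numeric(1))
  v01 <- vapply(vas_neg, function(yj) {
    mean(vapply(vas_pos, function(xi) psi(xi, yj), numeric(1)))
  }, numeric(1))
  s10 <- sum((v10 - mean(v10))^2) / (m - 1)
  s01 <- sum((v01 - mean(v01))^2) / (n - 1)
  s10 / m + s01 / n
}

# direct counting of se/sp at a threshold (positive test: vas >= t)
oracle_se_sp <- function(vas_neg, vas_pos, t) {
  c(se = mean(vas_pos >= t - 1e-9),
    sp = mean(vas_neg < t - 1e-9))
}

# exact two-sided Mann-Whitney p by enumerating group assignments
oracle_mw_p <- function(a, b) {
  pool <- c(a, b); r <- rank(pool)
  n1 <- length(a); n <- length(pool)
  mu <- n1 * (n - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(n, n1)
  us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
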