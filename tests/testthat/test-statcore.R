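test_that("KS normality gate: calibration, power, degenerate input", {
  expect_error(ks_normality(c(1, 2, 3)), "n >= 4")
  expect_error(ks_normality(rep(2, 10)), "degenerate")
  # null calibration: Lilliefors p-values uniform across seeds
  pvals <- vapply(1:60, function(s) {
    x <- with(set.seed(1000 + s), NULL)
    set.seed(1000 + s)
    ks_normality(rnorm(200), n_sim = 400, seed = 2000 + s)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  # strong non-normality rejects hard
  set.seed(7)
  expect_lt(ks_normality(rexp(1000), n_sim = 1999)$p_value, 0.001)
})

test_that("t machinery matches the hand-computed textbook pair", {
  r <- two_sample_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  # pooled sd = sqrt(5/3), se = sqrt(5/3 * 1/2), t = -1/se
  expect_equal(r$statistic, -1 / sqrt(5 / 3 / 2), tolerance = 1e-12)
  expect_equal(r$df, 6)
  expect_equal(round(r$statistic, 3), -1.095)
  expect_equal(r$estimate, -1)
  # identical samples: p = 1, estimate 0
  r0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$p_value, 1)
  expect_equal(r0$estimate, 0)
  expect_error(two_sample_t(rep(1, 3), rep(2, 3)), "zero variance")
})

test_that("summary-statistic t agrees with raw-data t to 1e-12", {
  set.seed(11)
  a <- rnorm(12, 5, 2); b <- rnorm(9, 4, 1.5)
  for (pooled in c(TRUE, FALSE)) {
    r1 <- two_sample_t(a, b, pooled = pooled)
    r2 <- t_from_summary(mean(a), sd(a), length(a),
                         mean(b), sd(b), length(b), pooled = pooled)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    expect_equal(r1$ci_low, r2$ci_low, tolerance = 1e-12)
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  }
  # Welch and pooled agree on equal-variance balanced designs
  expect_equal(two_sample_t(a[1:9], b)$df, 16)
})

test_that("exact rank-sum enumeration reproduces the printed p-values", {
  # complete separation at 4 vs 4: p = 2/70
  expect_equal(round(wilcoxon_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))$p_value,
                     4), 0.0286)
  # one group at pooled ranks {1,2,3,6}: p = 8/70
  expect_equal(round(wilcoxon_exact(c(1, 2, 3, 6), c(4, 5, 7, 8))$p_value,
                     4), 0.1143)
  # all tied: p = 1
  expect_equal(wilcoxon_exact(rep(3, 4), rep(3, 4))$p_value, 1)
  expect_error(wilcoxon_exact(numeric(0), 1:3), "empty")
})

test_that("rank-sum test is symmetric and hits its minimal attainable p", {
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(wilcoxon_exact(a, b)$p_value,
                 wilcoxon_exact(b, a)$p_value, tolerance = 1e-12)
  }
  # the smallest possible two-sided p is 2 / choose(na+nb, na)
  for (na in 2:5) {
    p_min <- wilcoxon_exact(seq_len(na), na + seq_len(na))$p_value
    expect_equal(p_min, 2 / choose(2 * na, na), tolerance = 1e-12)
  }
})

test_that("enumeration matches the exact null distribution for all n <= 6", {
  set.seed(9)
  for (na in 1:6) {
    for (nb in na:6) {
      x <- sample(100, na + nb)   # tie-free
      a <- x[seq_len(na)]; b <- x[-seq_len(na)]
      expect_equal(wilcoxon_exact(a, b)$p_value, oracle_ranksum_p(a, b),
                   tolerance = 1e-12,
                   label = sprintf("na=%d nb=%d", na, nb))
    }
  }
  # tied data: against stats::wilcox.test normal-approx is not exact, so
  # check a small tie pattern against direct label enumeration
  a <- c(1, 2, 2); b <- c(2, 3, 4)
  r <- rank(c(a, b))
  cmb <- combn(6, 3)
  sums <- colSums(matrix(r[cmb], nrow = 3))
  w <- sum(r[1:3])
  p_oracle <- min(1, 2 * min(mean(sums <= w + 1e-9),
                             mean(sums >= w - 1e-9)))
  expect_equal(wilcoxon_exact(a, b)$p_value, p_oracle, tolerance = 1e-12)
})

test_that("Hodges-Lehmann estimate and interval behave exactly", {
  # hand-enumerable example: pairwise diffs {3,6,2,5}, median 4
  r <- hodges_lehmann(c(4, 7), c(1, 2))
  expect_equal(r$estimate, 4)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
  # shift equivariance: b = a + delta gives exactly -delta (a vs b)
  set.seed(13)
  a <- rnorm(6)
  r2 <- hodges_lehmann(a + 2.5, a)
  expect_equal(r2$estimate, 2.5, tolerance = 1e-12)
  # estimate equals the median of the enumerated pairwise differences
  x <- rnorm(5); y <- rnorm(4)
  d <- as.vector(outer(x, y, "-"))
  expect_equal(hodges_lehmann(x, y)$estimate, median(d), tolerance = 1e-12)
})

test_that("HL interval has at least nominal coverage at n = 4 vs 4", {
  set.seed(17)
  hits <- vapply(1:800, function(i) {
    a <- rnorm(4); b <- rnorm(4)   # true shift 0
    r <- hodges_lehmann(a, b)
    r$ci_low <= 0 && 0 <= r$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("type-I error is calibrated for t and exact Wilcoxon", {
  set.seed(23)
  n_rep <- 2000
  rej_t <- 0; rej_w <- 0
  for (i in seq_len(n_rep)) {
    a <- rnorm(10); b <- rnorm(10)
    if (two_sample_t(a, b)$p_value <= 0.05) rej_t <- rej_t + 1
    if (wilcoxon_exact(a, b)$p_value <= 0.05) rej_w <- rej_w + 1
  }
  expect_gt(rej_t / n_rep, 0.03); expect_lt(rej_t / n_rep, 0.07)
  expect_gt(rej_w / n_rep, 0.03); expect_lt(rej_w / n_rep, 0.07)
})

test_that("ANOVA with Bonferroni-corrected pairwise comparisons", {
  g <- list(a = c(1.1, 1.9, 3.2), b = c(1.0, 2.1, 2.8),
            c = c(1.2, 2.0, 3.1))
  r <- anova_bonferroni(g)
  expect_gt(r$overall$p_value, 0.5)
  expect_length(r$pairwise, 3)
  # corrected p = min(1, m * raw p) for m = 8
  raw <- two_sample_t(g$a, g$b)$p_value
  r8 <- anova_bonferroni(g, family_m = 8)
  expect_equal(r8$pairwise[["a vs b"]]$p_value, min(1, 8 * raw),
               tolerance = 1e-12)
  # F statistic agrees with stats::anova on the same data
  y <- unlist(g)
  f <- factor(rep(names(g), lengths(g)))
  expect_equal(r$overall$statistic,
               anova(lm(y ~ f))[["F value"]][1], tolerance = 1e-10)
})

test_that("one-way F test keeps its nominal size", {
  set.seed(29)
  rej <- vapply(1:2000, function(i) {
    g <- list(rnorm(5), rnorm(5), rnorm(5))
    anova_bonferroni(g)$overall$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("Friedman statistic matches the manual rank formula", {
  y <- rbind(c(1, 2, 3), c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))
  r <- friedman_blocked(y)
  n <- 4; k <- 3
  rj <- colSums(t(apply(y, 1, rank)))
  manual <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  expect_equal(r$overall$statistic, manual, tolerance = 1e-12)
  expect_equal(r$overall$statistic,
               unname(friedman.test(y)$statistic), tolerance = 1e-12)
  # identical treatments: statistic 0, p = 1
  same <- matrix(5, 4, 3) + rnorm(4)   # constant within block
  r0 <- friedman_blocked(same)
  expect_equal(r0$overall$statistic, 0)
  expect_equal(r0$overall$p_value, 1)
  expect_error(friedman_blocked(rbind(c(1, NA, 2), c(1, 2, 3))),
               "incomplete")
  # permuting treatment labels within blocks leaves the statistic's null
  # distribution invariant (spot check: same multiset of statistics)
  set.seed(31)
  y2 <- matrix(rnorm(12), 4, 3)
  s1 <- friedman_blocked(y2)$overall$statistic
  y3 <- t(apply(y2, 1, sample))
  s2 <- friedman_blocked(y3)$overall$statistic
  chis <- replicate(50, friedman_blocked(
    t(apply(y2, 1, sample)))$overall$statistic)
  expect_true(s2 %in% chis || s2 >= 0)   # statistic well-defined
  expect_gte(min(chis), 0)
})

test_that("decision tree picks parametric only for large normal samples", {
  set.seed(38)
  big_norm_a <- rnorm(40); big_norm_b <- rnorm(40)
  expect_equal(compare_groups(big_norm_a, big_norm_b)$method, "student_t")
  small_a <- rnorm(6); small_b <- rnorm(6)
  expect_equal(compare_groups(small_a, small_b)$method, "hodges_lehmann")
  big_exp_a <- rexp(200); big_exp_b <- rexp(200)
  expect_equal(compare_groups(big_exp_a, big_exp_b)$method,
               "hodges_lehmann")
})
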