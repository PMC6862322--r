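comparison_result <- function(method, estimate = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              ci_level = NA_real_, p_value,
                              statistic = NA_real_, df = NA_real_,
                              correction = "none", family_m = NA_integer_) {
  stopifnot(p_value > 0, p_value <= 1 + 1e-12)
  structure(list(
    method = method, estimate = estimate,
    ci_low = ci_low, ci_high = ci_high, ci_level = ci_level,
    p_value = min(1, p_value), statistic = statistic, df = df,
    correction = correction, family_m = family_m
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.4g, %s%% CI [%.4g, %.4g], p = %.4g%s\n",
              x$method, x$estimate,
              ifelse(is.na(x$ci_level), "-", format(100 * x$ci_level)),
              x$ci_low, x$ci_high, x$p_value,
              if (x$correction != "none") {
                sprintf(" (%s, m = %d)", x$correction, x$family_m)
              } else ""))
  invisible(x)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS statistic against a normal with mean and SD estimated
#' from the data; since parameters are estimated, the p-value is obtained
#' by seeded Monte-Carlo over normal samples of the same size (the
#' Lilliefors correction).
#'
#' @param x numeric sample, `n >= 4`, non-degenerate.
#' @param n_sim Monte-Carlo replicates.
#' @param seed RNG seed for the null simulation.
#' @return list with `statistic` and `p_value`.
#' @export
ks_normality <- function(x, n_sim = 1999, seed = 1L) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("ks_normality: need n >= 4")
  if (sd(x) == 0) stop("ks_normality: degenerate (constant) sample")
  stat <- lilliefors_stat(x)
  n <- length(x)
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) lilliefors_stat(rnorm(n)),
           numeric(1))
  })
  list(statistic = stat,
       p_value = (1 + sum(sims >= stat - 1e-12)) / (n_sim + 1))
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

t_machinery <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                        pooled = TRUE, ci_level = 0.95) {
  est <- mean_a - mean_b
  if (pooled) {
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
    if (sp2 <= 0) stop("t test: zero variance in both samples")
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    method <- "student_t"
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    if (va + vb <= 0) stop("t test: zero variance in both samples")
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
    method <- "welch_t"
  }
  stat <- est / se
  p <- 2 * pt(-abs(stat), df)
  q <- qt(1 - (1 - ci_level) / 2, df)
  comparison_result(method, est, est - q * se, est + q * se, ci_level,
                    p_value = max(p, .Machine$double.xmin),
                    statistic = stat, df = df)
}

#' Two-sample t-test (pooled Student or Welch)
#'
#' @param a,b numeric samples, each `n >= 2`.
#' @param pooled `TRUE` for the classical pooled-variance Student test
#'   (the default, as reported in this literature), `FALSE` for Welch.
#' @param ci_level confidence level for the mean-difference interval.
#' @return a `comparison_result` (estimate = mean(a) - mean(b)).
#' @export
two_sample_t <- function(a, b, pooled = TRUE, ci_level = 0.95) {
  if (length(a) < 2L || length(b) < 2L) stop("two_sample_t: need n >= 2")
  t_machinery(mean(a), sd(a), length(a), mean(b), sd(b), length(b),
              pooled, ci_level)
}

#' Two-sample t-test from summary statistics
#'
#' Identical formulas to [two_sample_t()] computed from printed
#' mean/SD/n summaries, so published tables can be checked directly.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @param pooled,ci_level see [two_sample_t()].
#' @return a `comparison_result`.
#' @export
t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                           pooled = TRUE, ci_level = 0.95) {
  if (n_a < 2 || n_b < 2) stop("t_from_summary: need n >= 2")
  if (sd_a < 0 || sd_b < 0) stop("t_from_summary: negative sd")
  t_machinery(mean_a, sd_a, n_a, mean_b, sd_b, n_b, pooled, ci_level)
}

# cache of enumerated rank-sum null distributions, keyed by group size and
# the pooled midrank multiset (ties change the distribution)
.ranksum_cache <- new.env(parent = emptyenv())

ranksum_enumeration <- function(ranks, n_a) {
  key <- paste(n_a, paste(round(sort(ranks), 6), collapse = ","),
               sep = "|")
  hit <- .ranksum_cache[[key]]
  if (!is.null(hit)) return(hit)
  cmb <- utils::combn(length(ranks), n_a)
  sums <- colSums(matrix(ranks[cmb], nrow = n_a))
  .ranksum_cache[[key]] <- sums
  sums
}

#' Exact two-sided Wilcoxon rank-sum test by complete enumeration
#'
#' For pooled sizes up to `max_exact` the null distribution of the group-A
#' rank sum is enumerated over all `choose(n_a + n_b, n_a)` rank
#' assignments (midranks under ties, enumerated over the observed tie
#' pattern); the two-sided p-value is `2 * min(P(W <= w), P(W >= w))`
#' capped at 1.  Larger samples fall back to the normal approximation with
#' tie correction.
#'
#' @param a,b numeric samples.
#' @param max_exact largest pooled size for the exact path.
#' @return a `comparison_result` with method `"wilcoxon_exact"` (or
#'   `"wilcoxon_normal"`), p-value only.
#' @export
wilcoxon_exact <- function(a, b, max_exact = 20L) {
  n_a <- length(a); n_b <- length(b)
  if (!n_a || !n_b) stop("wilcoxon_exact: empty sample")
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n_a)])
  if (n_a + n_b <= max_exact) {
    sums <- ranksum_enumeration(r, n_a)
    eps <- 1e-9
    p <- 2 * min(mean(sums <= w + eps), mean(sums >= w - eps))
    comparison_result("wilcoxon_exact", p_value = min(1, p), statistic = w)
  } else {
    mu <- n_a * (n_a + n_b + 1) / 2
    ties <- table(r)
    n <- n_a + n_b
    sig2 <- n_a * n_b / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu) / sqrt(sig2)
    comparison_result("wilcoxon_normal",
                      p_value = max(2 * pnorm(-abs(z)),
                                    .Machine$double.xmin),
                      statistic = w)
  }
}

#' Hodges-Lehmann median difference with exact confidence interval
#'
#' The estimate is the median of all `n_a * n_b` pairwise differences
#' `a_i - b_j`; the confidence bounds are the order statistics of those
#' differences at ranks taken from the exact Mann-Whitney null
#' distribution, giving conservative (>= nominal) coverage.
#'
#' @param a,b numeric samples (estimate is location of `a` minus `b`).
#' @param ci_level nominal confidence level.
#' @return a `comparison_result` with method `"hodges_lehmann"`; its
#'   p-value is the exact rank-sum p from [wilcoxon_exact()].
#' @export
hodges_lehmann <- function(a, b, ci_level = 0.95) {
  if (!length(a) || !length(b)) stop("hodges_lehmann: empty sample")
  d <- sort(as.vector(outer(a, b, "-")))
  est <- stats::median(d)
  n <- length(d)
  alpha <- 1 - ci_level
  k <- stats::qwilcox(alpha / 2, length(a), length(b))
  k <- max(1L, min(k, floor(n / 2)))
  p <- wilcoxon_exact(a, b)$p_value
  comparison_result("hodges_lehmann", est, d[k], d[n + 1L - k], ci_level,
                    p_value = p)
}

#' One-way ANOVA with Bonferroni-corrected pairwise t-tests
#'
#' @param groups named list of numeric vectors (>= 2 groups, each
#'   `n >= 2`).
#' @param family_m Bonferroni family size for the pairwise tests; default
#'   is the number of pairs.
#' @param pooled pairwise tests pooled (Student) or Welch.
#' @return list with `overall` (a `comparison_result` carrying the F test)
#'   and `pairwise` (named list of corrected `comparison_result`s).
#' @export
anova_bonferroni <- function(groups, family_m = NULL, pooled = TRUE) {
  k <- length(groups)
  if (k < 2L) stop("anova_bonferroni: need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("anova_bonferroni: every group needs n >= 2")
  }
  n_i <- vapply(groups, length, 1L)
  m_i <- vapply(groups, mean, 1)
  n <- sum(n_i)
  gm <- sum(n_i * m_i) / n
  ssb <- sum(n_i * (m_i - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- k - 1; df2 <- n - k
  if (ssw <= 0) stop("anova_bonferroni: degenerate groups (zero variance)")
  f <- (ssb / df1) / (ssw / df2)
  overall <- comparison_result(
    "anova", p_value = max(pf(f, df1, df2, lower.tail = FALSE),
                           .Machine$double.xmin),
    statistic = f, df = df1)
  pairs <- utils::combn(k, 2)
  m <- if (is.null(family_m)) ncol(pairs) else family_m
  pw <- list()
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    r <- two_sample_t(groups[[i1]], groups[[i2]], pooled = pooled)
    r$p_value <- min(1, r$p_value * m)
    r$correction <- "bonferroni"
    r$family_m <- as.integer(m)
    pw[[paste(nm[i1], nm[i2], sep = " vs ")]] <- r
  }
  list(overall = overall, pairwise = pw)
}

#' Friedman rank test for complete blocked designs
#'
#' Chi-square approximation with tie correction; pairwise treatment
#' comparisons by Wilcoxon signed-rank with Bonferroni correction.
#'
#' @param y numeric matrix, blocks in rows, treatments in columns
#'   (complete design; >= 2 of each).
#' @param pairwise run the corrected pairwise comparisons.
#' @return list with `overall` (a `comparison_result`) and `pairwise`.
#' @export
friedman_blocked <- function(y, pairwise = TRUE) {
  y <- as.matrix(y)
  if (any(!is.finite(y))) stop("friedman_blocked: incomplete blocks")
  n <- nrow(y); k <- ncol(y)
  if (n < 2L || k < 2L) stop("friedman_blocked: need >= 2 blocks and >= 2 treatments")
  r <- t(apply(y, 1, rank))
  rj <- colSums(r)
  stat_num <- 12 * sum((rj - n * (k + 1) / 2)^2)
  ties <- apply(y, 1, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  })
  denom <- n * k * (k + 1) - sum(ties) / (k - 1)
  if (denom <= 0) {
    overall <- comparison_result("friedman", p_value = 1, statistic = 0,
                                 df = k - 1)
  } else {
    stat <- stat_num / denom
    overall <- comparison_result(
      "friedman",
      p_value = max(pchisq(stat, k - 1, lower.tail = FALSE),
                    .Machine$double.xmin),
      statistic = stat, df = k - 1)
  }
  pw <- NULL
  if (pairwise && k >= 2) {
    pairs <- utils::combn(k, 2)
    m <- ncol(pairs)
    nm <- colnames(y)
    if (is.null(nm)) nm <- paste0("t", seq_len(k))
    pw <- list()
    for (j in seq_len(m)) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      d <- y[, i1] - y[, i2]
      if (all(d == 0)) {
        p_raw <- 1; w_stat <- 0   # no information against the null
      } else {
        wt <- suppressWarnings(
          stats::wilcox.test(y[, i1], y[, i2], paired = TRUE))
        p_raw <- max(wt$p.value, .Machine$double.xmin)
        w_stat <- unname(wt$statistic)
      }
      pw[[paste(nm[i1], nm[i2], sep = " vs ")]] <- comparison_result(
        "signed_rank", p_value = min(1, p_raw * m), statistic = w_stat,
        correction = "bonferroni", family_m = as.integer(m))
    }
  }
  list(overall = overall, pairwise = pw)
}

#' Two-group comparison following the study's decision tree
#'
#' Parametric statistics (Student's t, mean difference) are used when both
#' samples have at least `n_threshold` observations and pass the
#' Kolmogorov-Smirnov normality gate; otherwise the exact Wilcoxon
#' rank-sum test with the Hodges-Lehmann median difference is used.
#'
#' @param a,b numeric samples.
#' @param n_threshold parametric-path sample-size gate (default 30).
#' @param alpha significance level for the normality gate.
#' @param ks_seed seed for the Lilliefors Monte-Carlo.
#' @return a `comparison_result`; `method` records the chosen path.
#' @export
compare_groups <- function(a, b, n_threshold = 30, alpha = 0.05,
                           ks_seed = 1L) {
  parametric <- length(a) >= n_threshold && length(b) >= n_threshold
  if (parametric) {
    parametric <- ks_normality(a, seed = ks_seed)$p_value > alpha &&
      ks_normality(b, seed = ks_seed + 1L)$p_value > alpha
  }
  if (parametric) two_sample_t(a, b) else hodges_lehmann(a, b)
}
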