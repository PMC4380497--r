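test_that("Wilcoxon rank-sum matches exact enumeration and handles ties", {
  # fully separated samples: 2 / C(6,3) = 0.1
  r <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_identical(r$method, "exact")
  expect_equal(r$p, oracle_wilcoxon_p(c(1, 2, 3), c(4, 5, 6)))

  # identical samples (ties force the normal path): p = 1
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # exact vs large-sample path agree within 0.02 at n = 6 + 6
  set.seed(13)
  x <- rnorm(6); y <- rnorm(6, 0.5)
  p_exact <- wilcoxon_ranksum(x, y)$p
  p_norm <- wilcoxon_ranksum(x, y, exact_max = 0L)$p
  expect_identical(wilcoxon_ranksum(x, y)$method, "exact")
  expect_lt(abs(p_exact - p_norm), 0.02)

  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "empty")
})

test_that("exact Wilcoxon path equals full enumeration for all splits of
           n <= 8", {
  set.seed(29)
  pool <- rnorm(8)
  for (nx in 2:6) {
    combs <- utils::combn(8, nx)
    for (j in seq_len(ncol(combs))) {
      x <- pool[combs[, j]]
      y <- pool[-combs[, j]]
      expect_equal(wilcoxon_ranksum(x, y)$p, oracle_wilcoxon_p(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("Cohen's d uses the pooled SD and the documented bands", {
  set.seed(2)
  x <- rnorm(50); x <- (x - mean(x)) / sd(x) + 1   # mean 1, sd 1
  y <- rnorm(50); y <- (y - mean(y)) / sd(y)       # mean 0, sd 1
  r <- cohens_d(x, y)
  expect_equal(r$d, 1, tolerance = 1e-9)
  expect_identical(r$band, "large")
  expect_equal(cohens_d(x, x)$d, 0)
  # band boundaries are inclusive upward; base sample has pooled SD exactly
  # 5, so shifts of 1.5 / 2.5 / 4.5 give d = 0.3 / 0.5 / 0.9 in exact
  # floating point arithmetic
  base <- c(-5, -5, 0, 5, 5)
  expect_identical(cohens_d(base + 2.5, base)$band, "medium")
  expect_identical(cohens_d(base + 1.5, base)$band, "small")
  expect_identical(cohens_d(base + 4.5, base)$band, "large")
  expect_identical(cohens_d(base + 1, base)$band, "negligible")
  expect_equal(cohens_d(base + 2.5, base)$d, 0.5)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "pooled SD")
})

test_that("correlations distinguish Pearson and Spearman and are calibrated", {
  x <- 1:20
  expect_equal(correlate(x, x)$r, 1)
  # monotone nonlinear transform: Spearman 1, Pearson < 1
  y <- exp(x / 4)
  expect_equal(correlate(x, y, "spearman")$r, 1)
  expect_lt(correlate(x, y, "pearson")$r, 1)
  expect_error(correlate(x, rep(2, 20)), "constant")

  # Monte-Carlo: mean Spearman rho near the generating rho = 0.7 at n = 10
  set.seed(41)
  rhos <- replicate(2000, {
    z <- rnorm(10); e <- rnorm(10)
    x <- z; y <- 0.7 * z + sqrt(1 - 0.49) * e
    correlate(x, y, "spearman")$r
  })
  expect_gt(mean(rhos), 0.6)
  expect_lt(mean(rhos), 0.75)
})

test_that("Bonferroni adjustment caps at 1 and preserves ordering", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 5), 1)
  p <- c(0.001, 0.04, 0.2, 0.01)
  expect_identical(order(bonferroni(p, m = 10)), order(p))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
})

test_that("summary t-test reproduces demographic table p-values and the
           raw-data t-test", {
  # age row: 45.80 (12.67) vs 50.30 (14.44), n = 10 each -> p = .47
  expect_equal(round(summary_ttest(45.80, 12.67, 10, 50.30, 14.44, 10)$p, 2),
               0.47)
  # education row: 12.00 (3.06) vs 14.00 (2.16) -> p = .11
  expect_equal(round(summary_ttest(12.00, 3.06, 10, 14.00, 2.16, 10)$p, 2),
               0.11)
  # equal means: t = 0, p = 1
  r0 <- summary_ttest(5, 1, 8, 5, 2, 8)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)

  # identity with the classic pooled t-test on raw data
  set.seed(3)
  x <- rnorm(12, 1); y <- rnorm(9, 0.4)
  rs <- summary_ttest(mean(x), sd(x), 12, mean(y), sd(y), 9)
  rt <- t.test(x, y, var.equal = TRUE)
  expect_equal(rs$t, unname(rt$statistic), tolerance = 1e-12)
  expect_equal(rs$p, rt$p.value, tolerance = 1e-12)
  expect_error(summary_ttest(1, 0, 5, 2, 0, 5), "zero")
})

test_that("Fisher exact test reproduces the demographic table and is
           symmetric", {
  expect_equal(fisher_exact(2, 8, 0, 10)$p, 0.4737, tolerance = 1e-4)
  expect_equal(fisher_exact(3, 7, 0, 10)$p, 0.2105, tolerance = 1e-3)
  expect_equal(fisher_exact(4, 6, 4, 6)$p, 1)

  # independent enumeration oracle: sum hypergeometric probabilities of
  # tables no more probable than the observed one
  oracle_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  for (tab in list(c(2, 8, 0, 10), c(9, 1, 2, 8), c(3, 4, 5, 1))) {
    p <- fisher_exact(tab[1], tab[2], tab[3], tab[4])$p
    expect_equal(p, do.call(oracle_fisher, as.list(tab)), tolerance = 1e-9)
    # row and column swaps leave p unchanged
    expect_equal(fisher_exact(tab[3], tab[4], tab[1], tab[2])$p, p)
    expect_equal(fisher_exact(tab[2], tab[1], tab[4], tab[3])$p, p)
  }
  expect_error(fisher_exact(1.5, 2, 3, 4), "integers")
})

simulate_long <- function(n_per_group, delta_group = 0, delta_time = 0,
                          delta_int = 0, subj_sd = 1, resid_sd = 1,
                          seed = 1) {
  withr::with_seed(seed, {
    subj <- sprintf("s%03d", seq_len(2 * n_per_group))
    grp <- rep(c("a", "b"), each = n_per_group)
    u <- rnorm(2 * n_per_group, 0, subj_sd)
    rows <- do.call(rbind, lapply(seq_along(subj), function(i) {
      data.frame(subject = subj[i], group = grp[i], time = factor(1:2),
                 y = 10 + u[i] + (grp[i] == "b") * delta_group +
                   (0:1) * delta_time + (grp[i] == "b") * (0:1) * delta_int +
                   rnorm(2, 0, resid_sd))
    }))
    rows
  })
}

test_that("mixed model recovers a pure group effect and balanced cell-mean
           contrasts", {
  d <- simulate_long(50, delta_group = 1.5, seed = 7)
  res <- mixed_model(d, "y")
  g <- res[res$effect == "groupb", ]
  expect_lt(abs(g$estimate - 1.5), 2.5 * g$se)
  expect_lt(g$p, 0.01)
  expect_false(attr(res, "singular"))
  expect_true(is.finite(attr(res, "residual_normality_p")))

  # balanced complete data: fixed effects equal cell-mean contrasts
  cm <- with(d, tapply(y, list(group, time), mean))
  expect_equal(res$estimate[res$effect == "(Intercept)"], cm["a", "1"],
               tolerance = 1e-6)
  expect_equal(res$estimate[res$effect == "groupb"], cm["b", "1"] - cm["a", "1"],
               tolerance = 1e-6)
  expect_equal(res$estimate[res$effect == "time2"], cm["a", "2"] - cm["a", "1"],
               tolerance = 1e-6)
  expect_equal(res$estimate[res$effect == "groupb:time2"],
               (cm["b", "2"] - cm["b", "1"]) - (cm["a", "2"] - cm["a", "1"]),
               tolerance = 1e-6)
})

test_that("mixed model tolerates missing repeated measures", {
  d <- simulate_long(20, delta_group = 2, seed = 9)
  d <- d[-sample(nrow(d), 8), ]  # drop some visits
  res <- mixed_model(d, "y")
  expect_true(all(c("groupb", "time2", "groupb:time2") %in% res$effect))
  expect_lt(res$p[res$effect == "groupb"], 0.05)
})

test_that("effects table flags singular fits rather than dropping them", {
  # no residual noise and no subject effect: variance components collapse
  d <- simulate_long(6, subj_sd = 0, resid_sd = 1e-8, seed = 2)
  res <- suppressMessages(suppressWarnings(mixed_model(d, "y")))
  expect_true(isTRUE(attr(res, "singular")))
})
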