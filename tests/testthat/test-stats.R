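test_that("Mann-Whitney worked examples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$statistic, 0)
  expect_equal(r$p_two_sided, 0.1, tolerance = 1e-12)
  expect_identical(r$method, "exact")
  same <- mann_whitney(c(2, 5, 9), c(2, 5, 9))
  expect_equal(same$p_two_sided, 1)
  expect_error(mann_whitney(numeric(0), 1), "empty")
})

test_that("exact Mann-Whitney p matches full enumeration up to (6, 6)", {
  set.seed(11)
  for (m in 2:6) for (n in 2:6) {
    x <- rnorm(m)
    y <- rnorm(n, 0.8)
    r <- mann_whitney(x, y)
    expect_identical(r$method, "exact")
    expect_equal(r$p_two_sided, brute_force_mw_p(x, y), tolerance = 1e-12,
                 label = sprintf("MW exact p, m=%d n=%d", m, n))
  }
})

test_that("Wilcoxon signed-rank worked examples", {
  r <- wilcoxon_signed_rank(c(2, 1, 3, 5, 4))
  expect_identical(r$statistic, 0)
  expect_equal(r$p_two_sided, 2 / 2^5, tolerance = 1e-12)
  anti <- wilcoxon_signed_rank(c(-1.5, 1.5))
  expect_equal(anti$p_two_sided, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "undefined")
  # zero differences are dropped before ranking
  r2 <- wilcoxon_signed_rank(c(0, 2, 1, 3, 5, 4, 0))
  expect_identical(r2$n, 5L)
  expect_equal(r2$p_two_sided, r$p_two_sided)
})

test_that("exact signed-rank p matches sign-pattern enumeration up to n = 10", {
  set.seed(12)
  for (n in 4:10) {
    d <- rnorm(n, 0.5)
    r <- wilcoxon_signed_rank(d)
    expect_identical(r$method, "exact")
    expect_equal(r$p_two_sided, brute_force_wsr_p(d), tolerance = 1e-12,
                 label = sprintf("WSR exact p, n=%d", n))
  }
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(13)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  expect_equal(mann_whitney(exp(x), exp(y)), mann_whitney(x, y))
  d <- rnorm(9, 0.4)
  # signed-rank invariance holds for odd monotone maps preserving signs
  expect_equal(wilcoxon_signed_rank(sign(d) * abs(d)^3),
               wilcoxon_signed_rank(d))
})

test_that("Dunn follow-up adjusts pairwise comparisons", {
  two_same <- dunn_multiple_comparison(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(two_same$p_adjusted, 1)
  set.seed(21)
  g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8), d = rnorm(8))
  r <- dunn_multiple_comparison(g)
  expect_identical(nrow(r), 6L)   # k(k-1)/2 pairs for k = 4
  expect_true(all(r$p_adjusted >= r$p_unadjusted - 1e-12))
  expect_true(all(r$p_adjusted <= 1))
  # one extreme-shifted group: its two comparisons dominate
  set.seed(22)
  g3 <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10, 8))
  r3 <- dunn_multiple_comparison(g3)
  pc <- r3$p_adjusted[r3$group1 == "c" | r3$group2 == "c"]
  pab <- r3$p_adjusted[r3$group1 == "a" & r3$group2 == "b"]
  expect_true(all(pc < pab))
  expect_error(dunn_multiple_comparison(list(a = 1:3)), "two groups")
  expect_error(dunn_multiple_comparison(list(a = 1:3, b = numeric(0))),
               "empty")
})

test_that("Pearson correlation worked values and error contracts", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -x)$r, -1, tolerance = 1e-12)
  r <- pearson_correlation(x, c(1, 3, 2, 4))
  expect_equal(r$r, 0.8, tolerance = 1e-12)
  # p from the t transform with n - 2 degrees of freedom
  tstat <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(r$p_two_sided, 2 * stats::pt(-tstat, df = 2),
               tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_correlation(1:2, 1:2), "size >= 3")
})

test_that("radiographic percent increase", {
  expect_identical(percent_increase(3, 3), 0)
  expect_identical(percent_increase(6, 3), 100)
  expect_equal(percent_increase(3.3, 3.0), 10, tolerance = 1e-12)
  expect_identical(percent_increase(c(3.3, 6), c(3, 3))[2], 100)
  expect_error(percent_increase(1, 0), "positive")
})
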