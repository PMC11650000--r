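# direct textbook-formula oracles, independent of the implementation path
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}
oracle_paired_t <- function(x, y) {
  d <- x - y; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - e)^2 / e)
  list(x2 = x2, p = pchisq(x2, 1, lower.tail = FALSE))
}

test_that("unpaired t matches the pooled-variance formula and its conventions", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  res <- unpaired_t(a, b)
  orc <- oracle_student_t(a, b)
  expect_equal(res$statistic, orc$t, tolerance = 1e-12)
  expect_equal(res$p_value, orc$p, tolerance = 1e-12)
  expect_equal(res$df, 4)
  # identical groups
  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # antisymmetry under group swap
  set.seed(1); x <- rnorm(8); y <- rnorm(10, 1)
  expect_equal(unpaired_t(x, y)$statistic, -unpaired_t(y, x)$statistic)
  expect_equal(unpaired_t(x, y)$p_value, unpaired_t(y, x)$p_value)
  # Cohen's d with pooled SD
  expect_equal(unpaired_t(a, b)$effect_size, (mean(a) - mean(b)) / 1)
  # degenerate zero-variance, unequal means
  dg <- unpaired_t(c(1, 1), c(2, 2))
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 0)
  expect_error(unpaired_t(1, c(1, 2)), "n >= 2")
})

test_that("paired t matches the one-sample formula on differences", {
  x <- c(2.1, 3.3, 1.8, 4.0, 2.9); y <- c(1.9, 2.8, 2.0, 3.1, 2.2)
  res <- paired_t(x, y)
  orc <- oracle_paired_t(x, y)
  expect_equal(res$statistic, orc$t, tolerance = 1e-12)
  expect_equal(res$p_value, orc$p, tolerance = 1e-12)
  expect_equal(res$df, 4)
  # degenerate contracts
  eq <- paired_t(x, x)
  expect_equal(eq$statistic, 0); expect_equal(eq$p_value, 1)
  expect_true(eq$degenerate)
  sh <- paired_t(x, x + 2)
  expect_equal(sh$p_value, 0); expect_true(sh$degenerate)
  expect_error(paired_t(x, y[1:3]), "equal length")
})

test_that("chi-square reproduces the cohort sex-ratio worked examples", {
  eeg <- chi_square_2x2(rbind(c(11, 9), c(6, 13)))
  expect_equal(round(eeg$statistic, 2), 2.17)
  meg <- chi_square_2x2(rbind(c(16, 12), c(30, 12)))
  expect_equal(round(meg$statistic, 2), 1.52)
  expect_equal(eeg$df, 1)
  # proportional table -> independence
  prop <- chi_square_2x2(rbind(c(10, 20), c(5, 10)))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("t and chi-square agree with formula oracles on 1000 random instances", {
  set.seed(1234)
  for (i in 1:1000) {
    a <- rnorm(sample(2:12, 1)); b <- rnorm(sample(2:12, 1), sd = 2)
    res <- unpaired_t(a, b); orc <- oracle_student_t(a, b)
    expect_lt(abs(res$statistic - orc$t), 1e-10)
    expect_lt(abs(res$p_value - orc$p), 1e-10)
    n <- sample(2:10, 1)
    x <- rnorm(n); y <- x + rnorm(n)
    resp <- paired_t(x, y); orcp <- oracle_paired_t(x, y)
    expect_lt(abs(resp$statistic - orcp$t), 1e-10)
    tab <- matrix(sample(1:40, 4, replace = TRUE), 2)
    resc <- chi_square_2x2(tab); orcc <- oracle_chisq(tab)
    expect_lt(abs(resc$statistic - orcc$x2), 1e-10)
    expect_lt(abs(resc$p_value - orcc$p), 1e-10)
  }
})

test_that("Bonferroni multiplies, caps, preserves order and validates m", {
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni(0.3, m = 1), 0.3)
  expect_equal(bonferroni(c(0.2, 0.5, 0.9), m = 34), c(1, 1, 1))
  p <- runif(20)
  expect_equal(bonferroni(p, m = 20), pmin(1, stats::p.adjust(p, "bonferroni")))
  expect_true(all(bonferroni(p, m = 25) >= p))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("unpaired t is calibrated under the null (rejection rate near 0.05)", {
  set.seed(2024)
  rej <- mean(replicate(2000, {
    unpaired_t(rnorm(20), rnorm(20))$p_value < 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("normality statistics match reference implementations and invariances", {
  set.seed(5)
  x <- rnorm(60)
  # Lilliefors statistic equals nortest's D
  expect_equal(normality_test(x, "lilliefors", n_mc = 200)$statistic,
               unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)
  # Anderson-Darling equals nortest's A and p
  ad <- normality_test(x, "anderson_darling")
  ref <- nortest::ad.test(x)
  expect_equal(ad$statistic, unname(ref$statistic))
  expect_equal(ad$p_value, ref$p.value)
  # location-scale invariance of both statistics
  y <- 3 + 2 * x
  expect_equal(normality_test(y, "lilliefors", n_mc = 200)$statistic,
               normality_test(x, "lilliefors", n_mc = 200)$statistic,
               tolerance = 1e-12)
  expect_equal(normality_test(y, "anderson_darling")$statistic,
               normality_test(x, "anderson_darling")$statistic,
               tolerance = 1e-12)
  expect_error(normality_test(rnorm(5)), "n >= 8")
  # Monte-Carlo p is seeded and reproducible
  p1 <- normality_test(x, "lilliefors", n_mc = 500, mc_seed = 9)$p_value
  p2 <- normality_test(x, "lilliefors", n_mc = 500, mc_seed = 9)$p_value
  expect_identical(p1, p2)
})

test_that("normality tests keep size under the null and power against skew", {
  null_ok <- power_ok <- c(ad = 0, lil = 0)
  for (s in 1:100) {
    set.seed(700 + s)
    xn <- rnorm(200); xe <- rexp(200)
    null_ok["ad"] <- null_ok["ad"] +
      (normality_test(xn, "anderson_darling")$p_value > 0.05)
    null_ok["lil"] <- null_ok["lil"] +
      (normality_test(xn, "lilliefors", n_mc = 800,
                      mc_seed = s)$p_value > 0.05)
    power_ok["ad"] <- power_ok["ad"] +
      (normality_test(xe, "anderson_darling")$p_value < 0.05)
    power_ok["lil"] <- power_ok["lil"] +
      (normality_test(xe, "lilliefors", n_mc = 800,
                      mc_seed = s)$p_value < 0.05)
  }
  expect_gte(null_ok["ad"], 90); expect_gte(null_ok["lil"], 90)
  expect_gte(power_ok["ad"], 95); expect_gte(power_ok["lil"], 95)
})

test_that("cohort comparisons dispatch, correct and validate as specified", {
  set.seed(77)
  vals <- rbind(matrix(rnorm(6 * 8, 0), 6),        # controls
                matrix(rnorm(6 * 8, 1), 6))        # patients, shifted
  tab <- toy_ratio_table(vals, groups = rep(c("control", "left_TLE"),
                                            each = 6),
                         hemisphere = rep(c("left", "right"), each = 4))
  hem <- cohort_comparison(tab, "hemisphere")
  expect_length(hem, 2)
  for (tt in hem) {
    expect_equal(tt$m_corrections, 2)
    expect_equal(tt$p_adjusted, min(1, 2 * tt$p_value))
    expect_equal(tt$correction, "bonferroni")
  }
  # hemisphere-level equals a direct unpaired t on hemisphere means
  hm <- hemisphere_mean(tab, "left")
  direct <- unpaired_t(hm[7:12], hm[1:6])
  expect_equal(hem[[1]]$statistic, direct$statistic)

  reg <- cohort_comparison(tab, "region")
  expect_length(reg, 2)
  expect_equal(reg[[1]]$df, 3)                    # 4 region pairs per side
  con_mean <- colMeans(vals[1:6, 1:4]); pat_mean <- colMeans(vals[7:12, 1:4])
  expect_equal(reg[[1]]$statistic, oracle_paired_t(con_mean, pat_mean)$t,
               tolerance = 1e-12)

  solo <- toy_ratio_table(vals[c(1, 7), ],
                          groups = c("control", "left_TLE"),
                          hemisphere = rep(c("left", "right"), each = 4))
  expect_error(cohort_comparison(solo, "hemisphere"), "n >= 2")
  onlycon <- toy_ratio_table(vals[1:3, ], groups = rep("control", 3),
                             hemisphere = rep(c("left", "right"), each = 4))
  expect_error(cohort_comparison(onlycon), "cohort")
})

test_that("synthetic cohorts separate with corrected significance (>=95/100)", {
  mc <- mc_results("alt")
  hit <- mc$p_adj_left < 0.05 & mc$p_adj_right < 0.05 & mc$mean_diff > 0
  expect_gte(sum(hit), 95)
})

test_that("family-wise error stays controlled on identical-parameter cohorts", {
  mc <- mc_results("null")
  fw <- mc$p_adj_left < 0.05 | mc$p_adj_right < 0.05
  expect_lte(sum(fw), 10)
})
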