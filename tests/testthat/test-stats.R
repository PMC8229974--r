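test_that("log10 percent transform floors zeros", {
  expect_equal(log10_percent(100), 2)
  expect_equal(log10_percent(0), -1)
  expect_equal(log10_percent(0.27), log10(0.27))
  expect_equal(log10_percent(0.05, floor = 0.1), -1)
  expect_error(log10_percent(5, floor = 0), "> 0")
})

test_that("Spearman rho matches the rank-difference formula", {
  r <- spearman_cor(1:4, c(2, 4, 6, 8))
  expect_equal(r$rho, 1)
  expect_equal(r$r_squared, 1)
  expect_equal(spearman_cor(1:4, c(8, 6, 4, 2))$rho, -1)
  # oracle: d^2 = (1,1,1,1,0), rho = 1 - 6*4/(5*24) = 0.8
  r5 <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r5$rho, oracle_spearman_rho(1:5, c(2, 1, 4, 3, 5)))
  expect_equal(r5$rho, 0.8)
  expect_equal(r5$r_squared, 0.64)
  expect_error(spearman_cor(1:5, rep(1, 5)), "undefined correlation")
  expect_error(spearman_cor(1:2, 1:2), "n >= 3")
})

test_that("Spearman is symmetric and invariant under monotone transforms", {
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    a <- spearman_cor(x, y); b <- spearman_cor(y, x)
    expect_equal(a$rho, b$rho)
    expect_equal(a$p_value, b$p_value)
    tr <- spearman_cor(exp(x), y^3 + 5 * y)
    expect_equal(tr$rho, a$rho)
  }
})

test_that("Mann-Whitney U comes from rank sums and p from exact
           enumeration at small n", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 9 / 2)
  # enumeration over all 6 splits: |U - 2| >= 1 in 4 of them -> p = 2/3
  expect_equal(mann_whitney(c(1, 3), c(2, 4))$p_value,
               oracle_mw_exact_p(c(1, 3), c(2, 4)))
  expect_equal(mann_whitney(c(1, 3), c(2, 4))$p_value, 2 / 3)
  expect_equal(mann_whitney(c(1, 3), c(2, 4))$statistic, 1)
})

test_that("U statistics from both groups sum to n1*n2 and match pairwise
           counting", {
  set.seed(7)
  for (i in 1:12) {
    a <- sample(1:8, sample(2:6, 1), replace = TRUE)
    b <- sample(1:8, sample(2:6, 1), replace = TRUE)
    ua <- mann_whitney(a, b)$statistic
    ub <- mann_whitney(b, a)$statistic
    expect_equal(ua + ub, length(a) * length(b))
    expect_equal(ua, oracle_u(a, b))
  }
})

test_that("exact and normal-approximation Mann-Whitney p agree for tie-free
           n1=n2=5", {
  set.seed(13)
  for (i in 1:10) {
    vals <- sample(1:100, 10)
    a <- vals[1:5]; b <- vals[6:10]
    p_exact <- mann_whitney(a, b)$p_value     # n = 10 -> exact path
    # the continuity-corrected approximation the large-n path uses
    pooled <- c(a, b); r <- rank(pooled)
    u <- sum(r[1:5]) - 15
    sigma <- sqrt(5 * 5 * 11 / 12)
    p_norm <- min(2 * pnorm(-(abs(u - 12.5) - 0.5) / sigma), 1)
    expect_lt(abs(p_exact - p_norm), 0.05)
  }
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
  expect_equal(fisher_exact(matrix(c(2, 2, 2, 2), 2)), 1)
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(sample(1:4, 4, replace = TRUE), 2)
    expect_equal(fisher_exact(tab), oracle_fisher_p(tab))
  }
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2)), "degenerate")
})

test_that("chi-square is the Pearson statistic without continuity
           correction", {
  res <- chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  tab <- matrix(c(12, 5, 7, 15), 2)
  res2 <- chi_square(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res2$statistic, sum((tab - e)^2 / e))
  expect_equal(res2$df, 1)
})

test_that("panel association recovers the generator's monotone structure", {
  noiseless <- simulate_panel(panel_gen_params(sigma_e = 0, sigma_t = 0,
                                               sigma_rfi = 0, seed = 3))
  rep <- associate_panel(noiseless)
  expr_rows <- rep[rep$comparison %in% c("dr4_meth_vs_expression",
                                         "dr5_meth_vs_expression"), ]
  expect_true(all(expr_rows$rho < -0.99))
  defaults <- associate_panel(simulate_panel(panel_gen_params(seed = 4)))
  dr4_rows <- defaults[defaults$comparison %in%
                         c("dr4_meth_vs_expression", "dr4_meth_vs_rfi",
                           "dr4_meth_vs_inhibition"), ]
  expect_true(all(dr4_rows$rho < 0))
  # the two genes methylation levels correlate positively across the panel
  expect_gt(defaults$rho[defaults$comparison == "dr4_meth_vs_dr5_meth"], 0)
})

test_that("shuffling inhibition destroys the methylation association", {
  panel <- simulate_panel(panel_gen_params(seed = 6))
  set.seed(99)
  high_p <- 0
  n_shuffles <- 100
  for (i in seq_len(n_shuffles)) {
    shuffled <- panel
    shuffled$inhibition_pct <- sample(panel$inhibition_pct)
    r <- spearman_cor(log10_percent(shuffled$dr4_pct),
                      shuffled$inhibition_pct)
    if (r$p_value > 0.05) high_p <- high_p + 1
  }
  expect_gte(high_p, 0.9 * n_shuffles)
})
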