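test_that("mean and SEM use the n-1 sample standard deviation", {
  ms <- mean_sem(c(1, 2, 3))
  expect_equal(ms$mean, 2)
  expect_equal(ms$sem, 0.5774, tolerance = 1e-4)
  expect_equal(mean_sem(rep(4, 5))$sem, 0)
  one <- mean_sem(7)
  expect_equal(one$sem, 0)
  expect_true(attr(one, "single_value"))
  # linearity: scaling values scales both mean and sem
  v <- c(0.3, 1.1, 2.5, 0.9)
  ms1 <- mean_sem(v)
  ms3 <- mean_sem(3 * v)
  expect_equal(ms3$mean, 3 * ms1$mean)
  expect_equal(ms3$sem, 3 * ms1$sem)
  expect_error(mean_sem(numeric(0)), "at least one")
})

test_that("Mann-Whitney exact branch reproduces small closed-form cases", {
  t1 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(t1$statistic_U, 0)
  expect_equal(t1$p_two_tailed, 1 / 3, tolerance = 1e-12)
  expect_equal(t1$method, "exact_enumeration")
  # identical multisets: U = n1 n2 / 2 and p = 1
  t2 <- mann_whitney_u(c(1, 2, 3), c(3, 2, 1))
  expect_equal(t2$statistic_U, 4.5)
  expect_equal(t2$p_two_tailed, 1)
  # degenerate pooled sample
  t3 <- mann_whitney_u(rep(2, 4), rep(2, 5))
  expect_equal(t3$p_two_tailed, 1)
  expect_true(t3$degenerate)
  # U bounds
  expect_gte(t1$statistic_U, 0)
  expect_lte(t1$statistic_U, t1$n1 * t1$n2)
})

test_that("exact branch equals brute-force enumeration on tie-free cases", {
  set.seed(4021)
  for (rep in 1:40) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    repeat {
      a <- round(stats::runif(n1, 0, 100), 3)
      b <- round(stats::runif(n2, 0, 100), 3)
      if (!anyDuplicated(c(a, b))) break
    }
    ours <- mann_whitney_u(a, b, mode = "exact")
    oracle <- brute_force_mw(a, b)
    expect_equal(ours$statistic_U, oracle$u)
    expect_equal(ours$p_two_tailed, oracle$p, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p on small instances", {
  set.seed(512)
  diffs <- replicate(100, {
    n1 <- sample(5:8, 1)
    n2 <- sample(5:8, 1)
    a <- stats::rnorm(n1)
    b <- stats::rnorm(n2, mean = stats::runif(1, -1, 1))
    pe <- mann_whitney_u(a, b, mode = "exact")$p_two_tailed
    pn <- mann_whitney_u(a, b, mode = "normal")$p_two_tailed
    abs(pe - pn)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("the U test agrees with the standard Wilcoxon implementation", {
  set.seed(99)
  for (rep in 1:20) {
    a <- stats::rnorm(25)
    b <- stats::rnorm(30, 0.4)
    ours <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
    expect_equal(ours$statistic_U, unname(ref$statistic))
    expect_equal(ours$p_two_tailed, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Pearson correlation handles exact and sampled cases", {
  x <- c(1, 2, 4, 7, 9)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_equal(pearson(x, -x)$p_value, 0)
  expect_error(pearson(x, rep(3, 5)), "variance")
  expect_error(pearson(x, x[1:3]), "equal length")
  # agrees with the standard implementation
  set.seed(7)
  u <- stats::rnorm(40)
  v <- 0.5 * u + stats::rnorm(40)
  ours <- pearson(u, v)
  ref <- stats::cor.test(u, v)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  # n = 100 bivariate normal, rho = 0.5: r inside the Fisher-z interval
  set.seed(81)
  z1 <- stats::rnorm(100)
  z2 <- 0.5 * z1 + sqrt(1 - 0.25) * stats::rnorm(100)
  r <- pearson(z1, z2)$r
  expect_gt(r, 0.33)
  expect_lt(r, 0.64)
})

test_that("log-normal fitting is ML-consistent and scale-equivariant", {
  expect_equal(fit_lognormal(exp(c(0, 0, 0)))$logmean, 0)
  set.seed(19)
  v <- stats::rlnorm(1e4, meanlog = 1, sdlog = 0.5)
  fit <- fit_lognormal(v)
  expect_lt(abs(fit$logmean - 1), 3 * 0.5 / sqrt(1e4))
  expect_lt(abs(fit$logsd - 0.5), 3 * 0.5 / sqrt(2 * 1e4))
  expect_gt(fit$gof_pvalue, 0.01)
  # scaling shifts logmean by log(c), leaves logsd unchanged
  fit3 <- fit_lognormal(3 * v)
  expect_equal(fit3$logmean, fit$logmean + log(3))
  expect_equal(fit3$logsd, fit$logsd)
  expect_error(fit_lognormal(c(1, -2)), "positive")
  # generated PSD areas follow the profile log-normal
  p <- load_profile("mouse_V1_L23_p14")
  ds <- generate_dataset(p, n_dendrites = 150, seed = 55)
  fit_psd <- fit_lognormal(ds$synapses$psd_area)
  se_lm <- p$psd_logsd / sqrt(fit_psd$n)
  expect_lt(abs(fit_psd$logmean - p$psd_logmean), 3 * se_lm)
})

test_that("change metrics give percent and fold changes", {
  cm <- change_metrics(0.43, 0.69)
  expect_equal(cm$percent_change, 60.465, tolerance = 1e-4)
  cm2 <- change_metrics(0.87, 2.1)
  expect_equal(cm2$fold_change, 2.414, tolerance = 1e-3)
  same <- change_metrics(5, 5)
  expect_equal(same$percent_change, 0)
  expect_equal(same$fold_change, 1)
  expect_error(change_metrics(0, 1), "positive")
})

test_that("significance stars follow the conventional cutpoints", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("ns", "*", "**", "***"))
})

test_that("the U test rejects strongly for fragment densities a factor ~2 apart", {
  # Poisson spine counts over 10 um fragments at the young vs adult rates
  set.seed(300)
  rej <- replicate(200, {
    a <- stats::rpois(20, 0.87 * 10) / 10
    b <- stats::rpois(20, 2.1 * 10) / 10
    mann_whitney_u(a, b)$p_two_tailed < 0.05
  })
  expect_gt(mean(rej), 0.95)
})
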