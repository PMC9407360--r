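test_that("the component-count distribution is proportional to 1/m on 2..20", {
  # P(M = 2) = (1/2) / sum_{m=2}^{20} 1/m
  p2 <- 0.5 / sum(1 / (2:20))
  expect_equal(p2, 0.19247, tolerance = 1e-4)
  set.seed(51)
  Ms <- vapply(1:10000, function(i) length(draw_random_mixture()$weights),
               numeric(1))
  expect_lt(abs(mean(Ms == 2) - p2), 4 * sqrt(p2 * (1 - p2) / 10000))
  # chi-squared goodness of fit to the 1/m law at the 1% level
  expected <- (1 / (2:20)) / sum(1 / (2:20))
  gof <- chisq.test(tabulate(Ms, 20)[2:20], p = expected)
  expect_gt(gof$p.value, 0.01)
})

test_that("random mixtures are valid distributions and draws are reproducible", {
  set.seed(52)
  for (i in 1:50) {
    d <- draw_random_mixture()
    expect_true(all(d$weights >= 0))
    expect_equal(sum(d$weights), 1, tolerance = 1e-12)
    expect_true(all(d$sds > 0))
    expect_true(length(d$weights) %in% 2:20)
  }
  set.seed(99); a <- draw_random_mixture()
  set.seed(99); b <- draw_random_mixture()
  expect_identical(a, b)
})

test_that("mixture pdf and sampler agree with the mixture's moments", {
  set.seed(53)
  d <- normal_mixture(c(0.3, 0.7), c(-1, 2), c(0.5, 1.5))
  expect_equal(integrate(function(x) dmixnorm(x, d), -Inf, Inf,
                         rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  draws <- rmixnorm(1e5, d)
  mu <- sum(d$weights * d$means)
  expect_lt(abs(mean(draws) - mu), 4 * sd(draws) / sqrt(length(draws)))
  # single-component degenerate path: the pdf is a plain normal density
  d1 <- normal_mixture(1, 0.5, 2)
  x <- seq(-3, 5, by = 0.5)
  expect_equal(dmixnorm(x, d1), dnorm(x, 0.5, 2), tolerance = 1e-14)
  expect_error(normal_mixture(c(0.5, 0.4), c(0, 1), c(1, 1)), "sum to 1")
  expect_error(normal_mixture(1, 0, -1), "positive")
})

test_that("level and power experiments are reproducible tables of the right shape", {
  lv <- run_level_experiment(m = 20, n = 20, replicates = 3, n_perm1 = 60,
                             n_perm2 = 120, seed = 77)
  expect_length(lv$levels, 3)
  expect_true(all(lv$levels >= 0 & lv$levels <= 1))
  expect_equal(lv$mean_level, mean(lv$levels))
  lv2 <- run_level_experiment(m = 20, n = 20, replicates = 3, n_perm1 = 60,
                              n_perm2 = 120, seed = 77)
  expect_identical(lv$levels, lv2$levels)
  # a single replicate returns that pair's conditional level alone
  l1 <- run_level_experiment(m = 20, n = 20, replicates = 1, n_perm1 = 60,
                             n_perm2 = 120, seed = 5)
  expect_length(l1$levels, 1)
  expect_equal(l1$mean_level, l1$levels[1])

  pc <- run_power_comparison(m = 15, n = 15, replicates = 4, n_perm = 99,
                             seed = 78)
  expect_identical(nrow(pc$p_values), 4L)
  expect_named(pc$p_values, c("replicate", "alb", "ks", "bowman"))
  expect_true(all(unlist(pc$p_values[, -1]) >= 0 &
                    unlist(pc$p_values[, -1]) <= 1))
  pc2 <- run_power_comparison(m = 15, n = 15, replicates = 4, n_perm = 99,
                              seed = 78)
  expect_identical(pc$p_values, pc2$p_values)
  # identical samples cannot look different: ALB p-value far from rejection
  # (fixed bandwidth: likelihood cross-validation degenerates under exact
  # ties, which duplicating the whole sample creates by construction)
  v <- qnorm((1:15) / 16)
  same <- permutation_distribution(v, v, b = 0.5, n_perm = 199, seed = 79)
  expect_gt(same$p_value, 0.2)
})
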