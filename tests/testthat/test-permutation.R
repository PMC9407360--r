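test_that("the observed statistic is the identity-permutation value", {
  set.seed(31)
  x <- rnorm(8); y <- rnorm(8, 1)
  pd <- permutation_distribution(x, y, b = 0.6, kernel = "L0", n_perm = 50,
                                 seed = 4)
  st <- alb_statistic(x, y, 0.6, "L0")
  expect_equal(pd$observed, st$alb, tolerance = 1e-12)
  expect_true(all(pd$alb_star <= alb_upper_bound(8, 8)))
})

test_that("permutation draws are reproducible from the recorded seed", {
  set.seed(32)
  x <- rnorm(10); y <- rnorm(10)
  a <- permutation_distribution(x, y, b = 0.5, n_perm = 99, seed = 11)
  b <- permutation_distribution(x, y, b = 0.5, n_perm = 99, seed = 11)
  expect_identical(a$alb_star, b$alb_star)
  expect_identical(a$p_value, b$p_value)
  c <- permutation_distribution(x, y, b = 0.5, n_perm = 99, seed = 12)
  expect_false(identical(a$alb_star, c$alb_star))
})

test_that("p-values count strict exceedances, with an add-one variant", {
  expect_equal(perm_p_value(0, c(-1, 0, 1)), 1 / 3)
  expect_equal(perm_p_value(2, c(-1, 0, 1)), 0)
  expect_equal(perm_p_value(-2, c(-1, 0, 1)), 1)
  expect_equal(perm_p_value(0, c(-1, 0, 1), add_one = TRUE), 3 / 4)
  expect_error(perm_p_value(0, numeric(0)))
})

test_that("critical values floor the permutation quantile at zero", {
  expect_equal(perm_critical_value(c(-0.3, -0.2, -0.1), alpha = 0.05), 0)
  s <- c(-0.2, -0.1, 0.1, 0.3)
  # order-statistic convention: sorted value at ceiling((1 - alpha) N)
  expect_equal(perm_critical_value(s, alpha = 0.25), 0.1)
  expect_equal(perm_critical_value(s, alpha = 0.05), max(0, max(s)))
  # max(0, t) rejects no more often than t alone
  set.seed(33)
  x <- rnorm(10); y <- rnorm(10)
  pd <- permutation_distribution(x, y, b = 0.5, n_perm = 199, seed = 2)
  expect_gte(pd$critical_value, pd$t_quantile)
})

test_that("sampled permutation values lie in the exhaustive enumeration support", {
  set.seed(34)
  x <- rnorm(3); y <- rnorm(3)
  z <- c(x, y)
  # all C(6,3) distinct label partitions, by direct statistic evaluation
  support <- apply(combn(6, 3), 2, function(idx)
    alb_statistic(z[idx], z[-idx], b = 0.7, kernel = "L0")$alb)
  pd <- permutation_distribution(x, y, b = 0.7, kernel = "L0", n_perm = 300,
                                 seed = 9)
  dist_to_support <- vapply(pd$alb_star,
                            function(v) min(abs(v - support)), numeric(1))
  expect_lt(max(dist_to_support), 1e-10)
  # with m = n both group assignments of a partition give the same value
  expect_equal(alb_statistic(x, y, 0.7, "L0")$alb,
               alb_statistic(y, x, 0.7, "L0")$alb, tolerance = 1e-12)
})

test_that("conditional levels are reproducible probabilities near alpha on average", {
  set.seed(35)
  x <- rnorm(30); y <- rnorm(30)
  l1 <- conditional_level(x, y, n_perm1 = 100, n_perm2 = 400, seed = 6)
  l2 <- conditional_level(x, y, n_perm1 = 100, n_perm2 = 400, seed = 6)
  expect_identical(l1, l2)
  expect_gte(l1, 0); expect_lte(l1, 1)
  # averaged over data sets the conditional level straddles alpha
  lv <- vapply(1:25, function(r) {
    conditional_level(rnorm(20), rnorm(20), n_perm1 = 100, n_perm2 = 300,
                      seed = r)
  }, numeric(1))
  expect_gt(mean(lv), 0.01)
  expect_lt(mean(lv), 0.12)
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(36)
  pv <- vapply(1:200, function(r) {
    x <- rnorm(15); y <- rnorm(15)
    permutation_distribution(x, y, kernel = "L0", n_perm = 499,
                             seed = 1000 + r)$p_value
  }, numeric(1))
  d <- suppressWarnings(ks.test(pv, "punif"))$statistic
  expect_lte(unname(d), 0.1)
})
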