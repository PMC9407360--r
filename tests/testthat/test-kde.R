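test_that("univariate kde matches direct evaluation", {
  expect_equal(kde_eval(0, 1, 0, "gaussian"), dnorm(0), tolerance = 1e-12)
  expect_equal(kde_eval(1, 1, c(0, 2), "gaussian"), dnorm(1),
               tolerance = 1e-12)
  # scale equivariance: f(u | h, U) = (1/h) f(u/h | 1, U/h)
  U <- c(-1, 0.3, 2.2)
  expect_equal(kde_eval(0.7, 0.25, U, "L0"),
               kde_eval(0.7 / 0.25, 1, U / 0.25, "L0") / 0.25,
               tolerance = 1e-12)
  expect_error(kde_eval(0, -1, U), "positive")
  expect_error(kde_eval(0, 1, numeric(0)), "non-empty")
})

test_that("bivariate product kde factorizes and is coordinate-symmetric", {
  expect_equal(kde_eval2(c(0, 0), 1, 1, matrix(0, 1, 2), "gaussian"),
               dnorm(0)^2, tolerance = 1e-12)
  expect_equal(kde_eval2(c(0, 0), 1, 1, matrix(0, 1, 2), "gaussian"),
               0.1591549, tolerance = 1e-6)
  u <- c(0.4, -0.2); pt <- matrix(c(0.1, 0.8), 1, 2)
  expect_equal(kde_eval2(u, 0.5, 1.5, pt, "t"),
               kde_eval(u[1], 0.5, pt[1, 1], "t") *
                 kde_eval(u[2], 1.5, pt[1, 2], "t"),
               tolerance = 1e-12)
  # swapping coordinates of u, the data and (h1, h2) leaves the value fixed
  U <- cbind(rnorm(4), rnorm(4))
  expect_equal(kde_eval2(u, 0.5, 1.5, U, "L0"),
               kde_eval2(rev(u), 1.5, 0.5, U[, 2:1], "L0"),
               tolerance = 1e-12)
  expect_error(kde_eval2(c(0, 0, 0), 1, 1, U), "2-dimensional")
})

test_that("kernel matrix is symmetric, label-free and correctly scaled", {
  M <- alb_kernel_matrix(c(0, 1), 1, "gaussian")
  expect_equal(exp(M$logM[1, 2]), dnorm(1), tolerance = 1e-12)
  expect_identical(M$logM, t(M$logM))
  expect_identical(diag(M$logM), c(-Inf, -Inf))
  z <- rnorm(7)
  M2 <- alb_kernel_matrix(z, 0.4, "L0")
  expect_equal(M2$logM, t(M2$logM), tolerance = 1e-14)
  expect_true(all(M2$logM[upper.tri(M2$logM)] > -Inf))
  expect_error(alb_kernel_matrix(z, -0.1, "L0"), "positive")
  expect_error(alb_kernel_matrix(z, 1, "L0", reflect = TRUE), "bivariate")
})

test_that("leave-one-out log-density equals direct kde evaluation", {
  set.seed(41)
  for (rep in 1:5) {
    fx <- random_fixture()
    z <- c(fx$x, fx$y)
    M <- alb_kernel_matrix(z, fx$b, "L0")
    for (i in sample(seq_along(z), 3)) {
      sub <- sort(sample(setdiff(seq_along(z), i),
                         sample(2:(length(z) - 1), 1)))
      expect_equal(loo_log_density(i, sub, M),
                   kde_eval(z[i], fx$b, z[sub], "L0", log = TRUE),
                   tolerance = 1e-10)
    }
  }
  # subset of size 1 at distance zero
  M <- alb_kernel_matrix(c(0.5, 0.5), 1, "gaussian")
  expect_equal(loo_log_density(1, 1:2, M), dnorm(0, log = TRUE),
               tolerance = 1e-12)
  expect_error(loo_log_density(1, 1, M), "empty")
  # appending a far-away point pulls the average down
  M3 <- alb_kernel_matrix(c(0, 0.1, 500), 1, "gaussian")
  expect_lt(loo_log_density(1, 1:3, M3), loo_log_density(1, 1:2, M3))
})

test_that("unit-square reflection produces the three mirror images", {
  r <- reflect_unit_square(c(0.2, 0.3))
  expect_equal(r$points,
               rbind(c(0.2, 0.3), c(0.2, -0.3), c(-0.2, -0.3), c(-0.2, 0.3)))
  expect_identical(r$index, rep(1L, 4))
  pts <- cbind(runif(5), runif(5))
  r5 <- reflect_unit_square(pts)
  expect_identical(nrow(r5$points), 20L)
  expect_identical(r5$index, rep(1:5, times = 4))
  # the origin is a fixed point of all four copies
  expect_true(all(reflect_unit_square(c(0, 0))$points == 0))
  expect_error(reflect_unit_square(c(1.2, 0.5)), "unit square")
})

test_that("boundary-corrected estimate integrates to 1 over the positive quadrant", {
  set.seed(7)
  pts <- cbind(runif(6), runif(6))
  f <- function(x, y)
    kde_eval2_reflected(cbind(x, y), 0.3, 0.4, pts, "gaussian")
  quad2 <- function(hi) {
    inner <- function(y)
      vapply(y, function(yy)
        integrate(function(x) f(x, yy), 0, hi, rel.tol = 1e-7)$value,
        numeric(1))
    integrate(inner, 0, hi, rel.tol = 1e-6)$value
  }
  # exact identity: the 4x estimate from the reflected points has total mass
  # 1 on the quadrant the data live in
  expect_equal(quad2(Inf), 1, tolerance = 1e-4)
  # over the unit square itself the mass is 1 up to the kernel leak past the
  # (uncorrected) upper edges, negligible for small bandwidths
  pts_in <- cbind(runif(6, 0.1, 0.7), runif(6, 0.1, 0.7))
  f <- function(x, y)
    kde_eval2_reflected(cbind(x, y), 0.03, 0.03, pts_in, "gaussian")
  expect_equal(quad2(1), 1, tolerance = 1e-4)
})

test_that("reflected kernel matrix matches the leave-out-four construction", {
  set.seed(9)
  pts <- cbind(runif(8, 0.2, 0.8), runif(8, 0.2, 0.8))
  b <- c(0.3, 0.25)
  M <- alb_kernel_matrix(pts, b, "t", reflect = TRUE)
  for (i in c(1, 5)) {
    sub <- setdiff(1:8, i)
    expect_equal(loo_log_density(i, sub, M),
                 kde_eval2_reflected(pts[i, ], b[1], b[2],
                                     pts[sub, ], "t", log = TRUE),
                 tolerance = 1e-10)
  }
  # far from the boundary with small bandwidths the correction is negligible
  mid <- cbind(runif(8, 0.45, 0.55), runif(8, 0.45, 0.55))
  Mr <- alb_kernel_matrix(mid, c(0.02, 0.02), "gaussian", reflect = TRUE)
  Mp <- alb_kernel_matrix(mid, c(0.02, 0.02), "gaussian", reflect = FALSE)
  expect_equal(loo_log_density(1, 2:8, Mr), loo_log_density(1, 2:8, Mp),
               tolerance = 1e-6)
  # coincident reflections at the origin: S_ij = 4 L(0)^2 / (b1 b2)
  Mo <- alb_kernel_matrix(matrix(0, 2, 2), c(0.5, 0.5), "gaussian",
                          reflect = TRUE)
  expect_equal(exp(Mo$logM[1, 2]), 4 * dnorm(0)^2 / 0.25, tolerance = 1e-12)
})

test_that("pooled loo density is the p_mn mixture of own-group and other-group estimates", {
  set.seed(12)
  fx <- random_fixture()
  m <- length(fx$x); n <- length(fx$y)
  p <- (m - 1) / (m + n - 1)
  for (i in seq_len(m)) {
    pooled <- kde_eval(fx$x[i], fx$b, c(fx$x[-i], fx$y), "L0")
    own <- kde_eval(fx$x[i], fx$b, fx$x[-i], "L0")
    other <- kde_eval(fx$x[i], fx$b, fx$y, "L0")
    expect_equal(pooled, p * own + (1 - p) * other, tolerance = 1e-10)
  }
})
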