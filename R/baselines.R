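#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] reporting the statistic
#' \eqn{D = \sup_u |\hat F_m(u) - \hat G_n(u)|} with the standard asymptotic
#' p-value, in the common report format of the package's baselines.
#'
#' @param x,y Non-empty univariate samples.
#' @return An object of class `"alb_baseline"`: list with `method`,
#'   `statistic`, `p_value`, `settings`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(
    list(method = "ks", statistic = unname(kt$statistic),
         p_value = unname(kt$p.value), settings = list(exact = FALSE)),
    class = "alb_baseline"
  )
}

#' Kernel L2-distance permutation test (Bowman style)
#'
#' Two-sample test based on the integrated squared difference of Gaussian
#' kernel density estimates,
#' \deqn{T = \int \{\hat f_X(u \mid h) - \hat f_Y(u \mid h)\}^2\, du,}
#' with a common normal-reference bandwidth computed from the pooled sample
#' ([stats::bw.nrd()]) and a label-permutation p-value. The integral is exact:
#' with Gaussian kernels, \eqn{\int \phi_h(u-a)\phi_h(u-b)\,du =
#' \phi_{h\sqrt2}(a-b)}, so T is a quadratic form \eqn{a^\top W a} in the
#' signed label weights \eqn{a_i = g_i/m - (1-g_i)/n} with
#' \eqn{W_{ij} = \phi_{h\sqrt2}(z_i - z_j)}, and the same W serves every
#' permutation.
#'
#' @param x,y Univariate samples, each with at least 2 observations.
#' @param n_perm Number of label permutations.
#' @param bandwidth Common bandwidth h; default is the pooled normal-reference
#'   value.
#' @param seed Integer seed; if `NULL`, drawn and recorded.
#' @return An `"alb_baseline"` with `statistic`, `p_value` (strict-exceedance
#'   proportion), and `settings` (bandwidth, permutations, seed).
#' @export
bowman_l2_test <- function(x, y, n_perm = 999L, bandwidth = NULL,
                           seed = NULL) {
  s <- combine_samples(x, y)
  h <- if (is.null(bandwidth)) stats::bw.nrd(s$z) else bandwidth
  stopifnot(is.finite(h), h > 0, n_perm >= 1L)
  W <- stats::dnorm(outer(s$z, s$z, "-"), sd = h * sqrt(2))
  stat_of <- function(g) {
    a <- g / s$m - (1 - g) / s$n
    drop(a %*% W %*% a)
  }
  observed <- stat_of(as.numeric(s$labels == 1L))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  t_star <- withr_seed(seed, {
    G <- random_label_matrix(s$m, s$n, n_perm)
    A <- G / s$m - (1 - G) / s$n
    colSums(A * (W %*% A))
  })
  structure(
    list(method = "bowman", statistic = observed,
         p_value = mean(t_star > observed),
         settings = list(bandwidth = h, n_perm = n_perm, seed = seed)),
    class = "alb_baseline"
  )
}

#' @export
print.alb_baseline <- function(x, ...) {
  cat("Two-sample test [", x$method, "]: statistic = ",
      format(x$statistic, digits = 6), ", p-value = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
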