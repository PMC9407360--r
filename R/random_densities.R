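#' Normal mixture distributions
#'
#' Container for a finite normal mixture with weights `weights`, component
#' means `means` and component standard deviations `sds`.
#'
#' @param weights Non-negative weights summing to 1 (tolerance 1e-12).
#' @param means,sds Component means and (positive) standard deviations.
#' @return An object of class `"normal_mixture"`.
#' @export
normal_mixture <- function(weights, means, sds) {
  stopifnot(length(weights) == length(means), length(means) == length(sds),
            all(is.finite(c(weights, means, sds))))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be non-negative and sum to 1")
  if (any(sds <= 0)) stop("component standard deviations must be positive")
  structure(list(weights = weights, means = means, sds = sds),
            class = "normal_mixture")
}

#' @export
print.normal_mixture <- function(x, ...) {
  cat("Normal mixture with", length(x$weights), "component(s)\n")
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds),
        digits = 4)
  invisible(x)
}

#' Randomly generated normal-mixture density
#'
#' Draws a normal mixture from the benchmark prior used to study the
#' unconditional behaviour of the ALB statistic:
#' * the number of components M is drawn from \{2, ..., 20\} with
#'   \eqn{P(M = m) \propto 1/m};
#' * given M, the weights are Dirichlet(1/2, ..., 1/2);
#' * the component variances are i.i.d. inverse-gamma with shape 1/2 and
#'   scale 1/2 (density \eqn{\propto x^{-3/2} e^{-1/(2x)}}), giving a heavy
#'   right tail of scales;
#' * the means are conditionally independent, \eqn{\mu_j | \sigma_j \sim
#'   N(0, \sigma_j^2)}.
#'
#' Uses the current R random number stream; call `set.seed()` first for
#' reproducibility.
#'
#' @return A [normal_mixture()].
#' @examples
#' set.seed(11)
#' d <- draw_random_mixture()
#' @export
draw_random_mixture <- function() {
  support <- 2:20
  M <- sample(support, 1L, prob = 1 / support)
  g <- stats::rgamma(M, shape = 0.5)          # Dirichlet(1/2,...,1/2)
  w <- g / sum(g)
  sigma2 <- 1 / stats::rgamma(M, shape = 0.5, rate = 0.5)
  mu <- stats::rnorm(M, mean = 0, sd = sqrt(sigma2))
  normal_mixture(w, mu, sqrt(sigma2))
}

#' @rdname normal_mixture
#' @param x Evaluation points.
#' @param d A `"normal_mixture"`.
#' @export
dmixnorm <- function(x, d) {
  stopifnot(inherits(d, "normal_mixture"))
  v <- vapply(seq_along(d$weights), function(j)
    d$weights[j] * stats::dnorm(x, d$means[j], d$sds[j]),
    numeric(length(x)))
  if (is.matrix(v)) rowSums(v) else sum(v)
}

#' @rdname normal_mixture
#' @param k Number of draws.
#' @export
rmixnorm <- function(k, d) {
  stopifnot(inherits(d, "normal_mixture"))
  j <- sample.int(length(d$weights), k, replace = TRUE, prob = d$weights)
  stats::rnorm(k, d$means[j], d$sds[j])
}

#' Conditional-level experiment for the ALB permutation test
#'
#' Replicates the small-permutation-count calibration study: for each of
#' `replicates` independently generated pairs of samples, the likelihood
#' cross-validation bandwidth is selected, `n_perm1` permuted statistics give
#' an estimated 1-alpha critical percentile, and the proportion of `n_perm2`
#' further permuted statistics exceeding it is recorded as the replicate's
#' approximate conditional level. Their mean estimates the unconditional
#' level of the test based on `n_perm1` permutations.
#'
#' `rx` and `ry` generate the two samples; under the null they are the same
#' distribution (the default draws both standard normal, which is without loss
#' of generality since the null distribution of the statistic is location-
#' scale invariant). Note the conditional level concerns the *permutation*
#' null, so the protocol applies unchanged when `rx` and `ry` differ.
#'
#' @param m,n Sample sizes.
#' @param replicates Number of replicate sample pairs.
#' @param rx,ry Functions of one argument k returning k draws.
#' @param kernel Kernel or kernel name.
#' @param n_perm1,n_perm2 First- and second-stage permutation counts.
#' @param alpha Nominal level.
#' @param seed Master seed; per-replicate child seeds are derived from it.
#' @param band Interval whose coverage share is reported in the summary.
#' @return An object of class `"alb_level_experiment"`: list with `levels`
#'   (one conditional level per replicate), `mean_level`, `share_in_band`,
#'   `band`, and the configuration.
#' @export
run_level_experiment <- function(m = 50L, n = 50L, replicates = 500L,
                                 rx = stats::rnorm, ry = stats::rnorm,
                                 kernel = "L0", n_perm1 = 338L,
                                 n_perm2 = 3845L, alpha = 0.05,
                                 seed = NULL, band = c(0.03, 0.07)) {
  stopifnot(replicates >= 1L)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  seeds <- withr_seed(seed, replicate_seeds(replicates))
  levels <- vapply(seq_len(replicates), function(r) {
    withr_seed(seeds[r], {
      x <- rx(m); y <- ry(n)
      conditional_level(x, y, kernel = kernel, n_perm1 = n_perm1,
                        n_perm2 = n_perm2, alpha = alpha,
                        seed = child_seed())
    })
  }, numeric(1))
  structure(
    list(levels = levels, mean_level = mean(levels),
         share_in_band = mean(levels >= band[1] & levels <= band[2]),
         band = band, m = m, n = n, replicates = replicates,
         n_perm1 = n_perm1, n_perm2 = n_perm2, alpha = alpha, seed = seed),
    class = "alb_level_experiment"
  )
}

#' @export
print.alb_level_experiment <- function(x, ...) {
  cat("Conditional-level experiment: ", x$replicates, " replicates, m = ",
      x$m, ", n = ", x$n, ", ", x$n_perm1, " vs ", x$n_perm2,
      " permutations\n", sep = "")
  cat("  mean conditional level (approx. unconditional level): ",
      format(x$mean_level, digits = 4), "\n", sep = "")
  cat("  share of levels in [", x$band[1], ", ", x$band[2], "]: ",
      format(x$share_in_band, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Power comparison of the ALB test against baselines
#'
#' For each replicate pair of samples, computes the permutation p-value of the
#' ALB test (likelihood cross-validation bandwidth, `n_perm` permutations) and
#' the p-values of the requested baseline tests on the same data.
#'
#' @inheritParams run_level_experiment
#' @param n_perm Permutations for the ALB (and Bowman) permutation p-values.
#' @param methods Subset of `c("alb", "ks", "bowman")`.
#' @return An object of class `"alb_power_comparison"`: list with `p_values`
#'   (data frame: replicate, one column per method), `rejections` (named count
#'   of p-values below `alpha` per method), and the configuration.
#' @export
run_power_comparison <- function(m = 50L, n = 50L, replicates = 500L,
                                 rx = stats::rnorm,
                                 ry = function(k) stats::rnorm(k, sd = 2),
                                 kernel = "L0", n_perm = 3845L, alpha = 0.05,
                                 methods = c("alb", "ks", "bowman"),
                                 seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(replicates >= 1L)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  seeds <- withr_seed(seed, replicate_seeds(replicates))
  rows <- lapply(seq_len(replicates), function(r) {
    withr_seed(seeds[r], {
      x <- rx(m); y <- ry(n)
      out <- list(replicate = r)
      if ("alb" %in% methods)
        out$alb <- permutation_distribution(x, y, kernel = kernel,
                                            n_perm = n_perm,
                                            seed = child_seed())$p_value
      if ("ks" %in% methods)
        out$ks <- ks_two_sample(x, y)$p_value
      if ("bowman" %in% methods)
        out$bowman <- bowman_l2_test(x, y, n_perm = n_perm,
                                     seed = child_seed())$p_value
      out
    })
  })
  p <- do.call(rbind, lapply(rows, as.data.frame))
  rej <- vapply(methods, function(mm) sum(p[[mm]] < alpha), numeric(1))
  structure(
    list(p_values = p, rejections = rej, alpha = alpha, m = m, n = n,
         replicates = replicates, n_perm = n_perm, methods = methods,
         seed = seed),
    class = "alb_power_comparison"
  )
}

#' @export
print.alb_power_comparison <- function(x, ...) {
  cat("Power comparison: ", x$replicates, " replicates, m = ", x$m,
      ", n = ", x$n, ", ", x$n_perm, " permutations, alpha = ", x$alpha,
      "\n  rejections: ", paste(names(x$rejections), x$rejections,
                                sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

replicate_seeds <- function(k) sample.int(.Machine$integer.max - 1L, k)
child_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)
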