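#' Permutation null distribution of the ALB statistic
#'
#' Conditional on the pooled order statistics, every relabelling of the m+n
#' observations into groups of sizes m and n is equally likely under the null
#' hypothesis of equal densities. This function draws `n_perm` uniformly
#' random relabellings, computes the permuted statistic ALB* for each through
#' the shared pairwise kernel matrix (the bandwidth is permutation-invariant,
#' so it is fixed), and summarizes the permutation distribution.
#'
#' The permutation p-value is the proportion of ALB* values strictly larger
#' than the observed ALB. The critical value is `max(0, t)` where t is the
#' empirical 1-alpha quantile of the ALB* values: rejection never occurs on a
#' negative statistic, which would constitute evidence *for* equality.
#'
#' @param x,y The two samples (vectors, or 2-column matrices).
#' @param b Bandwidth; if `NULL`, selected by [select_bandwidth()] on the
#'   pooled sample.
#' @param kernel Kernel or kernel name.
#' @param n_perm Number of label permutations.
#' @param alpha Level used for the reported quantile and critical value.
#' @param seed Integer seed for reproducibility; if `NULL`, an entropy-derived
#'   seed is drawn and recorded in the result.
#' @param reflect Unit-square reflection correction (bivariate only).
#' @param add_one Use the add-one p-value `(#\{ALB* >= ALB\} + 1)/(N + 1)`
#'   instead of the plain proportion of strict exceedances.
#' @return An object of class `"alb_perm"`: list with `observed`, `alb_star`
#'   (length `n_perm`), `p_value`, `t_quantile`, `critical_value`, `alpha`,
#'   `n_perm`, `bandwidth`, `kernel`, `m`, `n`, `seed`.
#' @examples
#' set.seed(1)
#' pd <- permutation_distribution(rnorm(12), rnorm(12), b = 0.5,
#'                                kernel = "gaussian", n_perm = 99, seed = 7)
#' pd$p_value
#' @export
permutation_distribution <- function(x, y, b = NULL, kernel = "L0",
                                     n_perm = 999L, alpha = 0.05,
                                     seed = NULL, reflect = FALSE,
                                     add_one = FALSE) {
  stopifnot(n_perm >= 1L)
  n_perm <- as.integer(n_perm)
  s <- combine_samples(x, y)
  if (is.null(b)) b <- select_bandwidth(s$z, kernel, reflect = reflect)$b
  M <- alb_kernel_matrix(s$z, b, kernel, reflect)
  eng <- alb_engine(M)
  observed <- alb_from_labels(eng, s$labels, s$m, s$n)$alb
  if (is.null(seed))
    seed <- sample.int(.Machine$integer.max - 1L, 1L)
  alb_star <- withr_seed(seed, {
    G <- random_label_matrix(s$m, s$n, n_perm)
    alb_from_G(eng, G, s$m, s$n)
  })
  tq <- perm_quantile(alb_star, alpha)
  structure(
    list(observed = observed, alb_star = alb_star,
         p_value = perm_p_value(observed, alb_star, add_one = add_one),
         t_quantile = tq, critical_value = max(0, tq),
         alpha = alpha, n_perm = n_perm, bandwidth = b, kernel = M$kernel,
         m = s$m, n = s$n, seed = seed),
    class = "alb_perm"
  )
}

#' @export
print.alb_perm <- function(x, ...) {
  cat("ALB permutation distribution (", x$n_perm, " permutations)\n",
      "  observed ALB = ", format(x$observed, digits = 6),
      ", p-value = ", format(x$p_value, digits = 4), "\n",
      "  1-alpha quantile t = ", format(x$t_quantile, digits = 6),
      ", critical value max(0, t) = ", format(x$critical_value, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Permutation p-value
#'
#' The proportion of permuted statistics strictly larger than the observed
#' one; ties count as non-exceedances. The add-one variant
#' `(#\{ALB* >= observed\} + 1)/(N + 1)` guarantees validity at the cost of a
#' small conservative bias and is available behind a flag.
#'
#' @param observed Observed statistic.
#' @param alb_star Permuted statistics (non-empty).
#' @param add_one Use the add-one variant.
#' @export
perm_p_value <- function(observed, alb_star, add_one = FALSE) {
  stopifnot(length(alb_star) >= 1L)
  if (add_one) (sum(alb_star >= observed) + 1) / (length(alb_star) + 1)
  else mean(alb_star > observed)
}

#' Permutation critical value
#'
#' `max(0, t)` where t is the empirical 1-alpha quantile of the permuted
#' statistics, taken as the order statistic at position
#' `ceiling((1-alpha) * N)` (a conservative convention). For large samples
#' under the null the quantile itself is typically negative, in which case the
#' critical value is 0: positive ALB is already evidence against equality.
#'
#' @param alb_star Permuted statistics.
#' @param alpha Level, strictly between 0 and 1.
#' @export
perm_critical_value <- function(alb_star, alpha = 0.05) {
  max(0, perm_quantile(alb_star, alpha))
}

perm_quantile <- function(alb_star, alpha) {
  stopifnot(alpha > 0, alpha < 1, length(alb_star) >= 1L)
  sort(alb_star)[ceiling((1 - alpha) * length(alb_star))]
}

#' Conditional level of a permutation test based on few permutations
#'
#' Estimates the conditional (given the data) rejection probability of the
#' test whose critical value is the 1-alpha percentile of `n_perm1`
#' permutations: draws `n_perm1` permuted statistics, takes their percentile,
#' then draws `n_perm2` further permutations and returns the proportion
#' strictly exceeding that percentile. Values near alpha indicate that
#' `n_perm1` permutations already locate the critical value well.
#'
#' @inheritParams permutation_distribution
#' @param n_perm1 Permutations used to estimate the critical percentile.
#' @param n_perm2 Further permutations used to measure the exceedance rate.
#' @return A single number in [0, 1].
#' @export
conditional_level <- function(x, y, b = NULL, kernel = "L0",
                              n_perm1 = 338L, n_perm2 = 3845L, alpha = 0.05,
                              seed = NULL, reflect = FALSE) {
  stopifnot(n_perm1 >= 1L, n_perm2 >= 1L)
  s <- combine_samples(x, y)
  if (is.null(b)) b <- select_bandwidth(s$z, kernel, reflect = reflect)$b
  M <- alb_kernel_matrix(s$z, b, kernel, reflect)
  eng <- alb_engine(M)
  if (is.null(seed))
    seed <- sample.int(.Machine$integer.max - 1L, 1L)
  withr_seed(seed, {
    g1 <- random_label_matrix(s$m, s$n, n_perm1)
    g2 <- random_label_matrix(s$m, s$n, n_perm2)
    first <- alb_from_G(eng, g1, s$m, s$n)
    second <- alb_from_G(eng, g2, s$m, s$n)
    mean(second > perm_quantile(first, alpha))
  })
}

# 0/1 indicator matrix, one column per permutation, m ones marking the X-group
random_label_matrix <- function(m, n, N) {
  G <- matrix(0, nrow = m + n, ncol = N)
  for (p in seq_len(N)) G[sample.int(m + n, m), p] <- 1
  G
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
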