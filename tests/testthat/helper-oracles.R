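# Brute-force ALB: direct kernel-density evaluations, no kernel matrix.
# Independent of the engine it checks.
brute_alb <- function(x, y, b, kernel = "gaussian", reflect = FALSE) {
  bivar <- is.matrix(x)
  m <- if (bivar) nrow(x) else length(x)
  n <- if (bivar) nrow(y) else length(y)
  z <- if (bivar) rbind(x, y) else c(x, y)
  get_row <- function(obj, i) if (bivar) obj[i, , drop = FALSE] else obj[i]
  drop_row <- function(obj, i) if (bivar) obj[-i, , drop = FALSE] else obj[-i]
  f <- function(u, subset) {
    if (bivar && reflect)
      kde_eval2_reflected(u, b[1], b[2], subset, kernel, log = TRUE)
    else if (bivar)
      kde_eval2(u, b[1], b[2], subset, kernel, log = TRUE)
    else
      kde_eval(u, b, subset, kernel, log = TRUE)
  }
  lb <- vapply(seq_len(m + n), function(i) {
    own <- if (i <= m) drop_row(x, i) else drop_row(y, i - m)
    f(get_row(z, i), own) - f(get_row(z, i), drop_row(z, i))
  }, numeric(1))
  list(alb = mean(lb), log_bf = lb)
}

# Random univariate fixture with group sizes in [3, 5] each
random_fixture <- function() {
  m <- sample(3:5, 1)
  n <- sample(3:5, 1)
  list(x = rnorm(m, sd = runif(1, 0.5, 2)),
       y = rnorm(n, mean = runif(1, -1, 1)),
       b = runif(1, 0.2, 2))
}
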