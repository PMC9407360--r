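#' Kernel density estimate at a point
#'
#' Evaluates the estimator
#' \deqn{\hat f_K(u \mid h, U) = \frac{1}{kh}\sum_{i=1}^k K\!\left(\frac{u - U_i}{h}\right)}
#' for a univariate sample `U`. The log variant is computed by log-sum-exp
#' over the log-kernel terms, so heavy-tailed kernels at small bandwidths do
#' not underflow.
#'
#' @param u Evaluation points (numeric vector).
#' @param h Bandwidth, a single positive number.
#' @param data The sample U, a non-empty numeric vector.
#' @param kernel An [alb_kernel()] or a kernel name.
#' @param log If `TRUE`, return the log-density.
#' @return Numeric vector of (log-)density values, one per element of `u`.
#' @examples
#' kde_eval(0, 1, 0, "gaussian")        # dnorm(0)
#' kde_eval(1, 1, c(0, 2), "gaussian")  # dnorm(1)
#' @export
kde_eval <- function(u, h, data, kernel = "L0", log = FALSE) {
  kernel <- resolve_kernel(kernel)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("bandwidth 'h' must be a single positive number")
  if (length(data) == 0L) stop("'data' must be non-empty")
  stopifnot(all(is.finite(u)), all(is.finite(data)))
  lt <- outer(u, data, function(a, b) kernel$log_density((a - b) / h)) -
    log(h) - log(length(data))
  out <- apply(lt, 1L, logsumexp)
  if (log) out else exp(out)
}

#' Bivariate product-kernel density estimate
#'
#' Evaluates
#' \deqn{\hat f_K(u \mid h, U) = \frac{1}{k h_1 h_2}\sum_i
#'   K\!\left(\frac{u_1 - U_{i1}}{h_1}\right)
#'   K\!\left(\frac{u_2 - U_{i2}}{h_2}\right)}
#' with one bandwidth per coordinate.
#'
#' @param u Evaluation point(s): a length-2 vector or a 2-column matrix.
#' @param h1,h2 Positive bandwidths for the two coordinates.
#' @param data A 2-column matrix of observations.
#' @inheritParams kde_eval
#' @export
kde_eval2 <- function(u, h1, h2, data, kernel = "L0", log = FALSE) {
  kernel <- resolve_kernel(kernel)
  if (any(c(h1, h2) <= 0) || !all(is.finite(c(h1, h2))))
    stop("bandwidths must be positive")
  u <- as_points2(u)
  data <- as_points2(data)
  if (nrow(data) == 0L) stop("'data' must be non-empty")
  out <- vapply(seq_len(nrow(u)), function(r) {
    lt <- kernel$log_density((u[r, 1L] - data[, 1L]) / h1) +
      kernel$log_density((u[r, 2L] - data[, 2L]) / h2)
    logsumexp(lt) - log(h1) - log(h2) - log(nrow(data))
  }, numeric(1))
  if (log) out else exp(out)
}

#' Boundary-corrected density estimate on the unit square
#'
#' Augments the sample with its three reflections across the axes (see
#' [reflect_unit_square()]), computes the product-kernel estimate from the
#' 4k reflected points, and multiplies by 4 so the estimate integrates to 1
#' over the unit square. Reduces the boundary bias of the plain estimate along
#' the lines x = 0 and y = 0.
#'
#' @inheritParams kde_eval2
#' @export
kde_eval2_reflected <- function(u, h1, h2, data, kernel = "L0", log = FALSE) {
  data <- as_points2(data)
  refl <- reflect_unit_square(data)$points
  out <- kde_eval2(u, h1, h2, refl, kernel, log = TRUE) + log(4)
  if (log) out else exp(out)
}

#' Reflect unit-square points across the axes
#'
#' Each observation (x, y) in the unit square generates three mirror images
#' (x, -y), (-x, -y) and (-x, y). Kernel estimation from the augmented set of
#' 4k points, rescaled by 4, corrects the boundary bias of the estimate along
#' x = 0 and y = 0.
#'
#' @param points A 2-column matrix (or length-2 vector) of points in
#'   the unit square; points outside it are an error.
#' @return A list with `points`, a (4k x 2) matrix holding the originals
#'   followed by the three reflected blocks, and `index`, an integer vector
#'   mapping each output row to the originating input row.
#' @examples
#' reflect_unit_square(c(0.2, 0.3))$points
#' @export
reflect_unit_square <- function(points) {
  p <- as_points2(points)
  if (any(p < 0 | p > 1))
    stop("all points must lie in the unit square [0,1]^2")
  k <- nrow(p)
  out <- rbind(
    p,
    cbind(p[, 1L], -p[, 2L]),
    cbind(-p[, 1L], -p[, 2L]),
    cbind(-p[, 1L], p[, 2L])
  )
  list(points = out, index = rep(seq_len(k), times = 4L))
}

#' Pairwise kernel matrix of a pooled sample
#'
#' Builds the matrix of scaled kernel evaluations between all pairs of pooled
#' observations at a fixed bandwidth. Because the matrix depends only on the
#' observations (never on group labels), a single matrix supports the observed
#' statistic and every label permutation: permuting labels merely
#' re-partitions its rows.
#'
#' Entries are stored on the log scale:
#' `logM[i, j] = log L((z_i - z_j)/b) - log b` (univariate), or the log of the
#' product kernel with per-coordinate bandwidths (bivariate). With
#' `reflect = TRUE` (bivariate unit-square data) entry (i, j) is the log of
#' the summed kernel contributions of observation j and its three reflections,
#' i.e. the j-th term of the 4-fold boundary-corrected estimate at z_i. The
#' diagonal is excluded by convention (log scale: `-Inf`), so row averages are
#' leave-one-out densities.
#'
#' @param z Pooled observations: numeric vector, or 2-column matrix.
#' @param b Bandwidth: scalar (univariate) or length-2 (bivariate).
#' @param kernel An [alb_kernel()] or kernel name.
#' @param reflect Apply the unit-square reflection correction (bivariate
#'   only).
#' @return An object of class `"alb_kernel_matrix"`: list with `logM`,
#'   `b`, `kernel` (name), `reflect`, `n` and `d`.
#' @export
alb_kernel_matrix <- function(z, b, kernel = "L0", reflect = FALSE) {
  kernel <- resolve_kernel(kernel)
  if (is.matrix(z) && ncol(z) == 2L) {
    if (length(b) != 2L || any(!is.finite(b)) || any(b <= 0))
      stop("bivariate data need two positive bandwidths")
    if (reflect && any(z < 0 | z > 1))
      stop("reflection correction requires data in the unit square")
    lx <- scaled_log_kernel(z[, 1L], b[1L], kernel, reflect)
    ly <- scaled_log_kernel(z[, 2L], b[2L], kernel, reflect)
    logM <- lx + ly - log(b[1L]) - log(b[2L])
  } else {
    z <- as.numeric(z)
    if (length(b) != 1L || !is.finite(b) || b <= 0)
      stop("bandwidth 'b' must be a single positive number")
    if (reflect)
      stop("reflection correction is only defined for bivariate data")
    logM <- kernel$log_density(outer(z, z, "-") / b) - log(b)
  }
  diag(logM) <- -Inf
  structure(
    list(logM = logM, b = b, kernel = kernel$name, reflect = reflect,
         n = nrow(logM), d = if (is.matrix(z) && ncol(z) == 2L) 2L else 1L),
    class = "alb_kernel_matrix"
  )
}

# log of L(d/b) or, with reflection, log[L((x_i-x_j)/b) + L((x_i+x_j)/b)]
# for one coordinate; the (1/b) factor is applied by the caller.
scaled_log_kernel <- function(x, b, kernel, reflect) {
  ld <- kernel$log_density(outer(x, x, "-") / b)
  if (!reflect) return(ld)
  ls <- kernel$log_density(outer(x, x, "+") / b)
  mx <- pmax(ld, ls)
  mx + log(exp(ld - mx) + exp(ls - mx))
}

#' @export
print.alb_kernel_matrix <- function(x, ...) {
  cat("Pairwise kernel matrix: ", x$n, " observations, kernel ", x$kernel,
      ", bandwidth ", paste(signif(x$b, 4), collapse = ", "),
      if (x$reflect) ", reflected" else "", "\n", sep = "")
  invisible(x)
}

#' Leave-one-out log-density from a kernel matrix
#'
#' Computes `log[(1/#S') sum_{j in S'} M[i, j]]` where `S'` is the given
#' subset of observations with `i` removed — the log of the kernel density
#' estimate at observation i built from the subset, leaving i out. Evaluated
#' stably by log-sum-exp on the stored log-kernel entries. With a reflected
#' kernel matrix this is the boundary-corrected leave-out-four estimate (the
#' observation and its three mirror images are all excluded, since they share
#' index i).
#'
#' @param i Index of the evaluation observation.
#' @param subset Indices (integer or logical mask) of the estimating subset;
#'   `i` is removed internally if present.
#' @param M An [alb_kernel_matrix()].
#' @return The leave-one-out log-density (a single number).
#' @export
loo_log_density <- function(i, subset, M) {
  stopifnot(inherits(M, "alb_kernel_matrix"))
  if (is.logical(subset)) subset <- which(subset)
  subset <- setdiff(as.integer(subset), as.integer(i))
  if (length(subset) == 0L)
    stop("subset is empty after removing observation ", i)
  logsumexp(M$logM[i, subset]) - log(length(subset))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

as_points2 <- function(u) {
  if (is.null(dim(u))) {
    if (length(u) != 2L) stop("expected a 2-dimensional point")
    u <- matrix(u, ncol = 2L)
  }
  u <- as.matrix(u)
  if (ncol(u) != 2L) stop("expected 2-column point data")
  storage.mode(u) <- "double"
  if (!all(is.finite(u))) stop("non-finite coordinates in point data")
  u
}
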