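---
title: "The ALB two-sample test: model, computation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ALB two-sample test: model, computation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(albtest)
```

## The testing problem and the statistic

Given independent samples $X_1,\dots,X_m \sim f$ and $Y_1,\dots,Y_n \sim g$,
we test $H_0: f \equiv g$. Write $Z = (X_1,\dots,X_m,Y_1,\dots,Y_n)$ for the
pooled sample and $\hat f_K(u \mid h, U) = (kh)^{-1}\sum_i K\{(u-U_i)/h\}$
for a kernel density estimate from an arbitrary set $U$ of $k$ points.

For each held-out observation $Z_i$ two models compete: a kernel estimate
built from $Z_i$'s **own group** with $Z_i$ removed (densities may differ),
and one built from the **pooled sample** with $Z_i$ removed (densities are
equal). Placing a prior $\pi$ on the bandwidth turns each into a marginal
likelihood for the single datum $Z_i$, and their ratio into a Bayes factor
$B_i$. The test statistic is the average of the log-Bayes factors,

$$\mathrm{ALB} = \frac{1}{m+n}\sum_{i=1}^{m+n}\log B_i.$$

The key simplification is the **scale-family prior** $\pi(h)=\pi_0(h/b)/b$:
integrating a kernel estimate with kernel $K$ over this prior yields another
kernel estimate whose kernel is

$$L(z) = \int_0^\infty u^{-1}\,\pi_0(u)\,K(z/u)\,du$$

and whose bandwidth is the prior scale $b$. So every marginal likelihood is
itself a kernel estimate — no numerical integration appears in the statistic
path — and

$$(m+n)\,\mathrm{ALB} = \sum_{i=1}^m \log \hat f_L(X_i \mid b, X_{-i})
 + \sum_{j=1}^n \log \hat f_L(Y_j \mid b, Y_{-j})
 - \sum_{i=1}^{m+n} \log \hat f_L(Z_i \mid b, Z_{-i}),$$

the log of a ratio of leave-one-out cross-validation likelihoods
("different" over "equal"). `alb_statistic()` computes this; tests verify
that the mean-of-$\log B_i$ and three-sum forms agree to $10^{-12}$ and that
both match brute-force kernel-density evaluations.

Averaging over the prior has a second, quantifiable benefit: $L$ always has
tails at least as heavy as $K$'s, and heavy tails are exactly what
likelihood cross-validation needs to behave well. The induced-kernel
construction is available directly as `induced_kernel()`; with a Gaussian
base kernel and the prior under which $h^2$ is inverse-gamma$(\nu/2,\nu/2)$
(`scale_mixture_prior()`), $L$ is the Student-$t_\nu$ density — the classical
normal scale-mixture identity, verified in the tests against `dt()` by
quadrature.

ALB is **sharply bounded above** (`alb_upper_bound()`): with
$p_{m,n}=(m-1)/(m+n-1)$, each own-group estimate enters the pooled one as a
mixture component,
$\hat f_L(X_i \mid b, Z_{-i}) = p_{m,n}\hat f_L(X_i \mid b, X_{-i}) +
(1-p_{m,n})\hat f_L(X_i \mid b, Y)$, giving $\log B_i \le -\log p_{m,n}$ and
$\mathrm{ALB} \le \log 2\cdot\max\{\tfrac{m}{m-1},\tfrac{n}{n-1}\}$ —
effectively $\log 2$. An average of single-observation Bayes factors can
never be overwhelming evidence, which is why the statistic is calibrated
frequentistically instead.

## Bandwidth: likelihood cross-validation on the pooled sample

`select_bandwidth()` maximizes the pooled leave-one-out log-likelihood
$\sum_i \log \hat f_L(Z_i \mid b, Z_{-i})$ — the denominator of the ALB
likelihood ratio. Because this criterion sees only the pooled observations,
the selected $\hat b$ is identical for every relabelling of the groups, so it
is computed once and shared by all permutations (a large computational
saving, and the "same function of the data" principle applied consistently).
The criterion is evaluated on the *sorted* pooled sample, which makes
$\hat b$ bit-reproducible under any reordering, not merely equal in exact
arithmetic.

The search strategy is a package decision (nothing canonical exists): a
41-point log-spaced grid on $[10^{-3}s,\,10\,s]$ with $s$ a robust scale of
the pooled data (MAD, falling back to IQR$/1.349$, then to the standard
deviation), then golden-section refinement on $\log b$ to relative tolerance
$10^{-4}$. The criterion is smooth and in practice unimodal in $\log b$; the
robust scale keeps outliers from dragging the grid. If the grid maximum sits
on a boundary the interval is widened tenfold and the fit flagged
(`widened`). For bivariate data, per-coordinate univariate fits initialize a
Nelder–Mead search over $(\log b_1,\log b_2)$; this keeps the bivariate path
deterministic and seed-free. The full evaluation trace is returned for
auditability.

Default kernel: **Hall's $L_0$**,
$L_0(u) \propto \exp\{-\tfrac12[\log(1+|u|)]^2\}$, for which the
cross-validated bandwidth is asymptotically optimal in Kullback–Leibler
loss; all simulation defaults use it. A Gaussian kernel is provided as a
building block but is deliberately *not* the default: likelihood
cross-validation is known to fail for kernels with Gaussian-or-lighter
tails.

## The permutation null and its calibration

Conditional on the pooled order statistics, all $\binom{m+n}{m}$ group
assignments are equally likely under $H_0$, so `permutation_distribution()`
draws uniformly random relabellings and recomputes the statistic for each.
Two implementation facts make this cheap: $\hat b$ is shared (above), and
the pairwise kernel evaluations are cached in a label-free matrix
(`alb_kernel_matrix()`), so each permuted statistic is an $O((m+n)^2)$
reduction — in practice one BLAS matrix product for the whole batch of
permutations. Entries are stored as logs and exponentiated after a per-row
shift (exact log-sum-exp), so heavy-tailed kernels at tiny bandwidths never
underflow.

Conventions, each recorded in the output:

* **p-value**: the proportion of permuted statistics *strictly* larger than
  the observed one; ties count against rejection. An add-one variant
  $(\#\{\mathrm{ALB}^* \ge \mathrm{ALB}\}+1)/(N+1)$ is available behind a
  flag for users who want guaranteed validity at finite $N$.
* **quantile**: the $1-\alpha$ permutation quantile $t_{m,n}$ is the order
  statistic at position $\lceil (1-\alpha)N \rceil$ — simple and
  conservative.
* **critical value**: $\max(0, t_{m,n})$. Under $H_0$ the statistic is
  negative with probability tending to 1, so $t_{m,n}$ itself is eventually
  negative; rejecting on a negative ALB would be rejecting on evidence *for*
  equality. Flooring at 0 costs nothing asymptotically and keeps the test
  sensible.
* **seeding**: one integer seed drives R's RNG for the permutation draws;
  experiment harnesses spawn per-replicate child seeds from a master seed.
  Identical seeds give bit-identical results (tested).

`conditional_level()` measures how well a *small* number of permutations
locates the critical value: it takes the $1-\alpha$ percentile of $N_1$
permuted statistics and reports the share of $N_2$ further permuted
statistics exceeding it — the conditional level, given the data, of the
$N_1$-permutation test. `run_level_experiment()` replicates this over
freshly generated data pairs; the mean conditional level estimates the
unconditional level.

## The simulation harness and what it emulates

The synthetic designs are the study conditions the package is checked
against, fixed once:

* **Null calibration**: both samples standard normal, $m=n=50$; the null
  distribution of ALB is location–scale invariant, so standard normal is
  without loss of generality. Levels use $N_1=338$ against $N_2=3845$
  permutations at $\alpha=0.05$.
* **Scale alternative**: $N(0,1)$ versus $N(0,2^2)$, $m=n=50$ — a case
  where density-based tests should beat ECDF-based ones, since the densities
  differ most where the distribution functions differ least.
* **Random mixture benchmark** (`draw_random_mixture()`): the number of
  components $M$ on $\{2,\dots,20\}$ with $P(M=m)\propto 1/m$; weights
  Dirichlet$(1/2,\dots,1/2)$; variances i.i.d. inverse-gamma with shape and
  scale $1/2$ (a deliberately heavy-tailed scale law, parameterized
  shape/scale — the common convention; recorded here because shape/rate is
  also in circulation); means $\mu_j \mid \sigma_j \sim N(0,\sigma_j^2)$.
  This produces wildly varied densities — sharp spikes, broad shoulders,
  well-separated modes — to probe the sign behaviour of ALB beyond the
  normal family.

These generators emulate i.i.d. continuous univariate data. They do not
emulate ties (real measurement rounding), dependence, or contamination, so
the calibration results say nothing about those settings; see limitations.

Reference problem sizes: the packaged study runs 500 replicates of each
experiment with the full 338/3845 permutation counts
(`scripts/acceptance.R`); the test suite exercises the same pipelines at 100
replicates and reduced second-stage counts, chosen so the whole suite runs
in well under a minute per experiment while binomial noise at 100 replicates
(standard error $\approx 0.002$ on a level of $0.05$) stays far inside the
asserted bands.

## Baselines

`ks_two_sample()` wraps `stats::ks.test()` with the asymptotic p-value.
`bowman_l2_test()` implements a kernel-$L_2$ permutation test: the
integrated squared difference of Gaussian-kernel estimates with a common
pooled normal-reference bandwidth (`bw.nrd`), the integral evaluated in
closed form through the Gaussian convolution identity
$\int\phi_h(u-a)\phi_h(u-b)\,du=\phi_{h\sqrt2}(a-b)$, and the null assessed
by the same label-permutation machinery. The historical test this emulates
left its bandwidth choice unrecorded, so our version is a faithful member of
the family rather than a replica; its headline numbers should be read as
soft references.

## The bivariate extension

With bivariate data the kernel is a product of univariate kernels with one
bandwidth per coordinate, and the scale-family prior factorizes the same
way, so everything above carries over (`kde_eval2()`, joint bandwidth
selection). For data supported on the unit square — such as normalized
energy measurements — plain estimates are biased along the axes $x=0$ and
$y=0$. `reflect_unit_square()` mirrors each observation across both axes;
the estimate built from the $4k$ reflected points and multiplied by 4
integrates to 1 over the positive quadrant exactly (tested by double
quadrature). In the leave-one-out scheme an observation is excluded
*together with its three mirror images*, so the estimate never sees the
point it is evaluated at. The correction addresses only the lower
boundaries; mass still leaks past $x=1$, $y=1$ when bandwidths are large
relative to the distance of the data from those edges. The recommended
bivariate kernel is $t_3$ (Gaussian base kernel under its generating prior)
— heavy-tailed, smooth, and exact in closed form.

## Numerical choices, degenerate inputs, limitations

* All kernels expose the log-density as the primitive; every leave-one-out
  average is a log-sum-exp. The induced-kernel quadrature integrates on the
  $u=e^t$ scale (absolute tolerance $10^{-8}$) because prior mass near 0 is
  otherwise easy to miss; nodes where $e^{\pm t}$ overflows contribute
  exactly 0 and are dropped.
* Duplicate observations are allowed in the statistic (kernel matrix entries
  stay finite; no jittering). But if the pooled sample contains *exact
  ties*, the cross-validation criterion diverges as $b\to 0$ and bandwidth
  selection rightly fails with a bracketing error — supply a fixed
  `bandwidth` in that case. Identical copies of one sample are the extreme
  case.
* Each group needs at least 2 members ($m>1$, $n>1$), or the leave-one-out
  own-group estimate is empty; bandwidth selection needs at least 3 distinct
  pooled values.
* Univariate boundary correction is not offered (the reflection scheme is
  defined for the bivariate unit square); nor are adaptive bandwidths,
  per-group bandwidths (contrary to the single-pooled-bandwidth principle
  the test is built on), dimensions above 2, or non-product bivariate
  kernels.
* The permutation distribution is sampled with replacement, not enumerated;
  exhaustive enumeration appears only as a test oracle at $m=n=3$.

## A worked example

```{r example}
set.seed(2026)
x <- rnorm(50)
y <- rnorm(50, sd = 2)
fit <- alb_test(x, y, kernel = "L0", n_perm = 999, seed = 11)
fit
```

The observed ALB is positive — the cross-validation likelihood that allows
the densities to differ beats the pooled one — and sits above essentially
all permuted values, so the test rejects. Compare the Kolmogorov–Smirnov
test on the same data:

```{r ks}
ks_two_sample(x, y)
```

A scale difference moves little mass in the ECDF metric but is conspicuous
to density estimates; this is the regime in which the ALB test's power
advantage is largest.
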