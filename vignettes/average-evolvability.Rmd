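---
title: "Quasi-exact average evolvability measures: model, series, and numerical choices"
author: "evolvavg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-exact average evolvability measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evolvavg)
```

## The model

A genetic covariance matrix $\mathbf{G}$ ($p \times p$, symmetric,
nonnegative definite) maps a selection gradient $\boldsymbol\beta$ to a
per-generation response $\Delta\bar{\mathbf z} = \mathbf G \boldsymbol\beta$
(the Lande equation). Writing $\mathbf u = \boldsymbol\beta /
|\boldsymbol\beta|$, the standard measures of evolvability and constraint
are

* evolvability $e = \mathbf u^T \mathbf G \mathbf u$,
* conditional evolvability $c = (\mathbf u^T \mathbf G^{-}\mathbf u)^{-1}$
  (0 when $\boldsymbol\beta \notin R(\mathbf G)$),
* autonomy $a = c/e$ and integration $i = 1 - a$,
* respondability $r = \sqrt{\mathbf u^T \mathbf G^2 \mathbf u}$,
* flexibility $f = e/r$,

and, for comparing two matrices responding to the same gradient, the
response difference $d = \sqrt{\mathbf u^T(\mathbf G_1-\mathbf G_2)^2
\mathbf u}$ and the response correlation $\rho$ of
$\mathbf G_1\boldsymbol\beta$ and $\mathbf G_2\boldsymbol\beta$. All are
ratios of quadratic forms in $\boldsymbol\beta$, hence scale-invariant in
$|\boldsymbol\beta|$. `evolvability()`, `conditional_evolvability()`,
`autonomy()`, `respondability()`, `flexibility()`,
`response_difference()` and `response_correlation()` implement these with
Moore--Penrose handling of singular $\mathbf G$; inputs for which a measure
is undefined (for example $e = 0$ in the denominator of $a$) return `NA`
with a machine-readable `reason` attribute rather than raising, so batch
pipelines keep going.

When many random gradients are of interest — the "random skewers" setting —
the canonical assumption is that $\mathbf u$ is uniform on the unit
hypersphere (equivalently $\boldsymbol\beta$ is spherically distributed).
The average of each measure over this distribution is then a moment of a
(multiple) ratio of quadratic forms in standard normal variables. The
average evolvability is exactly $\bar e = \mathrm{tr}(\mathbf G)/p$; the
other six averages have no elementary closed form but admit exact infinite
series in *top-order zonal/invariant polynomial coefficients*
$d_{i,j,k}(\mathbf A_1, \mathbf A_2, \mathbf A_3)$, the Taylor coefficients
of $\det(\mathbf I - \sum_l t_l \mathbf A_l)^{-1/2}$, with argument matrices
of the form $\mathbf I - \alpha \mathbf A$. For example

$$\bar c = \alpha \sum_{k \ge 0} \frac{(1)_k}{(p/2)_k}
  d_k(\mathbf I - \alpha \mathbf G^{-1}),$$

with $(a)_k$ the rising factorial and $0 < \alpha < 2/\lambda_{\max}
(\mathbf G^{-1})$, and similarly a single series for $\bar r$ (argument
$\mathbf I - \alpha\mathbf G^2$, weights $(-1/2)_k/(p/2)_k$), a hybrid
series over $d_{k,1}$ for $\bar f$, a double series over $d_{i,j}$ for
$\bar a$, the $\bar r$ series with argument $(\mathbf G_1 - \mathbf G_2)^2$
for $\bar d$, and a double series over $d_{i,j,1}$ for $\bar\rho$. The
package evaluates these by the standard recursion

$$\mathbf g_{i,j,k} = \sum_l \mathbf A_l
  (\mathbf g_{\ldots - 1_l} + d_{\ldots - 1_l}\mathbf I), \qquad
  d_{i,j,k} = \frac{\mathrm{tr}(\mathbf g_{i,j,k})}{2(i+j+k)},$$

streamed by total order so only adjacent layers are retained.

`qf_ratio_moment()` exposes the underlying engine in its general form,
$E[(\mathbf x^T\mathbf A\mathbf x)^m / (\mathbf x^T\mathbf B\mathbf x)^n]$
for $\mathbf x \sim N(\boldsymbol\mu, \mathbf I_p)$, including the
noncentral case through the rank-one third argument
$\boldsymbol\mu\boldsymbol\mu^T$; the existence condition $p/2 + m > n$
(positive definite $\mathbf B$) is checked before evaluation. The central
special cases reproduce the dedicated $\bar c$ and $\bar r$ series, which
is verified in the tests to $10^{-9}$.

## Truncation control

For $0 < \alpha \le 1/\lambda_{\max}$ every argument matrix is positive
semidefinite with spectrum in $[0, 1]$, so all polynomial coefficients are
nonnegative. Consequently truncation *underestimates* $\bar c$, $\bar a$,
$\bar f$, $\bar\rho$ (partial sums nondecreasing) and *overestimates*
$\bar r$, $\bar d$ (all terms after order 0 negative). On nonsingular
arguments, hard truncation-error bounds exist for $\bar c$, $\bar r$,
$\bar f$, $\bar d$; they are tail bounds of the form (for $\bar c$)

$$0 \le \bar c - \bar c_M \le \frac{(1)_{M+1}}{(p/2)_{M+1}}
  \Big(\alpha^{-(p-2)/2}|\mathbf G|^{1/2}
  - \alpha \sum_{k \le M} d_k\Big),$$

i.e. the known full sum of the unweighted coefficient series minus its
partial sum, damped by the worst remaining weight. The signed bound is
stored per order in the returned `series_evaluation`, and evaluation stops
at the first order where $|\text{bound}| \le$ `tol`.

No such bound is available for $\bar a$ or $\bar\rho$ (nor when
`alpha_factor > 1`, which voids the sign structure, nor on singular
arguments). These runs instead stop when the relative layer increment stays
below `tol` for 20 consecutive orders, and are reported as `"stabilized"`
rather than `"bound"`. A stabilization stop is a heuristic: for the
geometric-type tails encountered here it leaves a remainder of the same
order as the increments, which is ample for 4-decimal work, but it is not a
guarantee — which is exactly why the distinction is kept visible in the
`criterion` field.

## Tunable parameters

* `tol` (default `1e-8`, dimensionless for the bounded measures since the
  bound is absolute): the target truncation error, mirroring the accuracy
  used for the reference tables.
* `alpha_factor` (default 1): $\alpha$ as a multiple of
  $1/\lambda_{\max}$ of the relevant argument. The default is the largest
  value that guarantees sign-definite terms, monotone partial sums and
  valid bounds. Larger values (up to 2, exclusive) often converge faster
  but lose the bounds; converged values are $\alpha$-independent, which the
  tests verify.
* `max_order` (default 50,000 for single series, 5,000 total order for
  double series): truncation caps. Exhausting a cap returns a structured
  non-convergence — `converged = FALSE`, diagnostics, and the best partial
  sum — never an exception and never a silent wrong value. This mirrors the
  practical failure mode of $\bar\rho$ on ill-conditioned spectra at large
  $p$, where the higher-order coefficients grow so fast that the double
  series is computationally out of reach.

## Numerical choices

* **Overflow control.** Coefficients $d_{i,j}$ grow without bound for the
  double series even though the weighted terms converge. Each recursion
  layer carries a shared base-2 scale exponent; mantissas are renormalized
  whenever they leave $[2^{-680}, 2^{680}]$ (roughly $10^{\pm 205}$).
  Series weights (Pochhammer/Gamma ratios) are kept in log space and are
  combined with $\log|d|$ *per cell*, so a huge weight never multiplies an
  underflowed mantissa (the `Inf * 0` trap).
* **Diagonal fast path.** When all argument matrices commute — always the
  case for the one-matrix measures, and for two-matrix comparisons of
  matrices sharing eigenvectors — the recursions run on eigenvalue vectors
  in $O(M^2 p)$ instead of matrix products. The general matrix path is kept
  for non-commuting pairs and is checked against the vector path and a
  brute-force generating-function oracle in the tests.
* **Hybrid index $d_{k,1}$.** $\bar f$ needs $d_{k,1}(\mathbf I -
  \alpha\mathbf G^2, \mathbf G)$. This is computed by the two-index
  recursion with the second index capped at 1. In the eigenbasis of the
  first argument the recursion's diagonal is closed (a diagonal matrix
  times any matrix leaves the diagonal evolution autonomous), so only
  $\mathrm{diag}(\mathbf Q^T \mathbf B \mathbf Q)$ of the second argument
  enters; this makes the path exact for arbitrary symmetric second
  arguments at vector cost.
* **Bound evaluation in log space.** The full coefficient sums such as
  $\alpha^{-p/2}|\mathbf G|^{1/2}$ overflow double precision for large $p$;
  tails are therefore formed as `log_full + log1p(-exp(log_partial -
  log_full))` from the scaled cumulative sums.
* **Degenerate inputs.** Singular $\mathbf G$: $\bar c = \bar a = 0$ and
  $\bar i = 1$ exactly (the range condition holds with probability 0 under
  a continuous gradient distribution); $\bar r$, $\bar f$, $\bar d$ proceed
  without bounds. $\mathbf G_1 = \mathbf G_2$ short-circuits $\bar d = 0$.
  Zero matrices are rejected where the measure is undefined.
* **Range membership** for the fixed measures uses the residual
  $|(\mathbf I - \mathbf P)\boldsymbol\beta| \le 10^{-8}|\boldsymbol\beta|$
  with $\mathbf P$ the projector onto eigenvectors above the rank
  tolerance, computed from the residual vector itself (a norm-difference
  formulation loses half the significant digits to cancellation at full
  rank).
* **Rank tolerance** is `100 * .Machine$double.eps * lambda_max * p`,
  standard numerical-rank practice, user-overridable via `as_cov_matrix()`.

## Test-matrix generators

`eigen_profile()` and `make_covariance()` construct the standard
benchmark spectra: `one_large` (one large eigenvalue, the rest equal,
parameterized by the relative eigenvalue variance $V_{\mathrm{rel}} \in
[0,1)$, mean exactly 1) and `quadratic` (eigenvalues proportional to
squared ranks, mean 1), as diagonal matrices or as correlation matrices
with the same spectrum via a seeded random orthogonal similarity followed
by Givens rotations that pin each diagonal entry to 1 (Bendel--Mickey /
Davies--Higham). Each rotation fixes one diagonal entry exactly; at most
$p-1$ rotations are needed since the trace is already $p$. The rotation
parameter solves $(a_{jj}-1)t^2 - 2a_{ij}t + (a_{ii}-1) = 0$; the smaller
root is taken for numerical stability. The construction is reproducible
per seed only — there is no canonical random state for the published
"different eigenvectors" comparisons, so those are reported but not used
as numeric references. One caveat worth knowing: for a `one_large`
spectrum the unit-diagonal constraint forces the leading eigenvector's
components to equal magnitudes $\pm$, so different seeds can yield
commuting (even identical) correlation matrices at small $p$; the
`quadratic` spectrum does not have this degeneracy.

## Monte Carlo comparator

`mc_average()` implements the traditional random-skewers estimate: normalize
independent $N(0,1)$ vectors (uniform on the sphere), apply the fixed
measure per draw, report mean, $SE = s/\sqrt{n}$, and the
$\pm 1.96\,SE$ normal interval. It is unbiased but converges as
$n^{-1/2}$; it serves as the stochastic cross-check for every series value
in the tests (4 SE criterion). Draws where a measure is undefined are
excluded and counted; under continuous sampling this is a
probability-zero event except on singular $\mathbf G$, where the exact-zero
convention for $c$, $a$, $i$ is applied before sampling.

## Delta-method comparator

`delta_c()`, `delta_r()`, `delta_d()`, `delta_a()` implement the
Hansen--Houle closed-form approximations from eigenvalue summaries
(arithmetic mean $E$, harmonic mean $H$, population relative variance
$I(\cdot)$ — the population variance is forced by matching the published
comparator values). The autonomy form is the second-order Taylor expansion
of $E[c/e]$ about the sphere moments,

$$\hat a = \frac{\hat c}{E} - \frac{2H(E-H)}{(p+2)E^2}
         + \frac{2\hat c\, I(\lambda)}{(p+2)E},
  \qquad \hat c = H\Big(1 + \frac{2I(1/\lambda)}{p+2}\Big),$$

using $\mathrm{Var}(\mathbf u^T\mathbf A\mathbf u) = 2(p\,\mathrm{tr}
\mathbf A^2 - (\mathrm{tr}\mathbf A)^2)/(p^2(p+2))$ on the sphere; it is
exposed only because it reproduces the published comparator column to
4 decimals (a verification gate kept in the test suite). These
approximations carry no error control and can deviate from the converged
series by more than 5%; they are comparators, not substitutes. No delta
approximation exists for $\bar f$ or $\bar\rho$ and none is invented.

## Problem sizes and what the tests show

The test suite and the acceptance checks run the full benchmark at
$p = 5$ (all measures, all three conformations, both one- and two-matrix
comparisons), plus selected fast cells at $p = 20$ ($\bar c$, $\bar r$,
$\bar a$, $\bar\rho$) and $p = 200$ ($\bar f$, quadratic spectrum) — the
cells that converge in milliseconds to about a second on one CPU. The very
slow published cells (e.g. $\bar r$ on the strongly integrated spectrum at
$p = 200$, which needs $M$ in the millions) are deliberately not re-run;
nothing in the algorithm changes with $p$, only the order needed. The
deliberately-capped $\bar\rho$ runs exercise the structured
non-convergence path instead.

Because every input matrix is generated from stated eigenvalue
conformations, passing tests demonstrate correctness of the series
machinery, not robustness to the vagaries of empirical $\hat{\mathbf G}$
estimates: sampling noise, near-singularity from small samples, and
estimation bias are real-data features the generators do not emulate, and
averages of measures computed from noisy $\hat{\mathbf G}$ inherit that
noise in ways outside this package's scope.

## Known limitations

* $\bar a$ and $\bar\rho$ have no truncation bound; their stabilization
  stop is heuristic (see above).
* $\bar\rho$ on ill-conditioned spectra at large $p$ is computationally
  infeasible (coefficient growth); the package reports structured
  non-convergence rather than attempting it.
* Only spherically distributed selection gradients are covered; general
  $N(\boldsymbol\eta, \boldsymbol\Sigma)$ gradients are supported in the
  moment engine only through nonzero $\boldsymbol\mu$ with identity
  covariance.
* No sampling theory for estimated $\mathbf G$ (no uncertainty
  propagation), no Wishart simulation, no bending/regularization of
  indefinite estimates.

## A worked check

```{r example}
G01 <- make_covariance(eigen_profile("one_large", 5, v_rel = 0.1))
avg_cond_evolvability(G01)
mc_average("c", G01, n_iter = 10000, seed = 1)
delta_c(G01)
```
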