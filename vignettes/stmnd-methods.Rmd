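---
title: "Estimating the integral, mean and covariance of simplex-truncated Gaussians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the integral, mean and covariance of simplex-truncated Gaussians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmnd)
```

## The model

A simplex-truncated multivariate normal distribution (ST-MND) is an
n-dimensional Gaussian $N(\mu, \Sigma)$ restricted to the non-negative
region under the unit simplex, $x_i \ge 0$ and $\sum_i x_i \le 1$. It is
the natural distribution for compositional data — fractions of land
cover, mixture components, vote shares — whose spread would otherwise be
Gaussian: unlike the Dirichlet or logistic-normal families it is
unimodal for every parameter choice and is untroubled by exact zeros and
ones. Its three characterising quantities are the normalising integral
$Z \in (0,1)$, the truncated mean $\mu_T$ and the truncated covariance
$\Sigma_T$; none has a closed form for $n \ge 2$, which is why the
package provides three independent estimation routes plus a quadrature
reference.

The constructor `gaussian_params()` requires a *strictly* positive
definite $\Sigma$ (smallest eigenvalue above $10^{-12} \times$ trace):
every route needs either a Cholesky factor of $\Sigma$ or the inverse of
a transformed covariance, so the semi-definite boundary case is rejected
with a clear error rather than failing obscurely downstream. Covariances
are symmetrised as $(\Sigma + \Sigma^\top)/2$ after a $10^{-10}$
relative symmetry check, which absorbs CSV round-trip noise. Boundary
membership is inclusive ($\ge$, $\le$) — a measure-zero convention with
no effect on any estimate.

## Route 1: rejection sampling

`sample_rejection()` draws from the untruncated Gaussian and keeps
in-domain draws until `M` are kept. The acceptance ratio estimates $Z$,
and kept draws are exact ST-MND samples, so the moments are plain sample
statistics (covariance with the $M-1$ denominator; the convention is
immaterial at the default $M = 10^4$ but stated for reproducibility).
Draws use the lower Cholesky factor of $\Sigma$, so a fixed seed fixes
the draw sequence. The expected cost is $M/Z$ draws; a trial budget
(default $\max(10^7, 10^3 M)$) converts the pathological regime
$Z \ll 1$ into an informative error that recommends the rejection-free
route instead.

## Route 2: constrained slice sampling, subset simulation, HDR

In centred coordinates $y = x - \mu$ the simplex domain is the linear
system $A y + c \ge 0$ with $n + 1$ rows. Elliptical slice sampling
proposes moves along the ellipse
$y^*(\theta) = y_t \cos\theta + \nu \sin\theta$ with
$\nu \sim N(0, \Sigma)$; each constraint row restricts $\theta$ through
$r_j \cos(\theta - \phi_j) \ge -c_j$, whose solution set is a single arc
(or the whole circle) in closed form. Intersecting the per-constraint
arcs gives the exact feasible set, so $\theta^*$ can be drawn uniformly
over it — every proposal is accepted. Numerical choices worth recording:

* a constraint with $r_j$ below $10^{-12}(1 + |c_j|)$ is
  $\theta$-independent and treated as always-feasible (or an error if
  violated), since the arc trigonometry divides by $r_j$;
* arc endpoints are shrunk inward by $10^{-12}$ radians before sampling
  so the next state is strictly feasible under floating point;
* $\theta^*$ is drawn by choosing an interval with probability
  proportional to its length, then uniformly within it — exactly uniform
  over the union;
* chains start from the deterministic interior point $x_0 = 1/(2n)$
  (coordinates positive, sum $1/2$, hence interior to every loosened
  domain); a short burn-in (default 100 steps) guards against that
  deterministic start. Thinning keeps states whose in-chain index is a
  multiple of the thinning ratio.

The integral is estimated through a nested sequence of *loosened*
domains $A y + c + \gamma_s \mathbf{1} \ge 0$ with
$\gamma_1 > \dots > \gamma_S = 0$, so that
$Z = \prod_s p(L_s \mid L_{s-1})$. Subset simulation chooses the
schedule adaptively: each sample's shift value
$g_m = -\min(A y_m + c)$ measures how far it is from the exact domain,
and the next $\gamma$ is set so that a proportion $\rho$ of the current
samples falls inside. The defaults follow the recommended settings:
$\rho = 0.5$ (maximum-entropy split), $M = 16$ samples per level with
thinning 10. The adaptive schedule makes this estimate biased, so the
Holmes–Diaconis–Ross pass re-runs the level loop with the schedule
*fixed* and a much larger sample count (default $10^4$, thinning 2),
giving an unbiased $\log Z$. Two tie-breaking details the algorithm
statement leaves open are fixed deterministically: the next $\gamma$ is
the midpoint of the $k$-th and $(k+1)$-th order statistics of
$\{g_m\}$ with $k = \lceil \rho M \rceil$, and each level's chain is
seeded from a current sample already inside the new level (the seed
state itself is not counted). The final level keeps Step-5's count at
the clamped $\gamma = 0$ level, without re-estimating it from fresh
samples. Subset simulation, HDR and moment sampling consume independent
RNG streams derived from the master seed.

Moment estimates from the chain carry batch-means standard errors
(25 contiguous batches), which are robust to residual autocorrelation
after thinning; the tests use them to form combined-error agreement
bands between routes.

## Route 3: inclusion–exclusion over rectangle probabilities

The simplex domain is $\mathbb{R}^n$ minus $n + 1$ half-spaces
($x_i < 0$ and $\sum_i x_i > 1$). Inclusion–exclusion over the
$2^{n+1} - 2$ non-trivial intersections of those half-spaces expresses
$Z$, $E(X_i)$ and $E(X_i X_j)$ as alternating sums of, respectively, the
Gaussian mass $\Phi_v$ of each intersection and its conditional first
and second moments. Each intersection is described by a full-rank 0/1
constraint system $c_v < T_v x < d_v$ built by a two-step constructor
(identity start, then per-index bound replacement; the free row for the
simplex-face constraint is the smallest index not in $v$ — any choice
gives the same integrals because the untouched rows carry infinite
bounds). The transformation $w = T_v(x - \mu)$ turns each problem into a
zero-mean Gaussian with covariance $\varepsilon = T_v \Sigma T_v^\top$
truncated to a box, whose mass is a rectangle probability and whose
moments follow from the moment-generating-function identities: the first
moment is a weighted difference of univariate marginal densities at the
box endpoints, and the second moment adds endpoint-weighted univariate
terms and a four-corner combination of bivariate marginal densities.

The marginal densities of a box-truncated Gaussian are themselves
normal densities times lower-dimensional rectangle probabilities. Two
typographically ambiguous points in their standard statement are
resolved here and verified against the quadrature oracle:

* the conditional covariance in the univariate marginal is computed as
  the Schur complement
  $\varepsilon_{-k,-k} - \varepsilon_{-k,k}\varepsilon_{k,-k}/\varepsilon_{kk}$
  (mathematically the inverse of the reduced inverse, numerically
  stabler);
* the standardised conditional bounds in the bivariate marginal divide
  by standard deviations $\sqrt{\varepsilon_{ii}}$ and by the
  conditional standard deviation
  $\sqrt{(1-\rho_{iq}^2)(1-\rho_{ik,q}^2)}$, with the first- and
  second-order partial correlations computed by the recursive formulas.

Endpoint conventions make the identities well defined on half-infinite
boxes (which the constructor produces routinely): marginal densities at
infinite endpoints are zero, as are endpoint-weighted terms — Gaussian
tails dominate polynomials. Dimension-zero rectangle probabilities (the
$n = 2$ bivariate marginal) are 1.

Rectangle probabilities delegate to `mvtnorm::pmvnorm` (Genz–Bretz
randomised quasi-Monte-Carlo) with requested absolute accuracy
`abs_tol = 1e-6` by default. The default is deliberately tighter than
the common backend default of $10^{-4}$: the alternating sums cancel
heavily, and the tests demonstrate that tightening $10^{-4} \to 10^{-6}$
measurably improves covariance accuracy at $n = 4$–$5$. Because the
backend consumes the R RNG, each call runs under a fixed internal seed
with the caller's RNG state preserved — the route is deterministic for
fixed inputs. Each subset's mass and moments are computed once and
shared between the three assemblies. If the alternating sum strays
outside $(0, 1)$ by more than $10 \cdot \texttt{abs\_tol} \cdot
\#\text{terms}$ an error is raised; smaller excursions (pure
floating-point cancellation, e.g. when $Z \to 1$) are clipped with a
warning. The dimension cap (default 6, overridable) reflects the
$2^{n+1}-2$ term growth with $O(n^2)$ rectangle probabilities per term.
A known failure mode inherited from the backend: for rare problems the
covariance assembly can be dominated by error in a single large
rectangle probability; the per-subset masses are exposed in the
diagnostics to allow diagnosis.

## The quadrature oracle

`oracle_summary()` ($n \le 3$) is the package's independent reference.
It integrates the density over the simplex region following the nested
limits directly: conditional on the outer coordinates, the innermost
coordinate is univariate normal, and its zeroth/first/second partial
moments over $[0, 1 - \sum \text{rest}]$ are closed pnorm/dnorm
expressions; the remaining one or two coordinates are integrated by
nested adaptive 1-D quadrature. This replaces a naive iterated
quadrature of the raw density: the closed-form innermost step removes
one dimension exactly, and each remaining integration range is clipped
to $\pm 40$ conditional standard deviations so that arbitrarily
concentrated distributions (variances down to $10^{-8}$) are resolved
instead of slipping between adaptive nodes. Default tolerances are
$10^{-8}$ at $n \le 2$ and $10^{-6}$ at $n = 3$; a self-consistency test
halves them and checks the outputs do not move. The oracle shares no
code with the estimation routes and plays no role in the public
estimation path.

## The benchmark generator

`sample_problem()` reproduces the study conditions under which the three
routes are compared: $\mu$ uniform in the unit simplex by accept/reject
from $U(0,1)^n$ (acceptance probability $1/n!$), variances
$\sigma_{ii} \sim U(0, 0.25)$ — a plausible spread for compositional
fractions confined to $[0,1]$ — correlations
$\rho_{ij} \sim U(-0.5, 0.5)$, and wholesale resampling of $\Sigma$
until all eigenvalues are non-negative. The correlation range is part of
the conditions: wider ranges make the eigenvalue acceptance step
impractically slow from $n \approx 9$. A kept matrix that fails the
strict positive-definiteness floor (probability zero under continuous
sampling) gets $10^{-10} \times$ trace added to its diagonal, with a
message. What the generator does *not* emulate: real compositional
datasets with structural zeros, heavy tails, or correlations beyond
$\pm 0.5$ — passing tests certify the estimators on this family of
well-conditioned problems, not robustness to arbitrary covariances.

## Problem sizes used in the tests

The validation suite scales the full study design down to sizes chosen
to keep the whole suite comfortably re-runnable on one CPU: 25 problems
per dimension for the oracle-equivalence check at $n = 2, 3$; 20
problems per dimension for rejection-vs-HDR agreement at $n = 2$–$5$
with $10^4$ samples each (the study's per-method sample count); 100
repeated HDR runs at $10^3$ samples for the unbiasedness check; $10^5$
slice-sampling steps and 500 random arc-set cases for the sampler
correctness check; and four problems per dimension at $n = 4$–$5$ for
the tolerance-sensitivity comparison, using a $3 \times 10^4$-sample
rejection reference. Cross-method agreement is asserted within four
combined Monte-Carlo standard errors for at least 95 % of compared
quantities, mirroring the tight diagonal scatter the three routes
produce over the full benchmark.

## Known limitations

* The semi-analytical route is exponential in $n$; beyond the cap its
  cost and the accumulation of backend error make the sampling routes
  preferable. At $n = 5$ and beyond, accuracy is limited by the
  rectangle-probability backend, not by the identities.
* Chain-based moment estimates inherit autocorrelation; thinning 2 is a
  default, not a guarantee, and the batch-means errors should be
  consulted at higher dimension (heavier thinning measurably improves
  agreement at $n = 7$).
* The oracle stops at $n = 3$; above that, validation is cross-method.
* Only first and second moments are computed; higher-order moments and
  general convex polytopes are natural extensions of the same machinery
  but out of scope.
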