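---
title: "Error structure and optimal design for enzyme inhibition kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error structure and optimal design for enzyme inhibition kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinoed)
```

## The models and the two error structures

Reaction velocity in an inhibition assay is described by Michaelis-Menten
type laws in the substrate concentration $x_S$ and inhibitor concentration
$x_I$.  The package implements four mean functions: the two-parameter
Michaelis-Menten law $\theta_V x_S/(\theta_M + x_S)$, the competitive
inhibition model
$$\eta_C = \frac{\theta_V x_S}{\theta_M(1 + x_I/\theta_K) + x_S},$$
the non-competitive model
$$\eta_N = \frac{\theta_V x_S}{(\theta_M + x_S)(1 + x_I/\theta_K)},$$
and a four-parameter encompassing model with mixing parameter
$\lambda \in [0, 1]$,
$$\eta_E = \frac{\theta_V x_S}
  {\theta_M(1 + x_I/\theta_K) + x_S\bigl(1 + (1-\lambda) x_I/\theta_K\bigr)},$$
which reduces to $\eta_C$ at $\lambda = 1$ and factorises into $\eta_N$ at
$\lambda = 0$.  $\theta_V$ is the maximum velocity (rate units), $\theta_M$
the Michaelis constant (substrate units) and $\theta_K$ the inhibition
constant (inhibitor units); all are positive.

Two statistical specifications of the same kinetics are contrasted
throughout:

* **standard scale** — $y = \eta + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$.  Simple, but a large enough $\sigma$
  produces negative simulated rates, which are physically impossible and
  break likelihood computations;
* **log scale** — $\ln y = \ln \eta + \varepsilon$, i.e. multiplicative
  log-normal noise.  Rates stay positive at any noise level, at the cost of
  an undefined response at $x_S = 0$.

The choice barely moves the parameter estimates but changes the optimal
designs dramatically, which is the phenomenon the package exists to
explore.

All design computations are local: they require nominal parameter values.
`nominal_estimates()` ships the estimates (with standard errors and
residual SDs) from an initial dextromethorphan-sertraline experiment with
$N = 120$ observations; every `theta` argument defaults to them but can be
replaced by the user's own fit.

## Estimation

`fit_model()` minimises the residual sum of squares on the analysis scale
with box-constrained Levenberg-Marquardt (`minpack.lm`), using five
deterministically jittered starts; determinism was preferred over random
multistart so that identical calls give identical fits without touching the
RNG.  Standard errors come from the linearisation covariance
$\hat\sigma^2 (F^\top F)^{-1}$ with the analytic Jacobian.  When $\hat\lambda$
ends on a boundary of $[0,1]$ its standard error is flagged unreliable
(the linearisation does not hold there).  A rank-deficient Jacobian at the
optimum — e.g. fitting an inhibition model to data with no inhibitor
variation — raises an identifiability error rather than returning
meaningless covariances.

Zeros in the substrate or rate columns cannot be log-transformed;
`replace_zeros()` floors them at $\varepsilon = 0.02$, the value that
minimised the back-transformed residual SD in the reference study.  The
floor distorts the replaced wells slightly (the model mean at
$x_S = 0.02$ is not the floored rate), so simulation-based bias checks in
the test suite exclude zero-substrate wells instead of flooring them.
`residual_summaries()` reports the three comparison summaries: SSE/MSE on
the standard scale, on the log scale, and back-transformed
($y$ vs $\exp(\widehat{\ln y})$), each with $N - m$ degrees of freedom.

## Designs for parameter estimation

An approximate design $\xi$ is a probability measure on the design
rectangle $[0, 30] \times [0, 60]$; its information is
$M(\xi, \theta) = \sum_i \omega_i f(x_i) f(x_i)^\top$ with $f$ the gradient
of the (possibly log) response.  On the log scale $f$ is the standard
gradient divided by the rate — the entire effect of the error structure on
design enters through this rescaling.  `optimize_d()` maximises
$\det M$; `optimize_ds()` maximises $\det M / \det M_{22}$ for a parameter
subset of interest (here always $\lambda$, whose precise estimation
discriminates the two inhibition mechanisms).

The optimiser combines three standard ingredients:

1. a **multiplicative weight algorithm** on a candidate grid
   ($w_i \propto w_i \psi_i$, with $\psi$ the sensitivity function), with
   periodic admission of any grid point violating the equivalence bound;
2. **support consolidation**: grid-adjacent support points are merged
   (single-linkage, radius one grid step) — only when continuous
   refinement follows, since on the log grid the optimum sits exactly on
   corners;
3. on the standard scale, **joint continuous refinement** of support
   coordinates and weights (L-BFGS-B on the log-criterion), because the
   standard-case optima are interior points that no reasonable grid hits
   exactly; weights are then re-optimised exactly on the final support
   (BFGS on softmax logits with the analytic gradient
   $w_i(\psi_i - \bar\psi)$).

Every returned design is certified by its **equivalence theorem**: the
sensitivity $\psi(x) = f^\top M^{-1} f$ (or its Ds analogue) must not
exceed $m$ (resp. $s$) anywhere on the grid, to relative tolerance
$10^{-4}$; failure is an error, never a silent return.  Weights below
$10^{-6}$ are pruned; during polishing, stalled weights below $10^{-4}$
are cut and the equivalence check re-admits any point that was genuinely
needed.

Grids: the log case uses the fixed $31 \times 61$ lattice
$\{0.02, 1, \dots, 30\} \times \{0, 1, \dots, 60\}$ (the substrate axis
starts at the zero floor because $\ln \eta$ is undefined at $x_S = 0$; a
denser grid changes nothing because the optima sit on the corners).  The
standard case uses step 0.1 on both axes before continuous refinement.
`round_design()` converts approximate to exact designs by largest-remainder
apportionment, which satisfies the quota bound $|n_i - N\omega_i| \le 1$
and deliberately lets a very low-weight support point receive zero runs at
small $N$ (the rounding used in the reference study behaves the same way);
the more common efficient-apportionment rule would instead force one run
onto it.

`d_efficiency()`/`ds_efficiency()` compare designs on the
$(\det\,\mathrm{ratio})^{1/m}$ scale in percent; a design with fewer
support points than parameters is reported as singular (efficiency 0)
rather than an error, mirroring how such entries are marked in efficiency
tables.

## Designs for model discrimination

**T-optimality** assumes one model true at fixed nominal values and
maximises the lack-of-fit sum of squares
$\Delta_0(\xi) = \inf_{\theta_1} \sum_i \omega_i
(\eta_0(x_i) - \eta_1(\theta_1, x_i))^2$ that the rival cannot remove.
`t_optimal()` uses the Fedorov-Wynn vertex-direction algorithm: refit the
rival, move mass $1/(k+1)$ to the point of largest squared separation,
prune below $10^{-5}$; stopping at 5000 iterations or a relative
sensitivity gap below $10^{-4}$, whichever comes first.  Because the plain
$1/(k+1)$ schedule closes the gap only like $1/k$, the final support
receives an exact weight optimisation: BFGS on softmax logits followed by
pairwise Frank-Wolfe steps (mass transfer from the worst to the best
support point with exact line search), which resolves the kinks of this
piecewise-smooth criterion well past the certification tolerance.  The
inner minimisation is box-constrained Levenberg-Marquardt, warm-started
along the algorithm's path and multistarted (10 deterministic jitters) for
final values; rival parameters are bounded below by positivity only, with
no artificial upper bounds.

`ct_optimal()` maximises the compound criterion
$(1-\nu)\ln\Delta_0 + \nu\ln\Delta_1$, removing the need to declare one
model true; $\nu = 0, 1$ reproduce the pure T-optima.  `t_efficiency()`
re-solves the inner problem from scratch (global multistart) for every
design it evaluates — the criterion's definition — rather than reusing an
earlier run's rival estimate, which can differ noticeably when the inner
problem has a deep minimum far from the nominals.

**$\delta$-optimality** (`delta_value()`, `delta_optimal()`) is the
symmetric alternative: both models are linearised at their nominal
estimates, each parameter vector is restricted to a flexible nominal box
$[\hat\theta_v \pm r\hat\sigma_v]$, and the criterion is the minimal
distance between the two linear expectation surfaces — a box-constrained
linear least-squares problem.  It is solved by projected quasi-Newton
(L-BFGS-B) with the analytic gradient, which for this convex quadratic
converges to the unique optimum; tests cross-check it against a coarse 6-D
grid plus independent coordinate descent.  For $r > 4$ some lower bounds
go negative; alternative *a* clips them at zero and alternative *b*
additionally shifts the clipped amount onto the upper bound.  Exact
designs are found by the standard exchange heuristic from a seeded random
start: each design slot in turn takes its best improving exchange against
the full candidate grid until a pass makes no change.  The full grid is
used as the candidate set (no K-truncation) because it is small here.

## The simulation study

`hit_rate_study()` measures real discriminatory power: for each exact
design, `B` datasets are simulated from each rival model in turn
(multiplicative log-normal noise on the log scale) and classified by the
smaller residual sum of squares on the analysis scale — the
likelihood-ratio rule for equal-variance Gaussian errors with equal
parameter counts; exact ties (e.g. designs without inhibitor variation,
where the models coincide) are broken uniformly at random.  The reported
average hit rate weighs both truths equally.  Classification fits start
from the generating values with ±5% uniform jitter, and skip the
covariance step so that near-saturated designs (few distinct points) are
still classifiable.  Each design-by-truth cell derives its own seed from
the master seed, so single cells can be reproduced in isolation.  Default
problem sizes follow the small-scale study ($N = 6\ldots9$, $B = 100$,
$\sigma = 0.5128$, the log-case encompassing residual SD); the tests use
these sizes and `B` a few hundred at most, which keeps every check at desk
scale.

## The synthetic plate

The original $N = 120$ dextromethorphan-sertraline dataset is not public.
`default_template()` emulates its layout: 15 substrate levels on
$[0, 30]$, denser at the low end (for substrate saturation), crossed with
8 inhibitor levels on $[0, 60]$, both including 0 so the zero-replacement
path is exercised.  The exact ladders were never published; the defaults
are one realistic choice, kept in a single overridable constant.
`generate_study()` draws one observation per combination under either
error structure.  Passing tests on this synthetic plate shows the pipeline
recovers parameters under the *assumed* error models; it says nothing
about features real plates may add (pipetting outliers, heteroscedasticity
beyond the two structures, well position effects).

## Numerical choices and known limitations

* Tie-breaks: equal-criterion grid points are taken in lexicographic
  $(x_S, x_I)$ order; classification ties are randomised.
* The IC50 of the encompassing model is defined at substrate held at
  $\theta_M$ and computed by root finding (tolerance $10^{-10}$) rather
  than a closed form, so it remains correct for any monotone rate model;
  at $\lambda \in \{0, 1\}$ it reproduces the closed-form pure-model
  values, and $x_I = IC_{50}(E_0[y]/E_i[y] - 1)$ converts it into
  percent-inhibition ladders (Hill coefficient fixed at 1, the only case
  used).
* Published T-efficiency tables for these models were evidently computed
  by averaging one fixed terminal sensitivity function over each design
  rather than re-solving the inner problem per design; `t_efficiency()`
  deliberately implements the definition, so its values can differ from
  such tables by several points even when the designs themselves agree to
  three decimals.
* Standard-case discrimination grids default to step 0.25 (finer than the
  support structure requires, coarse enough for quick runs) with
  continuous refinement; published three-decimal support points are
  matched to ±0.05.
* The delta exchange heuristic is a local search; different seeds can end
  in different local optima.  Tests verify it matches exhaustive
  enumeration on instances small enough to enumerate.
* Hamilton-Watts-style second-order (curvature) design criteria and
  sequential T-procedures are out of scope.
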