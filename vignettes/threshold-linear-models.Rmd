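---
title: "Joint MAP prediction for ordinal and continuous traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint MAP prediction for ordinal and continuous traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrlmm)
```

## The model and its assumptions

Ordinal traits — disease status, calving ease, condition scores — violate
the normality assumptions of linear mixed models, yet the quantitative
genetics machinery (covariance between relatives, BLUP, genomic
relationship matrices) lives on a Gaussian scale. The threshold model
reconciles the two: each ordinal trait has an unobserved Gaussian
*liability*, and the observed category is the interval of the liability
between consecutive *thresholds*. `thrlmm` fits the joint model for $c$
ordinal and $m$ continuous traits,

$$\begin{bmatrix} l \\ y_2 \end{bmatrix} =
  \begin{bmatrix} W_1 & 0 \\ 0 & W_2 \end{bmatrix}
  \begin{bmatrix} \theta_1 \\ \theta_2 \end{bmatrix} +
  \begin{bmatrix} e_1 \\ e_2 \end{bmatrix},
  \qquad e \sim N(0, R \otimes I), \quad u \sim N(0, G_0 \otimes K),$$

where $\theta = (b, u)$ stacks fixed effects and additive genetic
effects, and $K$ is any relationship matrix: the solvers only see the
precision $S = \mathrm{blockdiag}(0, G_0^{-1} \otimes K^{-1})$, so
pedigree, genomic and single-step evaluations use the same code path.

Assumptions to be aware of:

- **Known variances and thresholds.** $R$, $G_0$ and the thresholds are
  inputs, typically estimated beforehand on a subset by MCMC. The
  categorical residual variances fix the liability scale (probit
  identification); the simulator uses variance 1 and thresholds $\{0\}$ /
  $\{0, 1\}$, but all remain free inputs.
- **Conditional independence across animals given $\theta$** — one
  record per animal (no permanent-environment or maternal effects).
- **Full-rank fixed effects.** The design keeps all levels of the first
  factor and drops the first level of each later factor. EBV contrasts
  are unaffected and direct sparse factorization requires full rank.

## Estimation

The target is the joint posterior mode (MAP) of $\theta$ — the same logic
by which BLUP arises in the linear case.

**Newton-Raphson.** The log posterior sums, per record, the log
probability of the observed category cell under the conditional
liability distribution $N(\mu_i, \Sigma_i)$ with
$\mu_i = W_{1i}\theta_1 + R_{12}R_{22}^{-1}(y_{2i} - W_{2i}\theta_2)$ and
the Schur complement $\Sigma_i = R_{11} - R_{12}R_{22}^{-1}R_{21}$. Its
exact gradient and Hessian only involve the mean and covariance of the
*truncated* distribution over the cell:
$\Delta_i = \Sigma_i^{-1}(E_T[l_i] - \mu_i)$ and
$\Gamma_i = \Sigma_i^{-1} - \Sigma_i^{-1}\mathrm{Var}_T(l_i)\Sigma_i^{-1}$.
Each Newton round is then *exactly* a linear mixed-model solve with
pseudo-observations $\tilde y_i = (\Gamma_i^{-1}\Delta_i + \mu_i,\,
y_{2i})$ and a per-record working residual precision $\tilde R_i^{-1}$
written in closed block form — never by inverting $\tilde R_i$. The
blocks are computed once per round and reused by the inner solver.

**EM.** Treating the liabilities as missing data, the E-step replaces
each $l_i$ by its truncated-normal conditional expectation $\tilde l_i$
and the M-step solves the ordinary multi-trait mixed model equations
with $(\tilde l, y_2)$ as phenotypes and the *full* $R$. The coefficient
matrix is constant over rounds, so its sparse Cholesky factorization is
computed once. The E/M constant terms (conditional-variance sums) do not
depend on $\theta$ and are never materialized.

**SQUAREM.** EM's linear convergence is accelerated by squared-iterate
extrapolation after every pair of plain EM updates, with steplength
$\alpha = -\lVert r\rVert / \lVert v \rVert$ (clamped to $\le -1$),
$r = \theta_1 - \theta_0$, $v = \theta_2 - \theta_1 - r$. The phasing
("every other round") is implemented as accelerate-after-each-pair; the
accelerated point is kept only if it does not worsen the convergence
metric, otherwise the plain iterate is used.

**Stopping.** Both solvers stop when
$\lVert e \rVert_2 / \lVert W'\tilde R^{-1}\tilde y \rVert_2 < 10^{-12}$
with $e$ the residual of plugging the current solutions into the working
system. EM's metric is evaluated on the same Newton working system so the
two solvers share one stopping semantics and their round counts are
comparable. Newton-Raphson typically needs 4–7 rounds, EM 15–40 with
acceleration.

**Gibbs benchmark.** A single-site sampler — truncated-normal draws for
each liability given everything else, scalar normal draws for each
equation of the full-$R$ mixed model equations in fixed order — provides
posterior-mean EBVs. It is deliberately the classical slow-mixing scheme;
it serves as the statistical reference, not as a production solver.
Monte-Carlo standard errors are estimated from batch means.

## Truncated-moment numerics

$E_T[l]$ and $\mathrm{Var}_T(l)$ have no closed form for $c \ge 2$. They
are computed by the classical moment recursions, which reduce every
moment to normal rectangle probabilities of dimension $c$, $c-1$ (the
one-dimensional marginal functions $F_k$) and $c-2$ (bivariate marginal
densities). Numerical choices, each cross-checked in the test suite
against rejection sampling and against finite differences of the log
cell probability:

- dimension 1: closed forms throughout ($\eta_k$, $\phi/\Phi$ ratios);
- dimension 2 (the hot path for the standard two-ordinal-trait layout):
  fully vectorized closed forms; rectangle probabilities via a 48-node
  Gauss–Legendre Drezner–Wesolowsky quadrature, accurate to ~1e-14 for
  $|\rho| \le 0.95$, with a Genz-integration fallback beyond;
- dimension 3+: Genz quasi-Monte-Carlo recursive integration
  (`mvtnorm`) under a fixed internal seed, so solver runs are bit-level
  reproducible; the per-call absolute error target is `1e-8`, escalating
  the point budget when the reported error exceeds it. This sits 4–5
  orders of magnitude below every downstream tolerance while keeping the
  moment recursion (which needs many conditional integrals per cell)
  affordable.
- cell probabilities below `1e-12` are clamped before division
  (boundary cells under extreme solutions); occurrences are counted in
  the solver diagnostics. Numerically indefinite truncated covariances
  are symmetrized and eigenvalue-floored.

Newton overshoot is guarded by step halving (up to 5 times) whenever a
round would increase the convergence metric; in practice the full step
is accepted in essentially all rounds.

## The simulator and what passing tests show

`sim_scenario()` generates the validation design the solvers are judged
on: an overlapping-generation pedigree without selection (parents drawn
from the previous generation, or two back with probability 0.2 —
the overlap rate is a choice, stated here, not a measured quantity),
breeding values by the additive recursion (founders $N(0, G_0)$,
Mendelian sampling $N(0, G_0/2)$), phenotypes from sex and generation
effects plus correlated residuals, and threshold discretization. Default
parameters, chosen once as field-realistic: heritabilities 0.23/0.29
(ordinal, residual variance 1) and 0.33/0.33 (continuous), genetic
correlations 0.3 and residual correlations 0.2 between all pairs,
thresholds $\{0\}$ (binary) and $\{0, 1\}$ (three categories). The
biased-variance sensitivity settings scale the two categorical additive
variances by (a) 0.8/1.1, (b) 1.2/0.9, (c) 0.8/0.8, preserving genetic
correlations.

The generator emulates the structure that matters for solver validation
— latent Gaussian liabilities, genuine pedigree covariance, overlapping
generations, correlated traits — but not everything real data brings:
no selection (so no bias from selective genotyping or culling), no
heterogeneous variances, no repeated or maternal records, and missing
records only when injected. Passing tests therefore show that the
algebra and the solvers are correct under the stated model, not that the
model fits any particular field dataset.

Problem sizes: the standard validation runs at 3,000 animals over 6
generations with 10,000 Gibbs sweeps (1,000 burn-in); the property
suites use 30–800 animals and up to $10^6$ rejection draws per
truncated-moment audit case. At that scale the full validation completes
in a few minutes on one CPU.

## Design choices on genuinely open points

- **Initialization** is $\theta = 0$; with step-halving and the floor,
  no starting-value sensitivity has been observed on the test suite.
- **Missing records** are supported by subsetting $R$ per missingness
  pattern (with cached per-pattern inverses); a complete-record layout
  is simply the one-pattern special case.
- **Unknown parents** are treated as founders; inbreeding in the
  $A$-inverse is off by default (the validation pedigrees are essentially
  non-inbred) and available via `inbreeding = TRUE`.
- **Equation ordering** is fixed (fixed-effect columns, then animals;
  traits contiguous within each unit) and relabeling invariance is
  tested.
- **Inner solvers**: direct sparse Cholesky by default at desk scale; a
  Jacobi-preconditioned conjugate-gradient path (optionally matrix-free)
  mirrors iteration-on-data schemes, with the inner tolerance tightening
  geometrically from `1e-6` to `1e-10` across Newton rounds so early
  rounds are cheap.
- **PEV**: prediction error variances come from diagonal entries of the
  inverse working coefficient matrix at convergence.

## Known limitations

Variance-component and threshold estimation are out of scope (inputs are
assumed known); censored traits, repeated records, maternal effects,
unknown-parent groups and metafounders are not modeled; truncation
regions are rectangles only, with dimension capped at 8; the Gibbs
benchmark offers no convergence diagnostics beyond seeds, batch-mean
standard errors and trace reproducibility.
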