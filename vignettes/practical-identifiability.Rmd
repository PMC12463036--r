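---
title: "Practical identifiability analysis with identifim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Practical identifiability analysis with identifim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(identifim)
```

## The model class and the fitting problem

`identifim` analyses models of the form `h(φ(t, θ))`: a state trajectory
`φ` (either given in closed form or as the solution of an ODE system
`φ̇ = f(φ, θ)` with initial state `φ₀(θ)`) composed with an observable map
`h` selecting or transforming the `L` measurable quantities. Data are `N`
time-stamped observation vectors, and the fitting criterion throughout is
the unweighted least-squares loss

$$\ell(\theta) = \sum_{i=1}^N \lVert h(\varphi(t_i, \theta)) - \hat h_i
\rVert_2^2 .$$

Unit noise weight is the default deliberately: the analysis is about the
*geometry* of the loss surface around an estimate, and a per-observable
weighting (supported through the noise-sigma machinery in the data
generator) rescales rows of the sensitivity matrix without changing any of
the rank statements below.

Two assumptions matter. First, the analysis is **local**: everything is
computed from first derivatives at a given `θ*`, so conclusions hold in a
neighbourhood of that estimate, and a poor fit (large residuals) weakens
the Gauss–Newton identification of the FIM with the loss Hessian. Second,
observables must be differentiable in the parameters; models with
non-smooth activations (the ReLU network in the zoo) are handled by the
differencing machinery but their sensitivities are only piecewise correct,
which is precisely why some ReLU neurons report an exactly zero coordinate
metric — their parameters sit in a flat region of the loss.

## Sensitivities

The central object is the `(N·L) × k` sensitivity matrix: `N` time blocks,
each `L × k`, with entry `(l, i)` equal to `∂h_l/∂θ_i` at that time. Two
routes are provided:

* **Forward sensitivity ODEs** (default for dynamic models): the augmented
  system `Ż = J_f Z + ∂f/∂θ`, `Z(0) = ∂φ₀/∂θ`, integrated alongside the
  states. The zoo's ODE models register analytic Jacobians; user models
  fall back to central differences on `f` with step `1e-7·max(1, |value|)`.
* **Central finite differences** on the observable trajectory, step
  `1e-6·max(1, |θᵢ|)` per parameter (configurable). For ODE models the
  perturbed trajectories are integrated at tolerances tightened to
  `min(rtol, 1e-11)` / `min(atol, 1e-13)`: differencing divides trajectory
  error by twice the step, so the integrator must be several orders more
  accurate than the step for the quotient to be meaningful. The suite
  verifies second-order convergence of this scheme against the forward
  route.

Sensitivities are **raw**, not rescaled by `|θᵢ|`. All thresholds below are
therefore scale-dependent, which mirrors how the identifiability metric is
defined; users with wildly different parameter magnitudes should rescale
their parameterization rather than the matrix.

Default integrator tolerances are `rtol = 1e-8`, `atol = 1e-10`
(`deSolve::ode`, `lsoda`) — tighter than typical for plain simulation
because every downstream quantity is a derived difference.

## The eigenstructure of the FIM

`F = SᵀS` is symmetrized against round-off and eigendecomposed with
eigenvalues clipped at zero. The rank threshold `eps_eig` is **absolute and
per-analysis**: the packaged configs use `1e-4` for the unit-scale
closed-form fixtures (polynomial, Hill) and `1e-6` for the ODE zoo, and
every report carries the full spectrum so the sensitivity of `r` to the
threshold is always inspectable. Eigenvector signs are fixed by making each
vector's largest-magnitude component positive (ties to the lowest index);
without such a convention heatmaps of `U` are irreproducible across LAPACK
builds.

Near-degenerate eigenvalue pairs (gap below `1e-8` of the spectral radius)
are flagged: within such a pair the individual eigenvectors are arbitrary
even though their span is stable.

## The coordinate metric

For parameter `i`, let `A` be the sensitivity matrix with column `i`
deleted (this has the same range as the column-permutation construction it
replaces, which is all the theory uses). The metric is
`‖(I − A A†) s_i‖_∞`, computed via an SVD pseudoinverse with relative
cutoff `tol_rank = 1e-10`. It is zero iff `s_i ∈ range(A)` — iff the
parameter is coordinate non-identifiable — and its magnitude grades how
much of `s_i` is not explained by the other columns. The flag threshold
defaults to `1e-8` of the largest column norm, tying "numerically zero" to
the scale of the problem.

Note one bound that does *not* hold: the ∞-norm of a projection residual is
bounded by the column's 2-norm, not by its largest entry; the tests assert
the valid bound.

The profile likelihood (`profile_likelihood()`) is kept as the classical
benchmark: 21 grid points over `θᵢ*(1 ± 0.5)` by default, each solved for
the remaining parameters with warm starts spreading outward from the
estimate, and classified flat when the profile range is below
`1e-6·(1 + min loss)`. The grid width and flatness tolerance are the
package's choices; profiles and the metric are compared
parameter-by-parameter in the test suite and agree on all fixtures.

## Regularization and uncertainty

The regularized refit adds `λ‖U_{k−r}ᵀ(θ − θ*)‖²` as √λ-scaled residual
rows, so the same trust-region least-squares machinery (with exact
Jacobian rows) solves it. `λ` defaults to 1 — the Gaussian-prior variance
`τ² = 1/(2λ)` is not fixed by theory, and reports always record the value
used. The refit FIM `λU_{k−r}U_{k−r}ᵀ + SᵀS` has spectrum
`{retained eigenvalues} ∪ {λ × (k−r)}`, verified as an identity in the
tests.

Prediction uncertainty is propagated **only from the non-identifiable
subspace**: covariance `τ²U_{k−r}U_{k−r}ᵀ`, first-order variance
`∇h_l Cov ∇h_lᵀ`, normal bands `mean ± z_{α/2}√Var`. The perturbation
scale `τ` defaults to `0.1·max(1, ‖θ‖)/√k` but is a user choice; band
*magnitudes* are therefore protocol-dependent, while band *structure* —
exact zeros at the data times for linear-in-parameter models, bulges where
the null directions act — is invariant and is what the tests assert. A
seeded Monte-Carlo band (`monte_carlo_band()`) is provided for visual
comparison; for linear models it converges to the analytic band, and the
evaluation grid always merges the data times into a 200-point uniform grid
so the zero-width property is directly visible.

## Optimal measurement-time selection

The greedy design loop scores a candidate time by
`d(t) = diag(U_{k−r}ᵀ S̃(t)ᵀ S̃(t) U_{k−r})` and picks the candidate with
(1) the largest count of entries above `tol_design`, breaking ties by
(2) the largest total score, then (3) the smallest time. The count
criterion realizes the "number of nonzero contributions" reading of the
objective, the sum tie-break its magnitude reading; the final time
tie-break plus internal sorting of the candidate grid makes the selection
invariant under permutations of the grid, which the suite checks.
`tol_design` defaults to `1e-10·(1 + current largest eigenvalue)`.
Candidate search is grid search (201 uniform points by default), not
continuous optimization: the score surface is cheap on a grid and
optimizing it continuously buys little when the FIM update re-ranks
candidates after every addition. Duplicate times are excluded from the
candidate pool. If no candidate scores above tolerance while the rank is
deficient, the run stops with a structural-non-identifiability diagnostic
(the rank test `structural_rank_test()` on a dense grid is the direct way
to confirm).

## The synthetic-data generator and what passing tests mean

`generate_synthetic()` adds i.i.d. homoscedastic Gaussian noise per
observable to exact model output, with a per-observable sigma vector
because trajectory scales differ (prey vs predator counts). Where a
protocol does not fix sigma, the default is 5% of each observable's
trajectory range. Defaults for the zoo are fixed once in the packaged
configs: polynomial `θ* = (1,1,1)` with data at `t = 1, 2, 3`; Hill
`(Vmax, Kd, n) = (1, 1, 4)` with concentrations `{0.1, 0.2, 3, 3.5, 4}`
(baseline and plateau, deliberately missing the transition region — the
sampling pattern that renders cooperativity practically non-identifiable);
Lotka–Volterra `(0.55, 0.028, 0.024, 0.84)` from `(30, 4)` over `[0, 20]`;
Michaelis–Menten `(1, 0.5, 0.3)` from `(10, 1, 0, 0)` over `[0, 60]`; SEIR
`(0.6, 0.2, 0.15)` from 1% infected over `[0, 100]`, 25 uniform samples
each.

This generator emulates the measurement model the analysis assumes:
additive, independent, homoscedastic Gaussian noise on exact dynamics. Real
data violate all four adjectives — proportional error, autocorrelated
residuals, model misspecification, missingness. Passing tests therefore
demonstrate that the machinery is correct *under its own assumptions*; they
do not certify that a real dataset's non-identifiability diagnosis is
exhaustive. The SEIR observable-richness comparison is the instructive
example: infected counts alone leave the incubation pathway poorly
determined, adding exposed counts is worth more per direction than adding
everything — conclusions about *which data to collect* that survive
noise, as the noisy-refit invariance test shows, but whose numerical ξ
values are protocol-specific.

## Numerical choices and degenerate inputs

* Eigenvalues are clipped at zero before any ratio; `ξ` returns 0 for a
  singular or zero FIM (absolute floor `1e-300` guards against underflow).
* `coordinate_metric()` requires `k ≥ 2` (with one parameter there is no
  complement to project onto).
* An empty non-identifiable block (`r = k`) short-circuits: regularized
  fitting reduces to plain least squares with `lambda` reported as 0, the
  null-space covariance is the zero matrix, bands collapse to the mean.
* Requesting only the initial time from an ODE model returns the initial
  state without integration (the integrator needs two distinct times).
* Profile grid points whose inner solve fails are marked non-converged and
  skipped; more than 50% failures aborts with an error.
* Monte-Carlo draws whose model evaluation fails are dropped with a
  warning; more than 10% aborts.

## Problem sizes

The shipped analyses are sized for interactive use: 25-point time grids
for the ODE fixtures, 81–201-point design grids, 220-matrix randomized
oracle suites, 10⁴-draw Monte-Carlo checks. The full test suite runs in a
few seconds; `scripts/acceptance.R` in about one.

## Known limitations

* No adjoint or automatic differentiation; very large `k` pays `k` forward
  solves (or differences) per analysis.
* The FIM-as-Hessian identification degrades for large-residual fits; a
  Hessian-based variant is the natural extension for non-quadratic losses.
* Identifiable-direction estimation error is deliberately *not* propagated
  into the uncertainty bands — they answer "what does fitting leave
  undetermined", not "what is the total prediction error".
* The greedy design optimizes rank completion, not classical alphabetic
  optimality criteria; it stops at "everything identifiable", not
  "everything maximally precise".
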