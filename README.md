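# identifim

Practical identifiability analysis for dynamic models via the Fisher
Information Matrix.

## The problem

Mechanistic models in systems biology — enzyme kinetics, predator–prey
systems, epidemic compartment models, dose–response curves — are routinely
calibrated by least squares against sparse, noisy time series. Even when a
model is *structurally* identifiable (its parameters are uniquely determined
by perfect continuous data), a particular finite dataset often cannot pin
down every parameter: different parameter combinations produce
indistinguishable trajectories, and fitted values along those directions are
arbitrary. Acting on such fits — predicting an epidemic peak, ranking drug
candidates by a fitted rate constant — is unsafe unless the
*practical* identifiability of each parameter has been checked.

`identifim` is a toolkit for exactly that check, and for what to do when it
fails. It is aimed at modelers who fit ODE or closed-form models
(`deSolve`-style) to tabular time-series data.

## The method

Let a model produce observables `h(φ(t, θ))` with parameters `θ ∈ R^k`, and
let data `ĥ_i` be observed at times `t_1 … t_N`. Around an estimate `θ*` the
package builds the **sensitivity matrix** `S`, the `(N·L) × k` stacking of
`∂h_l(φ(t_n, θ*)) / ∂θ_i` (forward sensitivity ODEs for dynamic models,
central differences otherwise), and the **Fisher Information Matrix**

    F(θ*) = Sᵀ S.

Everything else follows from the thresholded eigendecomposition
`F = U Σ Uᵀ`, `U = [U_r, U_{k−r}]`:

* **Practical identifiability.** All parameters are practically identifiable
  iff `F` is invertible; eigenvalues above a threshold `ε` mark identifiable
  parameter combinations `U_rᵀ θ`, the rest (`U_{k−r}ᵀ θ`) are
  non-identifiable.
* **Coordinate metric.** Per parameter, `‖(I − A A†) s_i‖_∞` — the residual
  of projecting the i-th sensitivity column onto the span `A` of the others
  — is zero exactly when parameter `i` is coordinate non-identifiable, and
  grades identifiability strength in between. It reproduces
  profile-likelihood classifications at a fraction of the cost (profiles are
  included as the benchmark).
* **Regularized refit.** Adding `λ ‖U_{k−r}ᵀ(θ − θ*)‖²` to the loss pins
  only the non-identifiable combinations; the refit FIM
  `λ U_{k−r} U_{k−r}ᵀ + Sᵀ S` is full rank by construction.
* **Null-space uncertainty.** Perturbing `θ` only inside the non-identifiable
  subspace (`θ̂ = θ̃ + U_{k−r} ε`, `ε ~ N(0, τ² I)`) and propagating to
  `Var(h_l(t)) = ∇h_l Cov ∇h_lᵀ` yields confidence bands that collapse at
  the data points — the uncertainty that fitting genuinely leaves behind.
* **Optimal design.** A greedy algorithm scores every candidate measurement
  time by `diag(U_{k−r}ᵀ S̃(t)ᵀ S̃(t) U_{k−r})` and adds the time activating
  the most null directions, until the FIM reaches full numerical rank — the
  minimal extra data that makes everything identifiable.
* **Contribution index.** `ξ = σ_min/σ_max` of the FIM summarizes in `[0, 1]`
  how evenly a dataset informs all parameter directions.

A model zoo ships the worked examples (polynomial, Hill dose–response,
single-hidden-layer neural net, Lotka–Volterra, Michaelis–Menten, SEIR) with
documented defaults and a seeded synthetic-data generator (model output plus
additive Gaussian noise).

## Worked example: a Hill curve sampled at baseline and plateau

```r
library(identifim)

hill <- zoo_model("hill")                    # Vmax = 1, Kd = 1, n = 4
data <- generate_synthetic(hill, times = hill$protocol$times,
                           sigma = 0.02, seed = 1)
S   <- sensitivity_matrix(hill, hill$theta, data$times)
ana <- eigendecompose_fim(fim(S), eps_eig = 1e-4, hill$param_names)
ana
#> <fim_analysis> k=3, r=2 identifiable directions (eps_eig=0.0001)
#>   eigenvalues: 2.958, 0.0006265, 1.52e-05
coordinate_metric(S)
#> <coordinate_report>
#>  parameter    metric identifiable
#>       Vmax 0.4937200         TRUE
#>         Kd 0.0141620         TRUE
#>          n 0.0038223         TRUE
```

The protocol samples the baseline (x = 0.1, 0.2) and the plateau
(x = 3–4) but misses the transition region, so one eigenvalue (1.52e-05)
falls below the threshold: the direction dominated by the cooperativity `n`
is practically non-identifiable from these five concentrations, while the
metric ranks the parameters Vmax > Kd > n. A refit that pins only that
direction stays honest about it:

```r
refit <- fit_regularized(hill, data, hill$theta, ana$Unull, lambda = 1)
refit
#> <fit_result> regularized (lambda=1) loss=0.00089186, converged=TRUE (7 iterations)
#>    Vmax      Kd       n
#> 1.03601 1.45207 3.90923
```

and the design module says which concentrations to measure next so that all
three parameters become identifiable:

```r
optimal_design(hill, hill$theta, initial_times = 0.25, eps_eig = 1e-4)
#> <design_result> full rank reached: 1 initial + 3 added times (eps_eig=0.0001)
#>   added: 0.7, 1.08, 4
```

Two of the three suggested concentrations land in the transition region —
precisely the stretch the original protocol skipped.

## Command line

Each analysis stage is also a subcommand over a YAML config (see
`packaged_config()` for the shipped examples):

```sh
Rscript inst/exec/identifim identify --config inst/extdata/configs/hill.yaml --out runs/hill
Rscript inst/exec/identifim design   --config inst/extdata/configs/hill.yaml --out runs/hill
```

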