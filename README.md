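# demobo

Bayesian optimization for expensive demographic-inference likelihoods.

Demographic inference fits a parametric population history to genetic data
by maximizing a log-likelihood. For site-frequency-spectrum likelihoods with
four or five populations a *single* evaluation can take minutes, so the
optimizer's evaluation count — not its arithmetic — dominates the cost.
demobo is a sequential model-based optimizer for this regime, aimed at
population geneticists and anyone minimizing an expensive black-box
function over a small bounded parameter box.

## Method

At each iteration a zero-mean Gaussian-process surrogate with a
Matern-family kernel

> k(t, t') = σ² ρ_ν(‖t − t'‖ / κ),  ν ∈ {1/2, 3/2, 5/2, ∞}
> (Exponential, Matern32, Matern52, RBF)

is refit from scratch to all evaluations so far: hyperparameters
(κ, σ², σ_ε²) maximize the log marginal likelihood via Cholesky
factorization and restarted L-BFGS-B with analytic log-space gradients.
A closed-form acquisition function — expected improvement (EI),
probability of improvement (PI), or expected improvement on the
log-transformed objective (LogEI) — is maximized over the normalized unit
cube to propose the next evaluation. The covariance prior can be fixed or
selected automatically by leave-one-out cross-validation (mean log
predictive density) on the initial design of 2d uniform points.

The recommended **ensemble** pipeline selects the prior between Matern52
and RBF by LOO-CV, then flips a fair coin each iteration between PI and
LogEI. A bounded BFGS `local_polish()` refines the final incumbent.

The package also ships a toy single-population SFS objective (independent
Poisson composite negative log-likelihood over a parametric expected
spectrum, with dadi/moments-style spectrum file I/O), standard benchmark
objectives, and a replication harness that aggregates best-so-far
convergence traces (median and quartiles) across seeded runs.

## Worked example

Simulate a 20-chromosome spectrum from the toy model at
(θ = 1000, β = 1, γ = 0.5), then recover the parameters with the ensemble
pipeline and a BFGS polish:

```r
library(demobo)

set.seed(1)
obs <- simulate_sfs(c(1000, 1, 0.5), 20)
obj <- make_toy_sfs_objective(obs)
sp  <- objective_space(obj)          # theta log-scaled on [10, 1e5]

obj(c(1000, 1, 0.5))                 # NLL at the generating truth
#> [1] 67.05549

res <- run_bo(obj, sp, bo_config("ensemble", budget = 120, seed = 42))
res
#> <bo_result> ensemble + Matern52, 120 evaluations, best value 71.5523
#> incumbent: theta = 986.251, beta = 1.0339, gamma = 0.145664

pol <- local_polish(obj, sp, res$incumbent$par)
sprintf("NLL %.4f at theta = %.1f, beta = %.3f, gamma = %.3f",
        pol$value, pol$par[1], pol$par[2], pol$par[3])
#> "NLL 66.6871 at theta = 1001.5, beta = 0.996, gamma = 0.474"
```

The 120-evaluation run lands in the right basin (θ within 1.4% of truth);
the polish then beats the truth's own negative log-likelihood (66.69 <
67.06, as the maximum-likelihood estimate must on sampled data) and
recovers θ to 0.15%. `res$history` holds the full evaluation record —
phase, acquisition used, parameters, value, best-so-far, wall time — and
`run_replicates()` + `aggregate_convergence()` produce the median/quartile
convergence summaries used to compare pipelines.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/demobo simulate-sfs --theta 1000 --beta 1 --gamma 0.5 \
    --n-chrom 20 --seed 1 --out spectrum.fs
Rscript inst/cli/demobo run --objective sfs:spectrum.fs --pipeline ensemble \
    --budget 120 --seed 42 --out out/
```

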