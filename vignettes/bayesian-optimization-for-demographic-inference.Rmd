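---
title: "Bayesian optimization for expensive demographic likelihoods: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian optimization for expensive demographic likelihoods: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demobo)
```

## The problem

Fitting a demographic model — population sizes, split times, migration rates
— to genetic data means maximizing a log-likelihood over a handful of bounded
parameters. For site-frequency-spectrum likelihoods the cost of a *single*
evaluation grows steeply with the number of populations: with four or five
populations one evaluation can take minutes, so an optimizer that needs tens
of thousands of evaluations (a genetic algorithm, a restarted local search)
becomes the bottleneck. demobo implements sequential model-based (Bayesian)
optimization for exactly this regime: a cheap probabilistic surrogate of the
expensive negative log-likelihood guides where to evaluate next, so that good
parameter values are found within a budget of a few hundred evaluations.

Throughout, the objective is a function $\phi : T \to \mathbb{R}$ to
*minimize* (a negative log-likelihood), where
$T \subset \mathbb{R}^d$ is a box of parameters. Internally every parameter
is mapped to $[0,1]$; parameters declared `log`-scaled in the
`search_space()` are mapped through their logarithm first, so scale-spanning
positive quantities are treated log-uniformly.

## The surrogate: zero-mean GP regression

The surrogate is a Gaussian process with zero prior mean and a stationary
Matern-family covariance
$k(t, t') = \sigma^2 \rho_\nu(\lVert t - t'\rVert / \kappa)$, in the four
closed-form smoothness classes $\nu \in \{1/2, 3/2, 5/2, \infty\}$
(`Exponential`, `Matern32`, `Matern52`, `RBF`). Observations are centered
and scaled (sample SD; scale 1 fallback for constant or single observations)
so the zero-mean prior is reasonable; predictions are mapped back to the
observation scale. A single isotropic length scale is shared across the
(normalized) dimensions: the family is parameterized by three positive
numbers $(\kappa, \sigma^2, \sigma_\varepsilon^2)$, and with inputs on the
unit cube one shared scale is meaningful. Anisotropic (per-dimension) length
scales are a deliberate non-goal.

Observation noise $\sigma_\varepsilon^2$ is *always* estimated, even though
the likelihood objectives are deterministic: it absorbs the structure the
smooth prior cannot represent and keeps the covariance matrix well
conditioned.

Hyperparameters are chosen by maximizing the log marginal likelihood
$$
\log p(y) = -\tfrac12 y^\top (K + \sigma_\varepsilon^2 I)^{-1} y
            -\tfrac12 \log\det(K + \sigma_\varepsilon^2 I)
            -\tfrac n2 \log 2\pi,
$$
computed through one Cholesky factorization per evaluation (the $O(n^3)$
step), with analytic gradients with respect to
$(\log\kappa, \log\sigma^2, \log\sigma_\varepsilon^2)$ — the log
parameterization enforces positivity. The optimizer is bounded L-BFGS-B
from multiple log-uniform random starts inside the box
$\log\kappa \in [\log 10^{-3}, \log 10^{3}]$,
$\log\sigma^2 \in [\log 10^{-4}, \log 10^{4}]$,
$\log\sigma_\varepsilon^2 \in [\log 10^{-8}, \log 10^{-1}]$ (normalized
inputs, standardized observations). `fit_hyperparameters()` defaults to 10
restarts; inside the optimization loop the refit — which happens from
scratch at *every* iteration — uses 3 restarts with an iteration cap of 40,
which in practice recovers the same optima at a fraction of the cost.
The noise floor of $10^{-8}$ is a numerical choice of this package, as is
the jitter policy: factorizations start at $10^{-8}\times$ the mean
diagonal and escalate tenfold up to $10^{-2}\times$, after which a
numerical error is raised; the applied jitter is recorded in the fitted
object.

## Acquisitions

Given the posterior mean $\mu(t)$ and standard deviation $s(t)$ and the
incumbent $y^\ast = \min_i y_i$, three closed-form criteria are available:

* **EI** — expected improvement
  $(y^\ast - \mu)\,\Phi(z) + s\,\varphi(z)$, $z = (y^\ast - \mu)/s$;
* **PI** — probability of improvement $\Phi(z)$;
* **LogEI** — expected improvement when the surrogate models
  $g = \log(y + s_0)$: with shifted incumbent $c$,
  $c\,\Phi\!\big(\tfrac{\ln c - \mu}{s}\big) -
   e^{\mu + s^2/2}\,\Phi\!\big(\tfrac{\ln c - \mu}{s} - s\big)$,
  the lognormal partial expectation. Negative log-likelihoods are usually
  positive so the shift $s_0$ is usually zero; otherwise values are shifted
  so their minimum becomes exactly 1 before taking logs, which keeps the
  transform defined and scale-stable. The closed form is validated in the
  test suite against Monte-Carlo estimates of the defining expectation
  rather than against any reference implementation.

Degenerate predictive spread ($s < 10^{-12}$) falls back to the exact
limits. Acquisition maximization draws 1,000 uniform candidates on the unit
cube, evaluates the acquisition in one batch, refines the 10 best by bounded
L-BFGS-B (central-difference gradients evaluated as one batched prediction),
and returns the best point found, with ties broken by candidate index. A
proposal within $10^{-9}$ (sup norm) of an already evaluated point is
replaced by the best non-duplicate candidate — duplicated inputs would make
the covariance matrix singular.

## Choosing the prior: leave-one-out cross-validation

For a candidate kernel family, hyperparameters are fitted once on the full
design and held fixed while each point is held out in turn; the held-out
predictive $N(\mu_i, \sigma_i^2)$ (noise included) is computed with the
standard rank-one identities from the inverse covariance — the test suite
verifies exact agreement with the naive refit loop. Each fold is scored by
the log predictive density
$-\frac{(y_i - \mu_i)^2}{2\sigma_i^2} - \frac12\log(2\pi\sigma_i^2)$,
which balances accuracy with calibration (for a fixed residual it peaks at
$\sigma_i^2 = (y_i-\mu_i)^2$); the squared-error variant
$-(y_i-\mu_i)^2 - \sigma_i^2$ is kept for diagnostics only, since it
rewards underestimated uncertainty. The score is the per-point mean, and
`select_prior()` returns the family with the highest score, with ties broken
in the fixed order Matern52, RBF, Matern32, Exponential (their typical
relative standing on likelihood surfaces). When the surrogate will model
log-transformed observations (a LogEI pipeline), the scores are computed on
the log-transformed data too. Per-fold hyperparameter refits would cost
$O(n^4)$ and are deliberately not done. On designs of fewer than 4 points a
message flags the score as low-information; it is still computed.

## The optimization loop and pipeline variants

A run evaluates an initial design of $2d$ points drawn uniformly on the
normalized cube (log-uniform in raw units for log parameters), selects the
prior, then repeats until the evaluation budget is spent: choose the
acquisition, refit the surrogate from scratch on all successful evaluations,
maximize the acquisition, evaluate the objective, record. "Budget" counts
*all* objective evaluations including the initial design. Budgets are best
kept under 1000, with 200–400 practical for genuinely expensive likelihoods.

The variants are: the 12 fixed pipelines (each acquisition with each kernel
family); `PI + auto` / `LogEI + auto` (prior selected by LOO-CV on the
initial design among all four families); and the **ensemble**: prior
selected between Matern52 and RBF only — the two families that dominate on
likelihood surfaces — and the acquisition chosen at every iteration by a
fair coin between PI and LogEI. The ensemble's prior is selected once, after
the initial design, and never revisited; its LOO-CV uses untransformed
observations (it serves both a PI and a LogEI surrogate, and the untransformed
scale is the common denominator — a choice this package makes explicitly).
After a run, `local_polish()` refines the incumbent with bounded L-BFGS-B
under a hard cap on objective calls; the polished value never exceeds the
starting value. Polish matters: BO locates the basin quickly, but the last
digits of the optimum come cheaply from a local method.

Failed objective evaluations (errors, non-finite values) are flagged and
excluded from the surrogate rather than assigned a penalty value, which
would corrupt the fit; a run aborts once more than half of its evaluations
have failed.

### Reproducibility

Every random element — initial design, hyperparameter restarts, acquisition
candidates, coin flips, replicate streams — draws its seed deterministically
from the master seed via `derive_seed()`, each consumer from its own
substream. Two runs with the same master seed are bit-identical; replicate
$r$ of a batch is unchanged if the other replicates are skipped.

## The synthetic objectives

The toy SFS objective is the package's domain anchor. A spectrum over
`n_chrom` chromosomes has expected entries
$\mu_i = \theta\, i^{-\beta} e^{-\gamma (i-1)/(n_\mathrm{chrom}-2)}$,
$i = 1,\dots,n_\mathrm{chrom}-1$, observed counts are independent Poisson
draws, and the objective is the Poisson composite negative log-likelihood
$\sum_i [\mu_i - \xi_i \log\mu_i + \log \xi_i!]$ (log-factorials via
`lgamma`). This is declared a *fixture*, not a demographic inference
method: it reproduces the features that matter to the optimizer — a
positive NLL surface, monotone-ish spectrum decay, a scale parameter
$\theta$ spanning orders of magnitude (hence log-scaled over $[10, 10^5]$
by default, with $\beta,\gamma \in [0,3]$ linear) — without claiming to
match any coalescent or diffusion expectation. What passing tests on it
show is that the optimizer finds and refines the basin of a realistic
likelihood surface; they say nothing about the adequacy of any demographic
model for real data, about multi-population spectra, or about likelihood
surfaces with ridges induced by parameter non-identifiability, all of which
are out of scope. Spectrum files use the plain-text single-population
unfolded dadi/moments dialect with masked monomorphic corners.

Standard benchmarks (`branin`, `hartmann6`, `rosenbrock`, `sphere`) with
known optima are included for optimizer validation, with an optional
artificial per-evaluation delay to emulate expensive evaluations (the delay
is excluded from every correctness check).

## Replication harness

`run_replicates()` runs seeded independent copies of a pipeline (convergence
studies conventionally use 64); `aggregate_convergence()` reduces their
non-increasing best-so-far traces to per-iteration median and quartiles
using linear interpolation between order statistics (R quantile type 7 —
the convention is recorded in the output's attributes). Wall-clock time is
logged per evaluation and cumulatively but never used as a stopping rule.
The `inst/cli/demobo` script exposes `run`, `replicate`, `aggregate` and
`simulate-sfs` subcommands over these functions.

## Numerical choices and verification sizes

The test suite verifies the pieces against independent oracles: dense
Gaussian conditioning and dense log-density computations (50 random
instances, $n \le 10$, $d \le 5$, agreement to $10^{-8}$), million-draw
Monte-Carlo estimates of the three acquisition expectations (50 random
contexts each, judged at 3 standard errors with the binomially expected
number of exceedances allowed and a 6-SE cap), naive leave-one-out refits
(every $n \le 25$, both metrics, with and without the log transform,
agreement to $10^{-6}$), and finite-difference checks of all kernel
gradients ($10^{-5}$ relative). End-to-end checks run every pipeline
variant to completion on a 2-d objective (budget 30), Branin with the
ensemble (budget 60, 20 seeds, median within 0.5 of the optimum), a 1-d
quadratic (budget 25, within $10^{-2}$ in at least 18 of 20 seeds), and
toy-SFS recovery ($\theta = 1000$, $\beta = 1$, $\gamma = 0.5$,
`n_chrom = 20`; ensemble budget 150 plus polish; median $\theta$ error
within 10%). These problem sizes were chosen so the full suite runs on a
laptop in minutes while still exercising realistic design sizes.

For the prior self-consistency study, GP data are simulated with
$\kappa = 0.2$, $\sigma^2 = 1$, noise $10^{-4}$ on $[0,1]^2$: $n = 40$
points for RBF-sampled data and $n = 80$ for Exponential-sampled data.
The asymmetry is deliberate — identifying the *roughness* of a $\nu = 1/2$
path against the neighboring $\nu = 3/2$ family requires sampling well
below the length scale, whereas smoothness shows at moderate density.

## Known limitations

* Isotropic length scale only; strongly anisotropic objectives are better
  served by per-dimension scales, which this package does not implement.
* No discrete or categorical parameters, no batch/parallel proposals, no
  entropy-search or UCB acquisitions, and no wall-clock-budgeted stopping.
* BO's own overhead grows with the iteration count (the refit is cubic in
  the number of evaluations); past several hundred evaluations the
  surrogate refits can rival a cheap objective.
* The LOO-CV prior score on a $2d$-point initial design is noisy for small
  $d$; the auto modes are most informative from $d \gtrsim 3$.
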