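# encure

Elastic-net penalized mixture cure models with time-varying covariates.

## The problem

In survival data with a cured fraction, some subjects will never experience
the event: the Kaplan–Meier curve plateaus at a positive level and treating
those subjects as ordinarily censored biases every standard survival model.
The mixture cure model (MCM) splits the population explicitly,

```
F̄_pop(t | x, z) = (1 − p(x)) + p(x) · F̄_u(t | z),
```

with a logistic **incidence** model `p(x) = expit(β'x)` for the probability
of being susceptible and a Cox proportional-hazards **latency** model
`λ(t|z) = λ0(t) exp(γ'z(t))` for the event times of the susceptible.
`encure` is for analysts who need this model when

* covariates vary over time in **both** components, supplied in standard
  counting-process `(start, stop, status]` format, and
* the relevant covariates must be *selected*, not assumed: both coefficient
  vectors can be penalized with the elastic net
  `λ[(1−α)‖·‖₁ + α‖·‖₂²]` (α = 0 LASSO, α = 1 ridge), tuned by BIC over a
  per-component grid.

Estimation is an EM algorithm: posterior susceptibility weights in the
E-step; a weighted Breslow baseline, a penalized weighted logistic update
and a penalized weighted Cox update (local quadratic approximation of the
penalty, safeguarded Newton steps) in the M-step.  The package also ships
the matching piecewise-exponential simulator (covariate paths
piecewise-constant on a 30-interval grid, cubic baseline `3t²`), a
benchmark harness for the FULL / ORACLE / LASSO / EN / COX comparator
study (MEE, MREE, correct/incorrect zero counts), and cure-fraction
diagnostics (Kaplan–Meier plateau, Maller–Zhou sufficient-follow-up test).
See `vignettes/encure-methods.Rmd` for the full methodology.

## A worked example

Simulate one dataset from the 40% censoring / 30% cure design (logistic
intercept 1.45, exponential censoring rate 0.02, 8 AR(0.5)-correlated
covariates per component, truths `β = (1.5, 0, −0.75, 0, −1.5, 0, 0.75, 0)`
and `γ = (−0.7, 0, 1, 0, −0.5, 0.75, 0, 0)`), then run the BIC-tuned
elastic-net fit:

```r
library(encure)
sc  <- builtin_scenario("cens40_cure30", N = 300)
sim <- simulate_dataset(sc, seed = 2024)
sim$data
#> <cp_data> 300 subjects, 3368 rows, 215 events
#>   incidence covariates: x1, x2, x3, x4, x5, x6, x7, x8
#>   latency covariates:   z1, z2, z3, z4, z5, z6, z7, z8

fit <- tune_bic(sim$data)$fit
fit
#> <encure_fit> n = 300  iterations = 71 (converged)
#>   loglik = -1147.067  df = 14  BIC = 2373.987
#>   incidence:  1.6655  1.3909  0.0000 -0.7371 -0.0259 -1.6519  0.0000  1.3184 -0.3886
#>   latency:   -0.6808  0.0037  0.8706 -0.0560 -0.5001  0.7346  0.0000 -0.0907
```

Reading the output: the latency fit recovers the generating pattern — the
four true signals (−0.7, 1, −0.5, 0.75) are estimated near their values and
one of the true zeros is set exactly to zero, none of the signals is lost.
The incidence slopes track their truths with the looser precision typical
of the latent cure status (two true zeros removed exactly).  `df = 14`
counts the nonzero slopes in both components plus the intercept, and the
BIC shown is the minimum over the sequential 10 × 5 per-component grid.

A quick check that the data carry enough follow-up for a cure fraction:

```r
times  <- tapply(sim$data$records$tstop,  sim$data$records$id, max)
events <- tapply(sim$data$records$status, sim$data$records$id, max)
maller_zhou(times, events)$p_value
#> 4.89e-165   # tiny p: follow-up extends far beyond the last event
```

There is also a thin command-line interface over the same functions
(`inst/cli/encure.R`) with `simulate`, `fit`, `tune`, `benchmark` and
`diagnose` subcommands.

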