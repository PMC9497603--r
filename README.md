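# nnaipw

Doubly robust estimation of the average treatment effect (ATE) from
observational data with neural-network nuisance models under targeted L1
regularization — for biostatisticians and epidemiologists who want
flexible, nonlinear treatment and outcome models without letting
instrumental variables destabilize the causal estimate.

## The problem and the method

With covariates `W`, binary treatment `A` and continuous outcome `Y`, the
ATE `β = E[Y¹ − Y⁰]` is estimated in two steps. Step one fits the
propensity score `g(W) = E[A|W]` and the outcome regressions
`qᵃ(W) = E[Y|A=a,W]` with multilayer perceptrons, either **jointly** (jNN:
one shared ReLU trunk, two output heads, so the representation is pulled
toward covariates predicting both treatment and outcome — the confounders)
or **separately** (dNN). Both families carry linear skip connections
(`Wα`, `Wγ`) and admit the treatment only as a linear term `βA` in the
outcome head. Training minimizes

    a·Σᵢ(Yᵢ − Ŷᵢ)² + b·CE(A, ĝ) + C_L1·Σ_{ω∈P}|ω| + C_L1TG·(Σ_{ω∈Γ_A}|ω| + Σ_{ω∈Ω₁}|ω|)

where `P` is the trunk-and-heads parameter set and the **targeted**
penalty `C_L1TG` shrinks only the treatment head `Γ_A` and first layer
`Ω₁`, damping what instruments can feed into the propensity score. Step
two plugs the predictions `(ĝ, q̂¹, q̂⁰)` into AIPW and its
Hajek-normalized variant nAIPW,

    β̂_nAIPW = Σ Aᵢ(Yᵢ−q̂¹ᵢ)wᵢ(1) / Σ Aⱼwⱼ(1) − Σ (1−Aᵢ)(Yᵢ−q̂⁰ᵢ)wᵢ(0) / Σ (1−Aⱼ)wⱼ(0) + mean(q̂¹−q̂⁰)

with `w(1) = 1/ĝ`, `w(0) = 1/(1−ĝ)`, plus IPW, normalized IPW and the
plug-in comparators, each with influence-function 95% intervals.

A simulation module generates the four-covariate-role study design
(confounders, instruments, outcome predictors, irrelevant noise; AR(1)
Gaussian covariates, pairwise nonlinear features, logistic treatment,
`Y = 3 + A + ... + ε`) with full ground truth, and a Monte Carlo harness
summarizes bias, Monte Carlo SD and RMSE over a scenario × hyperparameter
grid with bootstrap intervals, alongside distance-correlation
covariate-capture counts and the `geo = (R²·D·(1−D))^(1/3)` diagnostic.

## Worked example

```r
library(nnaipw)

scen <- scenario_config(n = 750, p = 32, seed = 1)   # weak-effects scenario
sim  <- simulate_scenario(scen)
sim
#> Simulated causal dataset: n = 750 , p = 32
#>   roles: confounder=8, iv=8, y_predictor=8, irrelevant=8
#>   treated fraction: 0.947  true effect (beta): 1
#>   propensity range: [ 0.7006 , 1 ]

fit <- fit_network(joint_network(32, c(32, 32, 32)), sim$w, sim$a, sim$y,
                   loss_config(cl1 = 0.1, cl1tg = 0.7),
                   optimizer_config(seed = 2))
fit
#> Joint neural network: p = 32 , hidden widths = 32-32-32
#>   trunk parameters under L1: 3234
#>   fitted (inputs standardized)
#>   objective: 277.63 -> 2.708 over 200 epochs

asymptotic_ci("naipw", sim$y, sim$a, fit$predictions)
#> ATE (naipw): 0.8508  SE 0.1757  95% CI [0.5065, 1.1951]  n = 750

f <- forward_joint(fit$net, sim$w, sim$a)
prediction_metrics(f$yhat, sim$y, fit$predictions$ghat, sim$a)
#> R2 = 0.0627  AUC = 0.8639  Somers' D = 0.7278  geo = 0.2316

capture_counts(sim$w, sim$roles, f$yhat, fit$predictions$ghat)
#> Covariate roles captured among top 15 inputs:
#>           confounder iv y_predictor irrelevant
#> outcome            4  3           5          3
#> treatment          4  8           2          1
```

The single-replication nAIPW interval covers the true effect `β = 1`; the
capture table shows the treatment model still attending to instruments —
the quantity the targeted penalty is meant to suppress — and `geo` scores
the fit pair. Averaged over 50 replications of this scenario the nAIPW
estimate centers on the truth (see below). The Monte Carlo harness
automates that loop:

```r
recs <- run_grid(list(weak = scen),
                 list(best = hyper_setting("jNN", c(32, 32, 32), 0.1, 0.7)),
                 replications = 50, master_seed = 1)
summarize_records(recs, true_beta = 1)
```

A command-line front end (`scripts/atesim.R`) exposes
`simulate` / `fit` / `estimate` / `experiment` / `summarize` subcommands
over the same functions.

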