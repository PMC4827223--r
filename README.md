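# covadj — covariate adjustment methods for randomised trials

Trial analysts adjust for prognostic baseline covariates to gain power,
but a *continuous* covariate can be put into the outcome model in many
ways: split at the median, cut into quartiles, entered linearly, or
modelled flexibly with fractional polynomials or restricted cubic
splines.  `covadj` implements seven such representations behind one
interface, for continuous outcomes (least squares, treatment effect =
adjusted difference in means) and binary outcomes (logistic regression,
treatment effect = conditional log odds ratio), and wraps them in a
Monte-Carlo engine that measures what each choice costs in bias, type I
error and power.  It is aimed at trial statisticians and methodologists
who want those trade-offs quantified under controlled conditions, and a
ready-made way to run all eight analyses (the seven adjusted plus an
unadjusted one) on their own trial data.

## The model

Synthetic trials follow

    Y_i = alpha + beta_T * T_i + beta_cov * f(X_i) + eps_i

with simple 1:1 randomisation `T_i ~ Bernoulli(0.5)`, covariate
`X ~ N(0,1)`, and association shape `f(X) = X`, `exp(X)` or `X^2`.
Continuous outcomes use `eps ~ N(0,1)` and n = 200; binary outcomes use a
standard-logistic latent error with `Y = 1{latent > 0}` (so coefficients
are conditional log odds ratios), a 50% control-arm event rate and
n = 600.  Effect sizes are calibrated, not arbitrary: `beta_cov` solves
`beta_cov * (p90 - p10) = sigma_e` with theoretical quantiles of `f(X)`,
and `beta_T` targets 80% power — in closed form for continuous outcomes,
by simulation-based bisection against the correctly specified adjusted
logistic analysis for binary ones.

The adjustment methods: median **dichotomisation**; quartile
**categorisation**; **linear**; **FP1**/**FP2** fractional polynomials
with powers from {-2, -1, -0.5, 0, 0.5, 1, 2, 3} selected by minimum
deviance (the treatment term always included, the covariate never
dropped); and restricted cubic splines with **3** or **5** knots at the
conventional percentiles, with the truncated-cubic basis that is linear
beyond the boundary knots.

## A worked example

Simulate the exponential-association scenario at a reduced 500
replications and compare the methods:

```r
library(covadj)
spec <- scenario_spec("continuous", "monotonic", reps = 500, seed = 7)
run_scenario(spec)
#> Scenario: continuous outcome, monotonic shape, n=200, reps=500, beta_trt=0.3962
#>        method mean_estimate     bias pct_attenuation rejection_rate mc_se_rejection power_vs_fp2 n_failed
#>  dichotomised        0.4014 0.005151         -1.3002          0.710         0.02029          7.0        0
#>   categorised        0.3999 0.003709         -0.9363          0.714         0.02021          6.6        0
#>        linear        0.4011 0.004933         -1.2450          0.754         0.01926          2.6        0
#>           fp1        0.4002 0.004044         -1.0207          0.780         0.01853          0.0        0
#>           fp2        0.3995 0.003337         -0.8421          0.780         0.01853          0.0        0
#>          rcs3        0.3994 0.003188         -0.8046          0.758         0.01915          2.2        0
#>          rcs5        0.3997 0.003511         -0.8861          0.776         0.01865          0.4        0
```

Every method is essentially unbiased (bias within Monte-Carlo error of
zero), but the grouping methods pay ~7 percentage points of power against
FP2 and the linear analysis ~3 — the covariate-outcome association here
is smooth but not linear.  `power_vs_fp2` is the percentage-point power
deficit relative to the FP2 analysis.

Analysing a trial dataset (here the package's bundled synthetic fixture)
with every covariate handling at once:

```r
fx <- system.file("extdata", "synthetic_trial.csv", package = "covadj")
cmd_analyze(fx, outcome = "y", arm = "arm", covariate = "x")
#> Treatment effect (log odds ratio), 95% CI
#>
#>        method estimate     se  lower upper  p_value converged odds_ratio or_lower or_upper
#>    unadjusted   0.9600 0.3027 0.3668 1.553 0.001515      TRUE      2.612    1.443    4.726
#>  dichotomised   0.9447 0.3039 0.3491 1.540 0.001878      TRUE      2.572    1.418    4.666
#>   categorised   1.0247 0.3123 0.4125 1.637 0.001035      TRUE      2.786    1.511    5.139
#>        linear   0.9351 0.3053 0.3368 1.533 0.002190      TRUE      2.547    1.400    4.634
#>           fp1   0.9639 0.3062 0.3638 1.564 0.001643      TRUE      2.622    1.439    4.778
#>           fp2   1.0082 0.3092 0.4023 1.614 0.001109      TRUE      2.741    1.495    5.024
#>          rcs3   0.9673 0.3078 0.3641 1.571 0.001674      TRUE      2.631    1.439    4.809
#>          rcs5   1.0204 0.3128 0.4073 1.633 0.001107      TRUE      2.774    1.503    5.122
```

Single trials can also be fitted through the formula interface,
`covadj(outcome ~ arm + covariate, data, method = "rcs3")`, which returns
an object with `print`, `summary`, `coef`, `confint`, `predict`,
`residuals` and `plot` methods (`plot` draws each method's estimated
covariate-outcome association).  A thin command-line wrapper over the
same functions lives in `inst/cli/covadj.R` with `simulate`, `calibrate`
and `analyze` subcommands; `simulate` consumes a YAML scenario grid such
as `inst/extdata/study_grid.yaml` and writes per-scenario CSV tables plus
a reproducibility manifest.  Time-to-event outcomes are out of scope.

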