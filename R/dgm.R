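## Data-generating model for the simulation study.
##
## Outcomes follow  Y = alpha + beta_trt * arm + beta_cov * f(X) + eps  with
## X ~ N(0, 1) and f one of identity, exp, square.  Continuous outcomes use
## eps ~ N(0, sigma_e); binary outcomes use a latent standard-logistic error
## (SD pi/sqrt(3)) and record 1{Y > 0}, so coefficients are conditional log
## odds ratios and the covariate effect is calibrated on the latent scale.

#' Draw a standard-normal baseline covariate
#'
#' @param n number of patients (positive integer).
#' @return Numeric vector of `n` i.i.d. N(0, 1) draws from the current RNG
#'   stream.
#' @export
#' @examples
#' set.seed(1)
#' generate_covariate(5)
generate_covariate <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
    stop("'n' must be a positive integer", call. = FALSE)
  rnorm(n)
}

#' Apply the covariate-outcome association shape
#'
#' Maps the covariate onto the scale on which it acts in the outcome model:
#' `"linear"` is the identity f(x) = x, `"monotonic"` the non-linear
#' monotone f(x) = exp(x), and `"nonmonotonic"` the U-shaped f(x) = x^2.
#'
#' @param x numeric vector.
#' @param shape one of `"linear"`, `"monotonic"`, `"nonmonotonic"`.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' transform_covariate(c(-2, 0, 1), "nonmonotonic")
transform_covariate <- function(x, shape) {
  shape <- match_shape(shape)
  switch(shape,
         linear       = x,
         monotonic    = exp(x),
         nonmonotonic = x^2)
}

match_shape <- function(shape) {
  if (!is.character(shape) || length(shape) != 1L || !shape %in% COVADJ_SHAPES)
    stop("'shape' must be one of ", paste(COVADJ_SHAPES, collapse = ", "),
         call. = FALSE)
  shape
}

## latent-logistic error SD; fixed by the logistic(0, pi^2/3) latent model
sigma_logistic <- function() pi / sqrt(3)

#' Calibrate the covariate effect from the quantile-spread rule
#'
#' Solves `beta_cov * (p90 - p10) = sigma_e`, where `p10`/`p90` are the
#' theoretical 10th and 90th percentiles of f(X) for X ~ N(0, 1): normal
#' quantiles for the linear shape, lognormal(0, 1) for the monotone
#' exponential, and chi-squared(1) for the quadratic.  An increase from the
#' 10th to the 90th percentile of f(X) then moves the outcome by one
#' residual SD.
#'
#' @param shape association shape, see [transform_covariate()].
#' @param sigma_e residual scale: 1 for continuous outcomes, `pi/sqrt(3)`
#'   for the latent-logistic binary model.
#' @return The calibrated covariate coefficient (a single number, linear in
#'   `sigma_e`).
#' @export
#' @examples
#' calibrate_beta_cov("nonmonotonic", 1)            # ~0.372
#' calibrate_beta_cov("nonmonotonic", pi / sqrt(3)) # ~0.674
calibrate_beta_cov <- function(shape, sigma_e = 1) {
  shape <- match_shape(shape)
  if (!is.numeric(sigma_e) || length(sigma_e) != 1L || !is.finite(sigma_e) ||
      sigma_e <= 0)
    stop("'sigma_e' must be a positive number", call. = FALSE)
  spread <- switch(shape,
    linear       = qnorm(0.9)          - qnorm(0.1),
    monotonic    = qlnorm(0.9)         - qlnorm(0.1),
    nonmonotonic = qchisq(0.9, df = 1) - qchisq(0.1, df = 1))
  sigma_e / spread
}

#' Calibrate the treatment effect for a continuous outcome
#'
#' Two-sample difference-in-means formula on the residual scale: the mean
#' difference detectable with the requested power in a 1:1 trial of `n`
#' patients, `(z[1 - alpha/2] + z[power]) * sigma_e * sqrt(4/n)`.
#'
#' @param n total sample size.
#' @param sigma_e residual SD.
#' @param power target power, in (0, 1).
#' @param alpha_level two-sided test size, in (0, 1).
#' @return The treatment-effect (difference in means) giving the target
#'   power under a correctly specified analysis.
#' @export
#' @examples
#' calibrate_beta_trt_continuous(200)  # ~0.396
calibrate_beta_trt_continuous <- function(n, sigma_e = 1, power = 0.8,
                                          alpha_level = 0.05) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("'n' must be a sample size >= 2", call. = FALSE)
  if (!is.numeric(power) || length(power) != 1L || power <= 0 || power >= 1)
    stop("'power' must be in (0, 1)", call. = FALSE)
  if (!is.numeric(alpha_level) || length(alpha_level) != 1L ||
      alpha_level <= 0 || alpha_level >= 1)
    stop("'alpha_level' must be in (0, 1)", call. = FALSE)
  if (sigma_e <= 0) stop("'sigma_e' must be positive", call. = FALSE)
  (qnorm(1 - alpha_level / 2) + qnorm(power)) * sigma_e * sqrt(4 / n)
}

#' Calibrate the binary-outcome intercept for a 50% control event rate
#'
#' Finds the latent-model intercept `alpha` such that the marginal control-arm
#' event rate `E_X[expit(alpha + beta_cov f(X))]` equals `rate` for
#' X ~ N(0, 1).  The expectation is evaluated by adaptive Gauss-Kronrod
#' quadrature ([stats::integrate()], relative tolerance 1e-12) and the root
#' located with [stats::uniroot()]; the achieved event rate is within 1e-6
#' of the target.
#'
#' @param shape association shape.
#' @param beta_cov covariate effect on the latent log-odds scale.
#' @param rate target marginal control-arm event rate (default 0.5).
#' @return The intercept `alpha` (a single number).
#' @export
#' @examples
#' calibrate_binary_intercept("linear", 0.7)         # 0 by symmetry
#' calibrate_binary_intercept("nonmonotonic", 0.674) # < 0
calibrate_binary_intercept <- function(shape, beta_cov, rate = 0.5) {
  shape <- match_shape(shape)
  if (!is.numeric(beta_cov) || length(beta_cov) != 1L || !is.finite(beta_cov))
    stop("'beta_cov' must be a finite number", call. = FALSE)
  if (rate <= 0 || rate >= 1) stop("'rate' must be in (0, 1)", call. = FALSE)
  event_rate <- function(alpha) {
    integrate(function(x) plogis(alpha + beta_cov * transform_covariate(x, shape)) * dnorm(x),
              lower = -Inf, upper = Inf, rel.tol = 1e-12)$value
  }
  lo <- -1; hi <- 1
  while (event_rate(lo) > rate && lo > -60) lo <- lo * 2
  while (event_rate(hi) < rate && hi <  60) hi <- hi * 2
  f_lo <- event_rate(lo) - rate
  f_hi <- event_rate(hi) - rate
  if (sign(f_lo) == sign(f_hi))
    stop(sprintf(paste0("could not bracket the intercept root: event rate is ",
                        "%.6f at alpha=%.1f and %.6f at alpha=%.1f"),
                 f_lo + rate, lo, f_hi + rate, hi), call. = FALSE)
  uniroot(function(a) event_rate(a) - rate, lower = lo, upper = hi,
          tol = 1e-10)$root
}

#' Calibrate the binary-outcome treatment effect by simulation
#'
#' Finds the conditional log odds ratio at which the correctly specified
#' adjusted logistic analysis (treatment plus the true f(X)) attains the
#' target power, by monotone bisection on empirical power.  Each candidate
#' is evaluated on `reps` simulated trials; common random numbers (the same
#' derived seed for every candidate) keep the power curve monotone in the
#' candidate effect, and bisection stops once the empirical power is within
#' `tol` of the target.
#'
#' @param spec a binary-outcome [scenario_spec()]; its `beta_trt` is ignored.
#' @param power target power (default 0.8).
#' @param reps simulated trials per candidate (default 10000).
#' @param seed seed for the common-random-number stream; defaults to a
#'   stream derived from `spec$seed`.
#' @param tol tolerance on the achieved power, in probability units
#'   (default 0.01, i.e. one percentage point).
#' @return The calibrated conditional log odds ratio, with the achieved
#'   empirical power attached as attribute `"power"`.
#' @export
calibrate_beta_trt_binary <- function(spec, power = 0.8, reps = 10000,
                                      seed = NULL, tol = 0.01) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$outcome_family != "binary")
    stop("'spec' must describe a binary-outcome scenario", call. = FALSE)
  if (is.null(seed)) seed <- derive_seed(spec$seed, stream = 999983L)
  n <- spec$n
  zcrit <- qnorm(1 - spec$alpha_level / 2)

  power_at <- function(beta_trt) {
    set.seed(seed)
    rej <- 0L
    for (i in seq_len(reps)) {
      arm <- rbinom(n, 1L, 0.5)
      x   <- rnorm(n)
      fx  <- transform_covariate(x, spec$shape)
      lat <- spec$intercept + beta_trt * arm + spec$beta_cov * fx + rlogis(n)
      y   <- as.integer(lat > 0)
      if (all(arm == arm[1L]) || all(y == y[1L])) next  # degenerate; ~never at n=600
      fit <- irls_logistic(cbind(1, arm, fx), y)
      if (!fit$converged) next
      se <- fit$se[2L]
      if (is.finite(se) && abs(fit$coef[2L] / se) > zcrit) rej <- rej + 1L
    }
    rej / reps
  }

  lo <- 0; p_lo <- spec$alpha_level
  hi <- 0.5
  p_hi <- power_at(hi)
  while (p_hi < power && hi < 3) {
    lo <- hi; p_lo <- p_hi
    hi <- min(3, hi * 1.6)
    p_hi <- power_at(hi)
  }
  if (p_hi < power)
    stop("bisection bracket not found: power at log OR = 3 is ",
         format(p_hi), call. = FALSE)
  mid <- (lo + hi) / 2; p_mid <- NA_real_
  for (it in seq_len(40L)) {
    mid <- (lo + hi) / 2
    p_mid <- power_at(mid)
    if (abs(p_mid - power) <= tol) break
    if (p_mid < power) lo <- mid else hi <- mid
  }
  structure(mid, power = p_mid)
}

#' Specify one simulation scenario
#'
#' Bundles the data-generating model of one Monte-Carlo scenario: outcome
#' family, association shape, sample size, effect sizes, replication count
#' and base seed.  Unstated quantities are filled in by the package's
#' calibration rules: `beta_cov` from the quantile-spread rule
#' ([calibrate_beta_cov()]), the binary intercept from the 50% control event
#' rate ([calibrate_binary_intercept()]), and `beta_trt = "calibrated"`
#' resolves to the 80%-power effect (closed form for continuous outcomes;
#' simulation-based bisection, deferred until [calibrate_scenario()] or
#' [run_scenario()], for binary ones).
#'
#' @param outcome_family `"continuous"` or `"binary"`.
#' @param shape association shape, see [transform_covariate()].
#' @param n total sample size; defaults to 200 (continuous) or 600 (binary).
#' @param beta_trt treatment effect: a number, `0` for a null scenario, or
#'   `"calibrated"` for the 80%-power value.
#' @param beta_cov covariate effect on the f(X) scale; default calibrated.
#' @param reps Monte-Carlo replications (default 5000).
#' @param seed base RNG seed.
#' @param alpha_level two-sided test size (default 0.05).
#' @param target_power power used when `beta_trt = "calibrated"`.
#' @return An object of class `"scenario_spec"`.
#' @export
#' @examples
#' scenario_spec("continuous", "monotonic", reps = 1000, seed = 7)
scenario_spec <- function(outcome_family = c("continuous", "binary"),
                          shape = c("linear", "monotonic", "nonmonotonic"),
                          n = NULL, beta_trt = "calibrated", beta_cov = NULL,
                          reps = 5000, seed = 1L, alpha_level = 0.05,
                          target_power = 0.8) {
  outcome_family <- match.arg(outcome_family)
  shape <- match.arg(shape)
  if (is.null(n)) n <- if (outcome_family == "continuous") 200L else 600L
  if (!is.numeric(n) || length(n) != 1L || n < 20 || n != floor(n))
    stop("'n' must be an integer >= 20", call. = FALSE)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1)
    stop("'reps' must be >= 1", call. = FALSE)
  if (alpha_level <= 0 || alpha_level >= 1)
    stop("'alpha_level' must be in (0, 1)", call. = FALSE)
  sigma_e <- if (outcome_family == "continuous") 1 else sigma_logistic()
  if (is.null(beta_cov)) beta_cov <- calibrate_beta_cov(shape, sigma_e)
  intercept <- if (outcome_family == "continuous") 0 else
    calibrate_binary_intercept(shape, beta_cov)

  needs_calibration <- FALSE
  if (identical(beta_trt, "calibrated")) {
    if (outcome_family == "continuous") {
      beta_trt <- calibrate_beta_trt_continuous(n, sigma_e, target_power,
                                                alpha_level)
    } else {
      beta_trt <- NA_real_      # resolved later by simulation-based bisection
      needs_calibration <- TRUE
    }
  }
  if (!is.numeric(beta_trt) || length(beta_trt) != 1L)
    stop("'beta_trt' must be a single number or \"calibrated\"", call. = FALSE)

  structure(list(outcome_family = outcome_family, shape = shape,
                 n = as.integer(n), sigma_e = sigma_e,
                 beta_cov = beta_cov, beta_trt = beta_trt,
                 intercept = intercept, alpha_level = alpha_level,
                 reps = as.integer(reps), seed = as.integer(seed),
                 target_power = target_power,
                 needs_calibration = needs_calibration),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Simulation scenario:", x$outcome_family, "outcome, shape =", x$shape,
      "\n  n =", x$n, " reps =", x$reps, " seed =", x$seed, "\n")
  bt <- if (is.na(x$beta_trt)) "(calibrated at run time)" else
    format(x$beta_trt, digits = 4)
  cat("  beta_trt =", bt, " beta_cov =", format(x$beta_cov, digits = 4),
      " intercept =", format(x$intercept, digits = 4), "\n")
  invisible(x)
}

#' Resolve any deferred effect-size calibration in a scenario
#'
#' For binary scenarios created with `beta_trt = "calibrated"`, runs
#' [calibrate_beta_trt_binary()] and stores the result; other scenarios are
#' returned unchanged.
#'
#' @param spec a [scenario_spec()].
#' @param reps simulated trials per bisection candidate.
#' @return The spec with `beta_trt` resolved.
#' @export
calibrate_scenario <- function(spec, reps = 10000) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (isTRUE(spec$needs_calibration)) {
    spec$beta_trt <- as.numeric(
      calibrate_beta_trt_binary(spec, power = spec$target_power, reps = reps))
    spec$needs_calibration <- FALSE
  }
  spec
}

#' Simulate one randomised trial
#'
#' Draws one trial from the scenario's data-generating model using the
#' current RNG stream: treatment by simple randomisation (independent
#' Bernoulli(0.5) per patient), covariate X ~ N(0, 1), and outcome
#' `Y = intercept + beta_trt * arm + beta_cov * f(X) + eps` with normal
#' error for continuous outcomes, or the indicator `1{Y > 0}` of the
#' latent-logistic response for binary ones.  Degenerate draws (an empty
#' arm, or an all-0/all-1 binary outcome) are regenerated with fresh draws;
#' more than 100 attempts is an error.
#'
#' @param spec a [scenario_spec()] with `beta_trt` resolved.
#' @return A `data.frame` of class `"trial_data"` with columns `arm` (0/1),
#'   `covariate`, and `outcome`; the number of regeneration attempts is
#'   attached as attribute `"attempts"`.
#' @export
#' @examples
#' sp <- scenario_spec("continuous", "linear", reps = 1, seed = 1)
#' set.seed(1)
#' head(simulate_trial(sp))
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.na(spec$beta_trt))
    stop("scenario 'beta_trt' is unresolved; run calibrate_scenario() first",
         call. = FALSE)
  n <- spec$n
  for (attempt in seq_len(100L)) {
    arm <- rbinom(n, 1L, 0.5)
    x   <- rnorm(n)
    fx  <- transform_covariate(x, spec$shape)
    lin <- spec$intercept + spec$beta_trt * arm + spec$beta_cov * fx
    if (spec$outcome_family == "continuous") {
      y <- lin + rnorm(n, sd = spec$sigma_e)
      degenerate <- all(arm == arm[1L])
    } else {
      y <- as.integer(lin + rlogis(n) > 0)
      degenerate <- all(arm == arm[1L]) || all(y == y[1L])
    }
    if (!degenerate) {
      out <- data.frame(arm = arm, covariate = x, outcome = y)
      class(out) <- c("trial_data", "data.frame")
      attr(out, "attempts") <- attempt
      return(out)
    }
  }
  stop("failed to generate a non-degenerate trial in 100 attempts",
       call. = FALSE)
}

#' Write a simulated trial as delimited text
#'
#' @param trial a `trial_data` data frame from [simulate_trial()].
#' @param path output file path.
#' @return `path`, invisibly.  The file has header `id,arm,x,y`.
#' @export
export_trial <- function(trial, path) {
  stopifnot(is.data.frame(trial))
  df <- data.frame(id = seq_len(nrow(trial)), arm = trial$arm,
                   x = trial$covariate, y = trial$outcome)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
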