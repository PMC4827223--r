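# Shared Monte-Carlo runs, memoised so that several test blocks can reuse
# one expensive simulation.  Sizes: 5000 replicates for the null (type I
# error) scenarios, 2000 for the powered scenarios; binary effect sizes are
# calibrated once per shape with 10000 trials per bisection candidate.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .run_cache))
    assign(key, fn(), envir = .run_cache)
  get(key, envir = .run_cache)
}

TEST_SEED <- 20260926L

null_run <- function(family, shape) {
  cached(paste("null", family, shape, sep = "_"), function() {
    run_scenario(scenario_spec(family, shape, beta_trt = 0, reps = 5000,
                               seed = derive_seed(TEST_SEED, 1L,
                                                  match(shape, c("linear", "monotonic", "nonmonotonic")) +
                                                    10L * (family == "binary"))))
  })
}

power_run <- function(family, shape) {
  cached(paste("power", family, shape, sep = "_"), function() {
    sp <- scenario_spec(family, shape, reps = 2000,
                        seed = derive_seed(TEST_SEED, 2L,
                                           match(shape, c("linear", "monotonic", "nonmonotonic")) +
                                             10L * (family == "binary")))
    sp <- calibrate_scenario(sp, reps = 10000)
    run_scenario(sp)
  })
}

# Monte-Carlo SE of a difference in rejection rates between two methods,
# computed from the paired per-replicate rejection indicators.
power_diff_se <- function(res, method_a, method_b) {
  alpha <- res$spec$alpha_level
  rej <- (res$p_values < alpha) & res$converged
  d <- as.numeric(rej[, method_a]) - as.numeric(rej[, method_b])
  sd(d) / sqrt(length(d))
}

rejection <- function(res, method)
  res$summaries$rejection_rate[res$summaries$method == method]

attenuation <- function(res, method)
  res$summaries$pct_attenuation[res$summaries$method == method]

# small synthetic trial for interface tests
make_trial <- function(family = "continuous", shape = "linear", n = 200,
                       beta_trt = 0.4, seed = 1) {
  sp <- scenario_spec(family, shape, n = n, beta_trt = beta_trt, reps = 1,
                      seed = seed)
  set.seed(seed)
  simulate_trial(sp)
}
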