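test_that("covariate draws are standard normal and reject bad n", {
  set.seed(101)
  x <- generate_covariate(1e6)
  expect_length(x, 1e6)
  expect_lt(abs(mean(x)), 0.01)
  expect_lt(abs(sd(x) - 1), 0.01)
  q <- unname(quantile(x, c(0.1, 0.9), type = 7))
  expect_lt(abs(q[1] + 1.281552), 0.01)
  expect_lt(abs(q[2] - 1.281552), 0.01)
  expect_error(generate_covariate(0), "positive integer")
  expect_error(generate_covariate(-3), "positive integer")
})

test_that("association shapes map covariates as identity, exp, square", {
  expect_equal(transform_covariate(0, "monotonic"), 1)
  expect_equal(transform_covariate(-2, "nonmonotonic"), 4)
  expect_equal(transform_covariate(1.5, "linear"), 1.5)
  expect_equal(transform_covariate(c(-1, 0, 2), "monotonic"),
               exp(c(-1, 0, 2)))
  expect_error(transform_covariate(1, "cubic"), "shape")
})

test_that("quantile-spread calibration matches theoretical quantiles", {
  ## continuous scale (sigma_e = 1)
  expect_equal(round(calibrate_beta_cov("nonmonotonic", 1), 3), 0.372)
  expect_equal(calibrate_beta_cov("linear", 1), 1 / (2 * qnorm(0.9)))
  expect_equal(round(calibrate_beta_cov("linear", 1), 4), 0.3902)
  expect_equal(calibrate_beta_cov("monotonic", 1),
               1 / (qlnorm(0.9) - qlnorm(0.1)))
  expect_lt(abs(calibrate_beta_cov("monotonic", 1) - 0.300), 0.01)
  ## latent-logistic scale (sigma_e = pi/sqrt(3))
  s <- pi / sqrt(3)
  expect_equal(round(calibrate_beta_cov("nonmonotonic", s), 3), 0.674)
  ## linearity in sigma_e, for every shape
  for (shape in c("linear", "monotonic", "nonmonotonic")) {
    expect_equal(calibrate_beta_cov(shape, 2), 2 * calibrate_beta_cov(shape, 1))
    expect_equal(calibrate_beta_cov(shape, s) / calibrate_beta_cov(shape, 1), s)
  }
  expect_error(calibrate_beta_cov("linear", -1), "positive")
})

test_that("theoretical quantile spread matches the empirical spread of f(X)", {
  set.seed(77)
  x <- rnorm(1e7)
  for (shape in c("linear", "monotonic", "nonmonotonic")) {
    fx <- transform_covariate(x, shape)
    emp <- diff(unname(quantile(fx, c(0.1, 0.9), type = 7)))
    theo <- 1 / calibrate_beta_cov(shape, 1)
    expect_lt(abs(emp - theo), 0.005)
  }
})

test_that("continuous treatment effect follows the two-sample power formula", {
  expect_equal(round(calibrate_beta_trt_continuous(200, 1, 0.80, 0.05), 4),
               0.3962)
  expect_equal(calibrate_beta_trt_continuous(200, 1, 0.80, 0.05),
               (qnorm(0.975) + qnorm(0.8)) * sqrt(4 / 200))
  ## z_{power} term vanishes at 50% power
  expect_equal(calibrate_beta_trt_continuous(100, 2, 0.5, 0.05),
               qnorm(0.975) * 2 * sqrt(4 / 100))
  ## sqrt(4/n) scaling
  expect_equal(calibrate_beta_trt_continuous(800, 1, 0.80, 0.05),
               calibrate_beta_trt_continuous(200, 1, 0.80, 0.05) / 2)
  expect_error(calibrate_beta_trt_continuous(200, 1, 1.2), "power")
})

test_that("binary intercept hits a 50% marginal control event rate", {
  ## symmetry: f(X) = X is odd, expit antisymmetric -> alpha = 0
  expect_lt(abs(calibrate_binary_intercept("linear", 0.7)), 1e-8)
  s <- pi / sqrt(3)
  set.seed(303)
  for (shape in c("monotonic", "nonmonotonic")) {
    bcov <- calibrate_beta_cov(shape, s)
    a <- calibrate_binary_intercept(shape, bcov)
    ## Monte-Carlo oracle: 1e6 control patients, 3 MC SEs ~ 0.0015
    x <- rnorm(1e6)
    rate <- mean(a + bcov * transform_covariate(x, shape) + rlogis(1e6) > 0)
    expect_lt(abs(rate - 0.5), 0.0015)
  }
  expect_lt(calibrate_binary_intercept(
    "nonmonotonic", calibrate_beta_cov("nonmonotonic", s)), 0)
})

test_that("scenario specs enforce the latent-logistic residual scale", {
  sp <- scenario_spec("binary", "linear", beta_trt = 0, reps = 10, seed = 1)
  expect_identical(sp$sigma_e, pi / sqrt(3))
  expect_identical(sp$n, 600L)
  sc <- scenario_spec("continuous", "monotonic", reps = 10, seed = 1)
  expect_identical(sc$sigma_e, 1)
  expect_identical(sc$n, 200L)
  expect_equal(sc$beta_cov, calibrate_beta_cov("monotonic", 1))
  expect_equal(sc$beta_trt, calibrate_beta_trt_continuous(200, 1, 0.8, 0.05))
  expect_error(scenario_spec("continuous", "linear", n = 10), "n")
  expect_error(scenario_spec("continuous", "linear", reps = 0), "reps")
  expect_error(scenario_spec("continuous", "linear", alpha_level = 1.5),
               "alpha_level")
})

test_that("simulated trials are reproducible and structurally valid", {
  sp <- scenario_spec("binary", "nonmonotonic", beta_trt = 0.4, reps = 1,
                      seed = 5)
  set.seed(42); t1 <- simulate_trial(sp)
  set.seed(42); t2 <- simulate_trial(sp)
  expect_identical(t1, t2)
  expect_identical(nrow(t1), 600L)
  expect_true(all(t1$outcome %in% c(0, 1)))
  expect_true(all(t1$arm %in% c(0, 1)))
  expect_gt(sum(t1$arm), 0)
  expect_gt(sum(1 - t1$arm), 0)
  expect_error(simulate_trial(scenario_spec("binary", "linear", reps = 1)),
               "unresolved")
})

test_that("noise-free continuous trials recover the treatment effect exactly", {
  sp <- scenario_spec("continuous", "linear", beta_trt = 0.4, reps = 1,
                      seed = 8)
  sp$sigma_e <- 1e-8
  set.seed(8)
  tr <- simulate_trial(sp)
  f <- fit_ols(tr$outcome, tr$arm, matrix(tr$covariate))
  expect_lt(abs(f$estimate - 0.4), 1e-6)
})

test_that("null binary model gives a 50% event rate in both arms", {
  sp <- scenario_spec("binary", "linear", n = 1e5, beta_trt = 0,
                      beta_cov = 0, reps = 1, seed = 9)
  set.seed(9)
  tr <- simulate_trial(sp)
  expect_lt(abs(mean(tr$outcome[tr$arm == 0]) - 0.5), 0.01)
  expect_lt(abs(mean(tr$outcome[tr$arm == 1]) - 0.5), 0.01)
})

test_that("latent-model covariate effect is recovered from control arms", {
  s <- pi / sqrt(3)
  bcov <- calibrate_beta_cov("linear", s)
  sp <- scenario_spec("binary", "linear", n = 1e5, beta_trt = 0, reps = 1,
                      seed = 10)
  set.seed(10)
  tr <- simulate_trial(sp)
  ctrl <- tr[tr$arm == 0, ]
  g <- glm(outcome ~ covariate, data = ctrl, family = binomial())
  expect_lt(abs(coef(g)["covariate"] - bcov),
            3 * summary(g)$coefficients["covariate", "Std. Error"])
})

test_that("binary treatment-effect bisection brackets a sane value", {
  run <- power_run("binary", "linear")
  bt <- run$spec$beta_trt
  ## unadjusted two-proportion 80%-power log OR at n=600, 50% event rate
  unadj <- (qnorm(0.975) + qnorm(0.8)) * sqrt(4 / (600 * 0.25))
  expect_gt(bt, unadj * 0.95)
  expect_lt(bt, unadj * 1.5)
  ## achieved power of the correctly specified analysis is near target
  ## (linear shape: the linear adjustment IS correctly specified)
  expect_lt(abs(rejection(run, "linear") - 0.8),
            0.02 + 3 * run$summaries$mc_se_rejection[3])
})

test_that("empirical power increases with the treatment effect", {
  sp0 <- scenario_spec("binary", "linear", beta_trt = 0, reps = 300,
                       seed = 31)
  grid <- c(0.15, 0.45, 0.9)
  pow <- vapply(grid, function(b) {
    sp <- scenario_spec("binary", "linear", beta_trt = b, reps = 300,
                        seed = 31)
    r <- run_scenario(sp)
    rejection(r, "linear")
  }, numeric(1L))
  expect_true(all(diff(pow) > 0))
})

test_that("trial export writes the documented delimited layout", {
  tr <- make_trial(n = 50, seed = 12)
  path <- tempfile(fileext = ".csv")
  export_trial(tr, path)
  back <- read.csv(path)
  expect_identical(names(back), c("id", "arm", "x", "y"))
  expect_equal(back$x, tr$covariate)
  expect_equal(back$y, tr$outcome)
})

test_that("derived seeds are positive 32-bit integers and distinct", {
  s <- vapply(1:500, function(r) derive_seed(123, 1L, r), integer(1L))
  expect_true(all(s >= 1))
  expect_true(all(s < 2^31))
  expect_gt(length(unique(s)), 499)  # collisions essentially absent
  expect_identical(derive_seed(7, 2, 3), derive_seed(7, 2, 3))
  expect_false(derive_seed(7, 2, 3) == derive_seed(7, 2, 4))
})
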