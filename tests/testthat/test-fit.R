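test_that("least-squares fit matches hand and pseudoinverse oracles", {
  f <- fit_ols(c(0, 1, 1, 2), c(0, 0, 1, 1))
  expect_equal(f$estimate, 1.0)
  ## noise-free recovery
  set.seed(41)
  x <- rnorm(80); arm <- rbinom(80, 1, 0.5)
  y <- 0.3 + 0.7 * arm + 1.2 * x - 0.4 * x^2
  f2 <- fit_ols(y, arm, cbind(x, x^2))
  expect_lt(abs(f2$estimate - 0.7), 1e-8)
  expect_lt(f2$deviance, 1e-16)
  ## Moore-Penrose oracle on random small problems
  for (i in 1:100) {
    n <- sample(20:60, 1)
    arm <- c(0, 1, rbinom(n - 2, 1, 0.5))
    B <- matrix(rnorm(n * sample(1:3, 1)), nrow = n)
    y <- rnorm(n)
    f3 <- fit_ols(y, arm, B)
    X <- cbind(1, arm, B)
    beta_pinv <- drop(MASS::ginv(X) %*% y)
    expect_lt(abs(f3$estimate - beta_pinv[2]), 1e-8)
  }
})

test_that("least-squares inference matches lm", {
  set.seed(42)
  x <- rnorm(150); arm <- rbinom(150, 1, 0.5)
  y <- 0.4 * arm + x + rnorm(150)
  b <- rcs_basis(x, rcs_knots(x, 5))
  f <- fit_ols(y, arm, b)
  ref <- lm(y ~ arm + b$columns)
  sref <- summary(ref)$coefficients["arm", ]
  expect_equal(f$estimate, unname(coef(ref)["arm"]), tolerance = 1e-10)
  expect_equal(f$se, unname(sref["Std. Error"]), tolerance = 1e-8)
  expect_equal(f$p_value, unname(sref["Pr(>|t|)"]), tolerance = 1e-8)
})

test_that("treatment estimate is invariant to shifting basis columns", {
  set.seed(43)
  x <- rnorm(100); arm <- rbinom(100, 1, 0.5)
  y <- 0.5 * arm + exp(x) + rnorm(100)
  B <- cbind(x, x^2)
  f1 <- fit_ols(y, arm, B)
  f2 <- fit_ols(y, arm, B + 100)   # intercept absorbs the shift
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-9)
  expect_equal(f1$se, f2$se, tolerance = 1e-7)
})

test_that("collinear basis columns are dropped with a warning", {
  set.seed(44)
  x <- rnorm(60); arm <- rbinom(60, 1, 0.5)
  y <- arm + x + rnorm(60)
  B <- cbind(a = x, b = 2 * x)
  expect_warning(f <- fit_ols(y, arm, B), "collinear")
  expect_true(f$converged)
  ref <- fit_ols(y, arm, matrix(x))
  expect_equal(f$estimate, ref$estimate, tolerance = 1e-10)
})

test_that("logistic fit matches the 2x2 closed form and glm", {
  ## arm=1: 20 events / 30 non-events; arm=0: 30 events / 20 non-events
  arm <- rep(c(1, 1, 0, 0), c(20, 30, 30, 20))
  y <- rep(c(1, 0, 1, 0), c(20, 30, 30, 20))
  f <- fit_logistic(y, arm)
  expect_equal(f$estimate, log((20 * 20) / (30 * 30)), tolerance = 1e-8)
  set.seed(45)
  x <- rnorm(300); arm <- rbinom(300, 1, 0.5)
  y <- rbinom(300, 1, plogis(0.3 * arm + x - 0.5 * x^2))
  B <- cbind(x, x^2)
  f2 <- fit_logistic(y, arm, B)
  g <- glm(y ~ arm + B, family = binomial(),
           control = glm.control(epsilon = 1e-12))
  expect_equal(f2$estimate, unname(coef(g)["arm"]), tolerance = 1e-8)
  expect_equal(f2$se, unname(summary(g)$coefficients["arm", "Std. Error"]),
               tolerance = 1e-6)
  expect_equal(f2$deviance, deviance(g), tolerance = 1e-8)
})

test_that("compiled and reference IRLS engines agree", {
  set.seed(46)
  for (i in 1:25) {
    n <- sample(50:200, 1)
    arm <- c(0, 1, rbinom(n - 2, 1, 0.5))
    B <- matrix(rnorm(n * sample(0:3, 1)), nrow = n)
    y <- rbinom(n, 1, plogis(0.2 * arm + rowSums(B) * 0.3))
    if (length(unique(y)) < 2) next
    X <- cbind(1, arm, B)
    a <- covadj:::irls_logistic(X, y, engine = "cpp")
    b <- covadj:::irls_logistic(X, y, engine = "r")
    if (a$converged && b$converged) {
      expect_equal(a$coef, b$coef, tolerance = 1e-8)
      expect_equal(a$deviance, b$deviance, tolerance = 1e-10)
      expect_equal(a$se, b$se, tolerance = 1e-8)
    }
  }
})

test_that("logistic deviance matches a generic optimiser oracle", {
  set.seed(47)
  negll <- function(beta, X, y) {
    eta <- drop(X %*% beta)
    sum(log1p(exp(-(2 * y - 1) * eta)))
  }
  worse <- 0
  for (i in 1:50) {
    n <- sample(60:150, 1)
    arm <- c(0, 1, rbinom(n - 2, 1, 0.5))
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.4 * arm + 0.8 * x))
    if (length(unique(y)) < 2) next
    f <- fit_logistic(y, arm, matrix(x))
    X <- cbind(1, arm, x)
    o <- optim(rep(0, 3), negll, X = X, y = y, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    expect_lt(f$deviance, 2 * o$value + 1e-6)
  }
})

test_that("null Wald p-values are uniform", {
  set.seed(48)
  p <- numeric(2000)
  for (r in 1:2000) {
    arm <- rbinom(100, 1, 0.5)
    if (length(unique(arm)) < 2) arm[1:2] <- c(0, 1)
    x <- rnorm(100)
    y <- x + rnorm(100)
    p[r] <- fit_ols(y, arm, matrix(x))$p_value
  }
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("FP selection recovers the true power and respects nesting", {
  set.seed(49)
  x <- rnorm(120); arm <- rbinom(120, 1, 0.5)
  y <- 0.5 * arm + 1.3 * x + rnorm(120, sd = 1e-5)
  f1 <- fit_fp(y, arm, x, 1, "continuous")
  expect_equal(f1$selected_powers, 1)
  expect_identical(attr(f1, "n_candidates"), 8L)
  ## with a genuinely linear association, FP1 at power 1 equals the linear fit
  lin <- fit_ols(y, arm, matrix(x + fp_shift(x)$shift))
  expect_equal(f1$estimate, lin$estimate, tolerance = 1e-10)
  ## nesting: FP2 <= FP1 <= linear deviance, on arbitrary noisy data
  for (i in 1:10) {
    xx <- rnorm(80); aa <- c(0, 1, rbinom(78, 1, 0.5))
    yy <- exp(xx / 2) + 0.3 * aa + rnorm(80)
    d_lin <- fit_ols(yy, aa, matrix(xx))$deviance
    d_fp1 <- fit_fp(yy, aa, xx, 1, "continuous")$deviance
    d_fp2 <- fit_fp(yy, aa, xx, 2, "continuous")$deviance
    expect_lte(d_fp1, d_lin + 1e-10)
    expect_lte(d_fp2, d_fp1 + 1e-10)
  }
  expect_identical(attr(fit_fp(rnorm(50), c(0, 1, rbinom(48, 1, .5)),
                               rnorm(50), 2, "continuous"),
                        "n_candidates"), 36L)
})

test_that("all seven methods analyse the identical trial", {
  tr <- make_trial("continuous", "linear", n = 200, beta_trt = 0.4,
                   seed = 51)
  res <- analyze_all_methods(tr, "continuous")
  expect_length(res, 7L)
  expect_identical(names(res), adjustment_methods())
  expect_identical(unname(vapply(res, `[[`, "", "method")),
                   adjustment_methods())
  ## low-noise variant: every method is unbiased for a linear association
  sp <- scenario_spec("continuous", "linear", beta_trt = 0.4, reps = 1,
                      seed = 52)
  sp$sigma_e <- 0.05
  set.seed(52)
  tr2 <- simulate_trial(sp)
  res2 <- analyze_all_methods(tr2, "continuous")
  for (f in res2)
    expect_lt(abs(f$estimate - 0.4), 3 * f$se + 0.02)
})

test_that("FP powers are reported only for FP methods", {
  tr <- make_trial(n = 100, seed = 53)
  res <- analyze_all_methods(tr, "continuous")
  for (m in adjustment_methods()) {
    if (m %in% c("fp1", "fp2"))
      expect_true(length(res[[m]]$selected_powers) >= 1)
    else
      expect_null(res[[m]]$selected_powers)
  }
  expect_true(all(vapply(res, function(f) f$p_value >= 0 && f$p_value <= 1,
                         logical(1L))))
})
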