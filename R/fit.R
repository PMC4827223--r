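## Outcome-model fitting and Wald inference on the treatment coefficient.
##
## Continuous outcomes: least squares through stats::lm.fit, t-reference
## with n - p df.  Binary outcomes: logistic maximum likelihood by iterative
## reweighted least squares (Fisher scoring; identical to Newton for the
## canonical link), z-reference.  The IRLS loop is written directly on the
## design matrix because the simulation study performs ~50 fits per
## replicate; tests cross-check it against stats::glm and a generic
## optimiser.

new_fitres <- function(method, estimate, se, statistic, p_value, converged,
                       deviance, df_residual, selected_powers = NULL,
                       coefficients = NULL, dropped = character(),
                       basis_meta = NULL, shift = 0) {
  structure(list(method = method, estimate = estimate, se = se,
                 statistic = statistic, p_value = p_value,
                 converged = converged, deviance = deviance,
                 df_residual = df_residual,
                 selected_powers = selected_powers,
                 coefficients = coefficients, dropped = dropped,
                 basis_meta = basis_meta, shift = shift),
            class = "covadj_fitres")
}

#' @export
print.covadj_fitres <- function(x, ...) {
  cat("Treatment-effect fit (", x$method, ")\n", sep = "")
  cat(sprintf("  estimate = %.5f  se = %.5f  p = %.4g  converged = %s\n",
              x$estimate, x$se, x$p_value, x$converged))
  if (!is.null(x$selected_powers))
    cat("  selected FP powers:",
        paste(x$selected_powers, collapse = ", "), "\n")
  invisible(x)
}

basis_columns <- function(basis) {
  if (is.null(basis)) return(NULL)
  if (inherits(basis, "covadj_basis")) return(basis$columns)
  as.matrix(basis)
}

## Assemble (intercept, arm, basis) and drop exactly-duplicated work later;
## rank deficiency is resolved by the fitters via pivoting.
assemble_design <- function(arm, basis) {
  B <- basis_columns(basis)
  X <- cbind("(Intercept)" = 1, arm = arm, B)
  X
}

## least squares with pivoted QR; drops aliased columns (never intercept or
## arm) with a warning and records them
ols_solve <- function(X, y) {
  fit <- lm.fit(X, y)
  dropped <- character()
  if (fit$rank < ncol(X)) {
    aliased <- names(fit$coefficients)[is.na(fit$coefficients)]
    if (any(aliased %in% c("(Intercept)", "arm")))
      stop("treatment or intercept column is aliased; cannot fit",
           call. = FALSE)
    warning("dropping collinear basis column(s): ",
            paste(aliased, collapse = ", "), call. = FALSE)
    dropped <- aliased
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    fit <- lm.fit(X, y)
  }
  rss <- sum(fit$residuals^2)
  df <- length(y) - fit$rank
  ## unscaled covariance from the pivoted QR factor
  R <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  V <- matrix(NA_real_, ncol(X), ncol(X))
  V[piv, piv] <- chol2inv(R)
  list(coef = fit$coefficients, rss = rss, df = df, cov_unscaled = V,
       dropped = dropped, X = X)
}

#' Least-squares fit of the adjusted trial model
#'
#' Fits `outcome ~ intercept + arm + basis columns` by ordinary least
#' squares and tests the treatment (arm) coefficient with a Wald t test on
#' `n - p` residual degrees of freedom.  Collinear basis columns are
#' dropped with a warning and recorded in the result.
#'
#' @param y numeric outcome vector.
#' @param arm 0/1 treatment indicator.
#' @param basis a `covadj_basis`, a numeric matrix, or `NULL` for an
#'   unadjusted fit.
#' @return A `covadj_fitres`: treatment estimate, SE, two-sided p-value,
#'   residual sum of squares as `deviance`, full coefficient vector, and
#'   the basis metadata needed for prediction.
#' @export
#' @examples
#' fit_ols(c(0, 1, 1, 2), c(0, 0, 1, 1), NULL)$estimate  # 1
fit_ols <- function(y, arm, basis = NULL) {
  check_fit_inputs(y, arm, basis)
  X <- assemble_design(arm, basis)
  s <- ols_solve(X, y)
  if (s$df < 1) stop("no residual degrees of freedom", call. = FALSE)
  sigma2 <- s$rss / s$df
  se <- sqrt(diag(s$cov_unscaled) * sigma2)
  est <- s$coef["arm"]
  tval <- est / se[which(colnames(s$X) == "arm")]
  se_arm <- se[which(colnames(s$X) == "arm")]
  p <- 2 * pt(-abs(tval), df = s$df)
  new_fitres(method = basis_method(basis), estimate = unname(est),
             se = unname(se_arm), statistic = unname(tval),
             p_value = unname(p), converged = TRUE, deviance = s$rss,
             df_residual = s$df, coefficients = s$coef[!is.na(s$coef)],
             dropped = s$dropped, basis_meta = basis_meta_of(basis),
             shift = basis_shift_of(basis))
}

## IRLS for logistic regression; convergence when the maximum absolute
## score is <= 1e-8 or the relative deviance change is <= 1e-10, hard cap
## 100 iterations; step-halving guards against divergence.  The compiled
## engine carries the simulation workload; the R reference implementation
## below is retained as the slower cross-check (engine = "r").
irls_logistic <- function(X, y, max_iter = 100L, score_tol = 1e-8,
                          dev_tol = 1e-10, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp")
    .irls_logistic_cpp(X, y, max_iter, score_tol, dev_tol)
  else
    irls_logistic_r(X, y, max_iter, score_tol, dev_tol)
}

irls_logistic_r <- function(X, y, max_iter = 100L, score_tol = 1e-8,
                            dev_tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  dev <- -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit <- .lm.fit(X * sw, z * sw)
    beta_new <- fit$coefficients
    if (fit$rank < p || any(!is.finite(beta_new)))
      return(list(coef = rep(NA_real_, p), se = rep(NA_real_, p),
                  deviance = dev, converged = FALSE, iter = it,
                  rank_deficient = fit$rank < p, pivot = fit$pivot))
    ## undo .lm.fit pivoting
    beta_new[fit$pivot] <- beta_new
    step <- beta_new - beta
    dev_new <- Inf
    for (h in 0:20) {
      beta_try <- beta + step / 2^h
      eta_try <- drop(X %*% beta_try)
      mu_try <- plogis(eta_try)
      mu_try <- pmin(pmax(mu_try, 1e-15), 1 - 1e-15)
      dev_new <- -2 * sum(y * log(mu_try) + (1 - y) * log1p(-mu_try))
      if (is.finite(dev_new) && dev_new <= dev + 1e-8) break
    }
    beta <- beta_try; eta <- eta_try; mu <- mu_try
    score <- drop(crossprod(X, y - mu))
    rel_dev <- abs(dev - dev_new) / (abs(dev_new) + 0.1)
    dev <- dev_new
    if (max(abs(score)) <= score_tol || rel_dev <= dev_tol) {
      converged <- TRUE
      break
    }
    ## flat deviance with an extreme linear predictor: quasi-separation,
    ## the MLE is drifting to infinity; further iterations cannot converge
    if (rel_dev <= 1e-6 && max(abs(eta)) > 20) break
  }
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X * sqrt(w))
  se <- tryCatch(sqrt(diag(chol2inv(chol(info)))),
                 error = function(e) rep(NA_real_, p))
  ## very large coefficients or exploding SEs signal (quasi-)separation
  if (converged && (any(abs(beta) > 1e3) || any(!is.finite(se))))
    converged <- FALSE
  list(coef = beta, se = se, deviance = dev, converged = converged,
       iter = it, rank_deficient = FALSE)
}

#' Maximum-likelihood logistic fit of the adjusted trial model
#'
#' Fits `logit P(outcome = 1) = intercept + arm + basis columns` by
#' iteratively reweighted least squares and tests the treatment coefficient
#' with a Wald z test.  Convergence requires the maximum absolute score to
#' fall below 1e-8 or the relative deviance change below 1e-10 within 100
#' iterations; separation or non-convergence is reported through the
#' `converged` flag rather than an error.
#'
#' @inheritParams fit_ols
#' @param y 0/1 outcome vector with both classes present.
#' @return A `covadj_fitres` with the deviance (-2 log-likelihood).
#' @export
#' @examples
#' set.seed(1)
#' arm <- rbinom(80, 1, 0.5); y <- rbinom(80, 1, plogis(0.4 * arm))
#' fit_logistic(y, arm, NULL)$method
fit_logistic <- function(y, arm, basis = NULL) {
  check_fit_inputs(y, arm, basis)
  if (!all(y %in% c(0, 1)))
    stop("binary outcome must contain only 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("binary outcome has only one class", call. = FALSE)
  X <- assemble_design(arm, basis)
  fit <- irls_logistic(X, y)
  dropped <- character()
  if (isTRUE(fit$rank_deficient)) {
    ## identify aliased columns via QR of X and refit without them
    q <- qr(X)
    aliased <- colnames(X)[q$pivot[-seq_len(q$rank)]]
    if (any(aliased %in% c("(Intercept)", "arm")))
      stop("treatment or intercept column is aliased; cannot fit",
           call. = FALSE)
    warning("dropping collinear basis column(s): ",
            paste(aliased, collapse = ", "), call. = FALSE)
    dropped <- aliased
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    fit <- irls_logistic(X, y)
  }
  arm_ix <- which(colnames(X) == "arm")
  est <- fit$coef[arm_ix]; se <- fit$se[arm_ix]
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  cf <- fit$coef
  names(cf) <- colnames(X)
  new_fitres(method = basis_method(basis), estimate = est, se = se,
             statistic = z, p_value = p, converged = fit$converged,
             deviance = fit$deviance, df_residual = nrow(X) - ncol(X),
             coefficients = cf, dropped = dropped,
             basis_meta = basis_meta_of(basis),
             shift = basis_shift_of(basis))
}

#' Fractional-polynomial fit with power selection
#'
#' Shifts the covariate to positivity ([fp_shift()]), fits the full model
#' (intercept + treatment + FP basis) for every candidate power
#' combination ([fp_candidates()]), and returns the fit minimising the
#' deviance (residual sum of squares for continuous outcomes).  The
#' treatment term is included in every candidate fit and the covariate is
#' never dropped, whatever its significance.  Ties keep the first candidate
#' in the canonical grid order, making runs bit-reproducible.  Candidates
#' that fail to converge are skipped; if all fail, an error is raised.
#'
#' @param y outcome vector.
#' @param arm 0/1 treatment indicator.
#' @param x raw covariate vector.
#' @param order 1 (FP1) or 2 (FP2).
#' @param family `"continuous"` or `"binary"`.
#' @return A `covadj_fitres` with `selected_powers` set and the number of
#'   evaluated candidates in attribute `"n_candidates"`.
#' @export
#' @examples
#' set.seed(1); x <- rnorm(60); arm <- rbinom(60, 1, 0.5)
#' y <- 0.5 * arm + x + rnorm(60, sd = 1e-4)
#' fit_fp(y, arm, x, order = 1, family = "continuous")$selected_powers  # 1
fit_fp <- function(y, arm, x, order, family = c("continuous", "binary")) {
  family <- match.arg(family)
  sh <- fp_shift(x)
  cands <- fp_candidates(order)
  ## precompute the single-power transforms once; candidate design matrices
  ## are then assembled by column indexing, and the scan calls the bare
  ## fitting engines (only the winning candidate gets the full inference)
  terms <- lapply(FP_POWERS, function(p) fp_term(sh$x, p))
  names(terms) <- as.character(FP_POWERS)
  logx <- log(sh$x)
  n <- length(y)
  best_pw <- NULL; best_dev <- Inf; n_failed <- 0L
  for (pw in cands) {
    if (length(pw) == 1L) {
      cols <- terms[[as.character(pw)]]
    } else if (pw[1L] == pw[2L]) {
      t1 <- terms[[as.character(pw[1L])]]
      cols <- cbind(t1, t1 * logx)
    } else {
      cols <- cbind(terms[[as.character(pw[1L])]],
                    terms[[as.character(pw[2L])]])
    }
    X <- cbind(1, arm, cols)
    if (family == "continuous") {
      f <- .lm.fit(X, y)
      if (f$rank < ncol(X)) { n_failed <- n_failed + 1L; next }
      dev <- sum(f$residuals^2)
    } else {
      f <- irls_logistic(X, y)
      if (isTRUE(f$rank_deficient) || !f$converged) {
        n_failed <- n_failed + 1L; next
      }
      dev <- f$deviance
    }
    if (dev < best_dev) { best_dev <- dev; best_pw <- pw }
  }
  if (is.null(best_pw))
    stop("no fractional-polynomial candidate converged", call. = FALSE)
  b <- fp_basis(sh$x, best_pw, sh$shift)
  best <- if (family == "continuous") fit_ols(y, arm, b)
          else fit_logistic(y, arm, b)
  best$selected_powers <- best_pw
  best$method <- if (order == 1) "fp1" else "fp2"
  attr(best, "n_candidates") <- length(cands)
  attr(best, "n_failed") <- n_failed
  best
}

#' Analyse one trial with all seven adjustment methods
#'
#' Runs the dichotomised, categorised, linear, FP1, FP2, RCS-3 and RCS-5
#' analyses on the identical dataset and returns one fit result per method.
#' Per-method failures are captured as flagged (non-converged, NA-estimate)
#' results rather than aborting the set.
#'
#' @param trial a `trial_data` data frame (columns `arm`, `covariate`,
#'   `outcome`), e.g. from [simulate_trial()].
#' @param family `"continuous"` or `"binary"`.
#' @return Named list of 7 `covadj_fitres`, in the canonical method order.
#' @export
analyze_all_methods <- function(trial, family = c("continuous", "binary")) {
  family <- match.arg(family)
  y <- trial$outcome; arm <- trial$arm; x <- trial$covariate
  fit1 <- function(method) {
    tryCatch({
      if (method == "fp1") fit_fp(y, arm, x, 1, family)
      else if (method == "fp2") fit_fp(y, arm, x, 2, family)
      else {
        b <- build_basis(x, method)
        if (family == "continuous") fit_ols(y, arm, b)
        else fit_logistic(y, arm, b)
      }
    }, error = function(e) {
      new_fitres(method = method, estimate = NA_real_, se = NA_real_,
                 statistic = NA_real_, p_value = NA_real_,
                 converged = FALSE, deviance = NA_real_,
                 df_residual = NA_integer_)
    })
  }
  setNames(lapply(COVADJ_METHODS, fit1), COVADJ_METHODS)
}

basis_method <- function(basis) {
  if (is.null(basis)) "unadjusted"
  else if (inherits(basis, "covadj_basis")) basis$method
  else "custom"
}
basis_meta_of <- function(basis)
  if (inherits(basis, "covadj_basis")) basis$meta else NULL
basis_shift_of <- function(basis)
  if (inherits(basis, "covadj_basis")) basis$shift else 0

check_fit_inputs <- function(y, arm, basis) {
  if (anyNA(y) || anyNA(arm))
    stop("missing values in outcome or arm", call. = FALSE)
  if (length(y) != length(arm))
    stop("outcome and arm lengths differ", call. = FALSE)
  if (!all(arm %in% c(0, 1)))
    stop("'arm' must be a 0/1 indicator", call. = FALSE)
  if (length(unique(arm)) < 2L)
    stop("both treatment arms must be represented", call. = FALSE)
  B <- basis_columns(basis)
  if (!is.null(B) && nrow(B) != length(y))
    stop("basis rows do not match outcome length", call. = FALSE)
  invisible(TRUE)
}
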