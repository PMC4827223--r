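## covadj(): formula front end and S3 methods.
##
## One call analyses one two-arm trial with a chosen covariate-adjustment
## method (or all of them) and returns a classed object carrying the
## treatment-effect inference plus everything needed to predict and to plot
## the estimated covariate-outcome association.

#' Covariate-adjusted analysis of a randomised trial
#'
#' Fits the trial outcome model `outcome ~ treatment + g(covariate)` where
#' `g` is one of eight handlings of the continuous baseline covariate:
#' excluded (`"unadjusted"`), median-dichotomised, quartile-categorised,
#' linear, fractional polynomial of order 1 or 2 (`"fp1"`, `"fp2"`; powers
#' selected from \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} by minimum deviance with
#' the treatment term always included), or a restricted cubic spline with 3
#' or 5 knots at the conventional percentiles (`"rcs3"`, `"rcs5"`).
#' Continuous outcomes are fitted by least squares (treatment effect =
#' adjusted difference in means, Wald t test); binary outcomes by logistic
#' maximum likelihood (treatment effect = conditional log odds ratio, Wald
#' z test).
#'
#' @param formula a two-sided formula `outcome ~ treatment + covariate`;
#'   the first right-hand-side variable is the 0/1 treatment indicator and
#'   the second the continuous baseline covariate.
#' @param data a data frame containing the formula variables.
#' @param family `"continuous"` or `"binary"`; defaults to `"binary"` when
#'   the outcome takes only values 0 and 1, else `"continuous"`.
#' @param method one of `"unadjusted"`, `"dichotomised"`, `"categorised"`,
#'   `"linear"`, `"fp1"`, `"fp2"`, `"rcs3"`, `"rcs5"`, or `"all"` (default)
#'   to fit every method on the same data.
#' @param conf_level confidence level for intervals (default 0.95).
#' @return An object of class `"covadj"` with `print`, `summary`, `coef`,
#'   `confint`, `predict`, `residuals` and `plot` methods.
#' @export
#' @examples
#' sp <- scenario_spec("continuous", "monotonic", reps = 1, seed = 3)
#' set.seed(3)
#' tr <- simulate_trial(sp)
#' fit <- covadj(outcome ~ arm + covariate, tr, method = "rcs3")
#' coef(fit)
covadj <- function(formula, data, family = NULL, method = "all",
                   conf_level = 0.95) {
  if (!inherits(formula, "formula") || length(formula) != 3L)
    stop("'formula' must be two-sided: outcome ~ treatment + covariate",
         call. = FALSE)
  vars <- all.vars(formula)
  if (length(vars) != 3L)
    stop("formula must name exactly outcome, treatment and covariate",
         call. = FALSE)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("variable(s) not in 'data': ", paste(miss, collapse = ", "),
         call. = FALSE)
  y <- data[[vars[1L]]]; arm <- data[[vars[2L]]]; x <- data[[vars[3L]]]
  if (anyNA(y) || anyNA(arm) || anyNA(x))
    stop("missing values are not supported", call. = FALSE)
  if (!all(arm %in% c(0, 1)))
    stop("treatment indicator '", vars[2L], "' must be 0/1", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("covariate '", vars[3L], "' is constant", call. = FALSE)
  if (is.null(family))
    family <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  family <- match.arg(family, c("continuous", "binary"))

  all_methods <- c("unadjusted", COVADJ_METHODS)
  methods <- if (identical(method, "all")) all_methods
             else match.arg(method, all_methods, several.ok = TRUE)

  fits <- setNames(lapply(methods, function(m)
    fit_one_method(y, arm, x, m, family)), methods)

  structure(list(call = match.call(), family = family,
                 variables = setNames(as.list(vars),
                                      c("outcome", "treatment", "covariate")),
                 fits = fits, conf_level = conf_level,
                 data = data.frame(outcome = y, arm = arm, covariate = x)),
            class = "covadj")
}

fit_one_method <- function(y, arm, x, method, family) {
  if (method == "fp1") return(fit_fp(y, arm, x, 1, family))
  if (method == "fp2") return(fit_fp(y, arm, x, 2, family))
  b <- if (method == "unadjusted") NULL else build_basis(x, method)
  if (family == "continuous") fit_ols(y, arm, b) else fit_logistic(y, arm, b)
}

effect_label <- function(family)
  if (family == "continuous") "difference in means" else "log odds ratio"

#' Tabulate the treatment-effect estimates of a covadj fit
#'
#' @param object a `covadj` object.
#' @param ... unused.
#' @return A data frame with one row per fitted method: estimate, standard
#'   error, confidence limits, p-value and convergence flag (for binary
#'   outcomes the estimate is the conditional log odds ratio; the odds
#'   ratio columns are added alongside).
#' @export
summary.covadj <- function(object, ...) {
  zq <- qnorm(1 - (1 - object$conf_level) / 2)
  rows <- lapply(object$fits, function(f) {
    data.frame(method = f$method, estimate = f$estimate, se = f$se,
               lower = f$estimate - zq * f$se,
               upper = f$estimate + zq * f$se,
               p_value = f$p_value, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (object$family == "binary") {
    out$odds_ratio <- exp(out$estimate)
    out$or_lower <- exp(out$lower)
    out$or_upper <- exp(out$upper)
  }
  attr(out, "effect") <- effect_label(object$family)
  attr(out, "conf_level") <- object$conf_level
  class(out) <- c("summary.covadj", "data.frame")
  out
}

#' @export
print.summary.covadj <- function(x, digits = 4, ...) {
  cat("Treatment effect (", attr(x, "effect"), "), ",
      format(100 * attr(x, "conf_level")), "% CI\n\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
print.covadj <- function(x, ...) {
  cat("Covariate-adjusted trial analysis (", x$family, " outcome)\n",
      sep = "")
  cat("Call: ", deparse(x$call), "\n\n")
  print(summary(x))
  invisible(x)
}

#' @export
coef.covadj <- function(object, ...) {
  vapply(object$fits, function(f) f$estimate, numeric(1L))
}

#' @export
confint.covadj <- function(object, parm, level = NULL, ...) {
  level <- level %||% object$conf_level
  zq <- qnorm(1 - (1 - level) / 2)
  est <- coef(object)
  se <- vapply(object$fits, function(f) f$se, numeric(1L))
  out <- cbind(lower = est - zq * se, upper = est + zq * se)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

covadj_linpred <- function(object, method, arm, x) {
  f <- object$fits[[method]]
  if (is.null(f)) stop("method '", method, "' was not fitted", call. = FALSE)
  B <- basis_from_meta(x, f$method, f$basis_meta, f$shift)
  colnames(B) <- basis_colnames(f$method, ncol(B))
  X <- cbind("(Intercept)" = rep(1, length(x)), arm = arm, B)
  drop(X[, names(f$coefficients), drop = FALSE] %*% f$coefficients)
}

basis_colnames <- function(method, d) {
  switch(method,
         unadjusted   = character(),
         dichotomised = "high",
         categorised  = c("q2", "q3", "q4"),
         linear       = "x",
         fp1          = ,
         fp2          = paste0("fp", seq_len(d)),
         rcs3         = ,
         rcs5         = c("x", paste0("nl", seq_len(d - 1L))))
}

#' Predict from a covadj fit
#'
#' @param object a `covadj` object.
#' @param newdata optional data frame with the treatment and covariate
#'   columns used in the fit; defaults to the training data.
#' @param method which fitted method to predict from; defaults to the first.
#' @param type `"link"` for the linear predictor (identical to the mean for
#'   continuous outcomes) or `"response"` for the event probability under a
#'   binary outcome.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.covadj <- function(object, newdata = NULL,
                           method = names(object$fits)[1L],
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    arm <- object$data$arm; x <- object$data$covariate
  } else {
    tv <- object$variables
    arm <- newdata[[tv$treatment]] %||% newdata$arm
    x <- newdata[[tv$covariate]] %||% newdata$covariate
    if (is.null(arm) || is.null(x))
      stop("'newdata' must contain the treatment and covariate columns",
           call. = FALSE)
  }
  eta <- covadj_linpred(object, method, arm, x)
  if (type == "response" && object$family == "binary") plogis(eta) else eta
}

#' @export
residuals.covadj <- function(object, method = names(object$fits)[1L], ...) {
  pred <- predict(object, method = method,
                  type = if (object$family == "binary") "response" else "link")
  object$data$outcome - pred
}

#' Plot the estimated covariate-outcome association
#'
#' Draws, for each fitted method, the estimated association between the
#' baseline covariate and the outcome (linear predictor in the control
#' arm), over the observed covariate range.
#'
#' @param x a `covadj` object.
#' @param methods which methods to draw; defaults to all fitted ones.
#' @param n_grid grid resolution.
#' @param ... passed to [graphics::matplot()].
#' @return The grid data frame, invisibly.
#' @export
plot.covadj <- function(x, methods = names(x$fits), n_grid = 200L, ...) {
  xr <- range(x$data$covariate)
  ## keep FP methods inside their shifted-positive domain
  xg <- seq(xr[1L], xr[2L], length.out = n_grid)
  preds <- sapply(methods, function(m)
    covadj_linpred(x, m, arm = rep(0, n_grid), x = xg))
  graphics::matplot(xg, preds, type = "l", lty = 1,
                    xlab = x$variables$covariate,
                    ylab = "linear predictor (control arm)", ...)
  graphics::legend("topleft", legend = methods, col = seq_along(methods),
                   lty = 1, cex = 0.8, bty = "n")
  invisible(data.frame(x = xg, preds))
}
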