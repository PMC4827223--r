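## Monte-Carlo engine: runs scenarios, accumulates per-method estimates and
## p-values, and summarises bias, attenuation, type I error / power and
## Monte-Carlo standard errors.

#' Run one Monte-Carlo scenario
#'
#' Simulates `spec$reps` trials (each replicate from its own seed stream
#' derived from `spec$seed`, so results are independent of execution order),
#' analyses every trial with all seven adjustment methods, and summarises
#' each method: mean treatment estimate, bias, percent attenuation
#' (`100 * (beta_trt - mean estimate) / beta_trt`, only when the true effect
#' is non-zero), rejection rate at the scenario's alpha level, Monte-Carlo
#' standard errors, and failure counts.  Non-converged replicates count as
#' non-rejections and are excluded from the estimate summaries.
#'
#' @param spec a [scenario_spec()]; a deferred binary treatment-effect
#'   calibration is resolved first (see [calibrate_scenario()]).
#' @param calib_reps simulated trials per calibration candidate, when
#'   calibration is needed.
#' @param verbose print a one-line progress note.
#' @return An object of class `"scenario_results"`: the resolved `spec`, a
#'   `summaries` data frame (one row per method, including `power_vs_fp2`,
#'   the percentage-point rejection-rate difference of FP2 minus the
#'   method), and the replicate-level estimate and p-value matrices.
#' @export
#' @examples
#' sp <- scenario_spec("continuous", "linear", beta_trt = 0, reps = 50,
#'                     seed = 11)
#' run_scenario(sp)$summaries[, c("method", "rejection_rate")]
run_scenario <- function(spec, calib_reps = 10000, verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  spec <- calibrate_scenario(spec, reps = calib_reps)
  reps <- spec$reps
  nm <- length(COVADJ_METHODS)
  est <- matrix(NA_real_, reps, nm, dimnames = list(NULL, COVADJ_METHODS))
  pval <- est
  conv <- matrix(FALSE, reps, nm, dimnames = list(NULL, COVADJ_METHODS))
  attempts <- integer(reps)

  for (r in seq_len(reps)) {
    set.seed(derive_seed(spec$seed, stream = 1L, rep = r))
    trial <- simulate_trial(spec)
    attempts[r] <- attr(trial, "attempts")
    fits <- analyze_all_methods(trial, spec$outcome_family)
    for (j in seq_len(nm)) {
      f <- fits[[j]]
      est[r, j] <- f$estimate
      pval[r, j] <- f$p_value
      conv[r, j] <- isTRUE(f$converged)
    }
  }

  summaries <- summarise_methods(est, pval, conv, spec)
  if (any(summaries$n_failed > 0.01 * reps))
    warning("more than 1% of replicates failed for method(s): ",
            paste(summaries$method[summaries$n_failed > 0.01 * reps],
                  collapse = ", "), call. = FALSE)
  if (verbose)
    message(sprintf("scenario %s/%s: %d reps, %d regenerated draws, %d failures",
                    spec$outcome_family, spec$shape, reps,
                    sum(attempts > 1L), sum(!conv)))
  structure(list(spec = spec, summaries = summaries,
                 estimates = est, p_values = pval, converged = conv,
                 regen_draws = sum(attempts > 1L)),
            class = "scenario_results")
}

summarise_methods <- function(est, pval, conv, spec) {
  reps <- nrow(est)
  alpha <- spec$alpha_level
  rows <- lapply(seq_len(ncol(est)), function(j) {
    ok <- conv[, j] & is.finite(est[, j])
    n_ok <- sum(ok)
    mean_est <- if (n_ok) mean(est[ok, j]) else NA_real_
    mc_se_est <- if (n_ok > 1L) sd(est[ok, j]) / sqrt(n_ok) else NA_real_
    bias <- mean_est - spec$beta_trt
    atten <- if (spec$beta_trt != 0)
      100 * (spec$beta_trt - mean_est) / spec$beta_trt else NA_real_
    ## non-converged replicates are non-rejections; denominator stays reps
    rej <- sum(pval[, j] < alpha & conv[, j], na.rm = TRUE) / reps
    data.frame(method = colnames(est)[j],
               mean_estimate = mean_est, mc_se_estimate = mc_se_est,
               bias = bias, pct_attenuation = atten,
               rejection_rate = rej,
               mc_se_rejection = sqrt(rej * (1 - rej) / reps),
               n_failed = reps - n_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$power_vs_fp2 <-
    100 * (out$rejection_rate[out$method == "fp2"] - out$rejection_rate)
  rownames(out) <- NULL
  out
}

#' @export
print.scenario_results <- function(x, digits = 4, ...) {
  s <- x$spec
  cat(sprintf("Scenario: %s outcome, %s shape, n=%d, reps=%d, beta_trt=%.4g\n",
              s$outcome_family, s$shape, s$n, s$reps, s$beta_trt))
  cols <- c("method", "mean_estimate", "bias", "pct_attenuation",
            "rejection_rate", "mc_se_rejection", "power_vs_fp2", "n_failed")
  print.data.frame(x$summaries[, cols], digits = digits, row.names = FALSE)
  invisible(x)
}

#' Run a grid of scenarios
#'
#' Runs each scenario independently (results in input order; each scenario
#' is fully determined by its own seed, so any execution order gives
#' identical aggregates).  A failing scenario is captured as an error
#' object in its slot rather than aborting the grid.
#'
#' @param specs non-empty list of [scenario_spec()] objects.
#' @param calib_reps,verbose passed to [run_scenario()].
#' @return A list of `scenario_results` (or captured errors), class
#'   `"grid_results"`.
#' @export
run_grid <- function(specs, calib_reps = 10000, verbose = FALSE) {
  if (!is.list(specs) || length(specs) == 0L ||
      !all(vapply(specs, inherits, logical(1L), "scenario_spec")))
    stop("'specs' must be a non-empty list of scenario_spec objects",
         call. = FALSE)
  out <- lapply(specs, function(sp)
    tryCatch(run_scenario(sp, calib_reps = calib_reps, verbose = verbose),
             error = function(e) e))
  class(out) <- "grid_results"
  out
}

#' The default 12-scenario study grid
#'
#' Two outcome families (continuous n=200, binary n=600) crossed with the
#' three association shapes and two treatment-effect settings (null, and
#' calibrated 80%-power effect).
#'
#' @param seed base seed; each scenario derives its own stream from it.
#' @param reps replications per scenario (default 5000).
#' @param alpha_level two-sided test size.
#' @return List of 12 [scenario_spec()] objects.
#' @export
default_scenario_grid <- function(seed = 1L, reps = 5000,
                                  alpha_level = 0.05) {
  specs <- list()
  i <- 0L
  for (family in c("continuous", "binary"))
    for (shape in COVADJ_SHAPES)
      for (effect in c("null", "calibrated")) {
        i <- i + 1L
        specs[[i]] <- scenario_spec(
          family, shape,
          beta_trt = if (effect == "null") 0 else "calibrated",
          reps = reps, seed = derive_seed(seed, stream = 100L + i),
          alpha_level = alpha_level)
      }
  specs
}

#' Flatten grid results into one summary table
#'
#' One row per (scenario, method): scenario descriptors, the true effect,
#' mean estimate, bias, percent attenuation, rejection rate (type I error
#' under the null, power otherwise), Monte-Carlo standard errors,
#' FP2-relative power difference, and failure counts.
#'
#' @param results a `grid_results` list from [run_grid()] (or a list of
#'   `scenario_results`).
#' @return A data frame.
#' @export
summarise_power_table <- function(results) {
  ok <- vapply(results, inherits, logical(1L), "scenario_results")
  if (!any(ok)) stop("no successful scenario results", call. = FALSE)
  rows <- lapply(results[ok], function(r) {
    s <- r$spec
    cbind(data.frame(outcome_family = s$outcome_family, shape = s$shape,
                     n = s$n, reps = s$reps, seed = s$seed,
                     beta_trt = s$beta_trt, beta_cov = s$beta_cov,
                     stringsAsFactors = FALSE),
          r$summaries)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
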