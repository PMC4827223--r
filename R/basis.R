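## Covariate representations ("bases").
##
## Each constructor returns a covadj_basis: the design-matrix columns the
## covariate contributes to the outcome model (intercept and treatment
## excluded), plus the metadata needed to rebuild the same columns for new
## data (cutpoints, FP powers and shift, spline knots and weights).

new_basis <- function(method, columns, meta = list(), shift = 0) {
  colnames(columns) <- meta$colnames %||% colnames(columns)
  structure(list(method = method, columns = columns, meta = meta,
                 shift = shift),
            class = "covadj_basis")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.covadj_basis <- function(x, ...) {
  cat("Covariate basis:", x$method, "-", ncol(x$columns), "column(s),",
      nrow(x$columns), "rows\n")
  if (length(x$meta)) {
    for (nm in setdiff(names(x$meta), "colnames"))
      cat(" ", nm, "=", paste(format(x$meta[[nm]], digits = 6),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

## sample percentiles: linear interpolation between order statistics
## ("type 7"), used consistently for medians, quartiles and knots
pctl <- function(x, probs) unname(quantile(x, probs, type = 7, names = FALSE))

#' Dichotomise a covariate at its sample median
#'
#' One indicator column `1{x > median(x)}`, the median computed with the
#' usual mid-interpolation convention.  A constant covariate yields an
#' all-zero column with a warning (the collinearity is handled by the model
#' fit).
#'
#' @param x numeric vector, length >= 2.
#' @return A `covadj_basis` with one 0/1 column; the cutpoint is stored in
#'   `meta$cutpoints`.
#' @export
#' @examples
#' dichotomise(c(1, 2, 3, 4))$columns
dichotomise <- function(x) {
  check_covariate(x, min_len = 2L)
  m <- median(x)
  col <- as.numeric(x > m)
  if (all(col == 0))
    warning("constant covariate: dichotomised column is all zero",
            call. = FALSE)
  new_basis("dichotomised", matrix(col, ncol = 1L,
                                   dimnames = list(NULL, "high")),
            meta = list(cutpoints = m))
}

#' Categorise a covariate at its sample quartiles
#'
#' Three mutually exclusive indicator columns for quartile groups 2-4
#' against the lowest quartile as reference; membership uses strict `>`
#' against the 25th/50th/75th sample percentiles, so the groups are the
#' half-open intervals (q25, q50], (q50, q75], (q75, Inf).
#'
#' @param x numeric vector, length >= 8.
#' @return A `covadj_basis` with three 0/1 columns; cutpoints in
#'   `meta$cutpoints`.
#' @export
#' @examples
#' categorise(1:8)$columns
categorise <- function(x) {
  check_covariate(x, min_len = 8L)
  q <- pctl(x, c(0.25, 0.5, 0.75))
  if (any(diff(q) <= 0)) {
    tied <- which(diff(q) <= 0)
    stop("tied quartile cutpoints (empty category between the ",
         paste(c("25th/50th", "50th/75th")[tied], collapse = " and "),
         " percentiles); categorisation is not possible", call. = FALSE)
  }
  cols <- cbind(q2 = as.numeric(x > q[1L] & x <= q[2L]),
                q3 = as.numeric(x > q[2L] & x <= q[3L]),
                q4 = as.numeric(x > q[3L]))
  new_basis("categorised", cols, meta = list(cutpoints = q))
}

linear_basis <- function(x) {
  check_covariate(x, min_len = 2L)
  new_basis("linear", matrix(x, ncol = 1L, dimnames = list(NULL, "x")))
}

#' Shift a covariate to strict positivity for fractional polynomials
#'
#' Power transforms require a strictly positive argument.  If `min(x) > 0`
#' the shift is 0; otherwise the shift is `-min(x) + delta`, with `delta`
#' the smallest positive gap between adjacent sorted distinct values of `x`
#' (the Royston-Sauerbrei convention).
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return A list with `x` (shifted vector, all entries > 0) and `shift`.
#' @export
#' @examples
#' fp_shift(c(-1, 0, 2))  # delta = 1, shift = 2
fp_shift <- function(x) {
  check_covariate(x, min_len = 2L)
  ux <- sort(unique(x))
  if (length(ux) < 2L)
    stop("constant covariate: cannot build a fractional-polynomial basis",
         call. = FALSE)
  shift <- if (ux[1L] > 0) 0 else -ux[1L] + min(diff(ux))
  list(x = x + shift, shift = shift)
}

FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Candidate fractional-polynomial powers
#'
#' Order 1 gives the 8 single powers from \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\};
#' order 2 gives all 36 unordered pairs (28 distinct + 8 repeated).  Power 0
#' denotes the log transform by convention.  The list order (ascending,
#' `p1 <= p2`) is the canonical tie-break order for model selection.
#'
#' @param order 1 or 2.
#' @return A list of numeric vectors (length `order` each).
#' @export
#' @examples
#' length(fp_candidates(2))  # 36
fp_candidates <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || !order %in% c(1, 2))
    stop("'order' must be 1 or 2", call. = FALSE)
  if (order == 1) return(lapply(FP_POWERS, function(p) p))
  out <- list()
  for (i in seq_along(FP_POWERS))
    for (j in i:length(FP_POWERS))
      out[[length(out) + 1L]] <- c(FP_POWERS[i], FP_POWERS[j])
  out
}

fp_term <- function(x, p) if (p == 0) log(x) else x^p

#' Fractional-polynomial basis columns
#'
#' For a single power p the column is `x^p` (`log(x)` when p = 0).  A
#' repeated pair (p, p) contributes `x^p` and `x^p * log(x)` (so (0, 0)
#' gives `log(x)` and `log(x)^2`).  The input must already be strictly
#' positive -- use [fp_shift()] first.
#'
#' @param x_shifted strictly positive numeric vector.
#' @param powers numeric vector of length 1 or 2 from the candidate grid.
#' @param shift the shift that was applied (stored as metadata).
#' @return A `covadj_basis` with 1 or 2 columns; `meta$powers` records the
#'   powers.
#' @export
#' @examples
#' fp_basis(exp(1), c(0, 0))$columns  # both columns 1
fp_basis <- function(x_shifted, powers, shift = 0) {
  if (any(!is.finite(x_shifted)) || any(x_shifted <= 0))
    stop("fractional-polynomial input must be strictly positive; ",
         "apply fp_shift() first", call. = FALSE)
  if (!length(powers) %in% 1:2)
    stop("'powers' must have length 1 or 2", call. = FALSE)
  if (length(powers) == 1L) {
    cols <- matrix(fp_term(x_shifted, powers), ncol = 1L)
  } else if (powers[1L] == powers[2L]) {
    t1 <- fp_term(x_shifted, powers[1L])
    cols <- cbind(t1, t1 * log(x_shifted))
  } else {
    cols <- cbind(fp_term(x_shifted, powers[1L]),
                  fp_term(x_shifted, powers[2L]))
  }
  colnames(cols) <- paste0("fp", seq_len(ncol(cols)))
  new_basis(if (length(powers) == 1L) "fp1" else "fp2", cols,
            meta = list(powers = powers), shift = shift)
}

#' Restricted-cubic-spline knot placement
#'
#' Knots at the conventional percentile locations: \{10, 50, 90\} for 3
#' total knots and \{5, 27.5, 50, 72.5, 95\} for 5, computed as
#' interpolated sample percentiles.  The first and last knot act as the
#' boundary pair between which the spline is cubic; beyond them it is
#' linear.
#'
#' @param x numeric vector, length >= 20.
#' @param total_knots 3 or 5 (counting the boundary knots).
#' @return Strictly increasing numeric vector of knot locations.
#' @export
#' @examples
#' rcs_knots(1:100, 3)  # 10.9 50.5 90.1
rcs_knots <- function(x, total_knots) {
  check_covariate(x, min_len = 20L)
  if (!total_knots %in% c(3, 5))
    stop("'total_knots' must be 3 or 5", call. = FALSE)
  probs <- if (total_knots == 3) c(0.10, 0.50, 0.90)
           else c(0.05, 0.275, 0.50, 0.725, 0.95)
  k <- pctl(x, probs)
  if (any(diff(k) <= 0))
    stop("knots are not distinct; too many ties in the covariate",
         call. = FALSE)
  k
}

#' Restricted-cubic-spline basis columns
#'
#' Truncated-power basis of a cubic spline constrained to be linear beyond
#' the boundary knots: the columns are `x` followed by, for each interior
#' knot k_j,
#' `(x - k_j)_+^3 - lambda_j (x - k_min)_+^3 - (1 - lambda_j) (x - k_max)_+^3`
#' with `lambda_j = (k_max - k_j) / (k_max - k_min)` and `(u)_+^3 = u^3` for
#' `u >= 0`, else 0.  The lambda weights make the cubic and quadratic terms
#' cancel beyond `k_max`, which gives the tail linearity.
#'
#' @param x numeric vector (finite).
#' @param knots strictly increasing numeric vector of >= 3 knots; first and
#'   last are the boundary knots.
#' @return A `covadj_basis` with `length(knots) - 1` columns; `meta` stores
#'   `knots` and the `lambda` weights.
#' @export
#' @examples
#' rcs_basis(c(-1, 0.25, 3), c(0, 0.5, 1))$columns
rcs_basis <- function(x, knots) {
  if (any(!is.finite(x)))
    stop("'x' must be finite", call. = FALSE)
  if (length(knots) < 3L || any(diff(knots) <= 0))
    stop("'knots' must be >= 3 strictly increasing values", call. = FALSE)
  k_min <- knots[1L]; k_max <- knots[length(knots)]
  interior <- knots[-c(1L, length(knots))]
  lambda <- (k_max - interior) / (k_max - k_min)
  tp3 <- function(u) ifelse(u >= 0, u^3, 0)
  nl <- vapply(seq_along(interior), function(j) {
    tp3(x - interior[j]) - lambda[j] * tp3(x - k_min) -
      (1 - lambda[j]) * tp3(x - k_max)
  }, numeric(length(x)))
  cols <- cbind(x, matrix(nl, nrow = length(x)))
  colnames(cols) <- c("x", paste0("nl", seq_along(interior)))
  new_basis(if (length(knots) == 3L) "rcs3" else "rcs5", cols,
            meta = list(knots = knots, lambda = lambda))
}

check_covariate <- function(x, min_len) {
  if (!is.numeric(x) || length(x) < min_len)
    stop("covariate must be a numeric vector of length >= ", min_len,
         call. = FALSE)
  if (any(!is.finite(x)))
    stop("covariate contains non-finite values", call. = FALSE)
  invisible(x)
}

## Build the basis for a named method on raw covariate values.
## For fp1/fp2 only the shift is done here; the power search happens in the
## fit (fit_fp), so this returns the shifted data plus candidates.
build_basis <- function(x, method) {
  switch(method,
         dichotomised = dichotomise(x),
         categorised  = categorise(x),
         linear       = linear_basis(x),
         rcs3         = rcs_basis(x, rcs_knots(x, 3)),
         rcs5         = rcs_basis(x, rcs_knots(x, 5)),
         stop("no direct basis for method '", method, "'", call. = FALSE))
}

## Rebuild basis columns for new covariate values from stored metadata
## (used by predict and plot methods).
basis_from_meta <- function(x, method, meta, shift = 0) {
  switch(method,
    unadjusted   = matrix(numeric(length(x)), nrow = length(x), ncol = 0L),
    dichotomised = matrix(as.numeric(x > meta$cutpoints), ncol = 1L),
    categorised  = {
      q <- meta$cutpoints
      cbind(as.numeric(x > q[1L] & x <= q[2L]),
            as.numeric(x > q[2L] & x <= q[3L]),
            as.numeric(x > q[3L]))
    },
    linear = matrix(x, ncol = 1L),
    fp1    = ,
    fp2    = {
      xs <- x + shift
      if (any(xs <= 0))
        stop("new covariate values fall outside the fitted ",
             "fractional-polynomial domain after shifting", call. = FALSE)
      fp_basis(xs, meta$powers, shift)$columns
    },
    rcs3 = ,
    rcs5 = rcs_basis(x, meta$knots)$columns,
    stop("unknown method '", method, "'", call. = FALSE))
}
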