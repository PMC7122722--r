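#' Bounds F-test for a level (cointegrating) relationship
#'
#' Tests the joint null that every lagged-level coefficient of the
#' error-correction regression is zero - the lagged dependent level plus all
#' `k` lagged regressor levels, `k + 1` restrictions in total. The Wald
#' statistic divided by the restriction count is compared with embedded
#' asymptotic bounds (see [bounds_critical_values()]): above the upper I(1)
#' bound the variables are cointegrated; below the lower I(0) bound there is
#' no level relationship; between the bounds the test is inconclusive.
#'
#' @param fit An `ecm_fit` containing all level terms.
#' @param level Significance level for the decision (0.10, 0.05, 0.025, 0.01).
#' @return A `bounds_test`: `statistic` (the F value), `k`, critical bounds,
#'   and `decision`.
#' @export
bounds_f_test <- function(fit, level = 0.05) {
  stopifnot(inherits(fit, "ecm_fit"))
  idx <- fit$level_cols
  if (anyNA(idx)) stop("fit is missing level columns", call. = FALSE)
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx]
  qn <- length(idx)
  Fstat <- drop(t(b) %*% solve(V, b)) / qn
  k <- qn - 1L
  cv <- bounds_critical_values(k, level)
  structure(list(statistic = Fstat, k = k, n_restrictions = qn,
                 level = level, cv = cv,
                 decision = decide_bounds(Fstat, cv[["I0"]], cv[["I1"]]),
                 dependent = fit$spec$dependent,
                 regressors = fit$spec$regressors),
            class = "bounds_test")
}

#' Trichotomous bounds decision
#'
#' @param f F statistic (non-negative).
#' @param cv_lower Lower (I(0)) critical bound.
#' @param cv_upper Upper (I(1)) critical bound; must exceed `cv_lower`.
#' @return `"cointegrated"`, `"inconclusive"` or `"no level relationship"`.
#' @export
decide_bounds <- function(f, cv_lower, cv_upper) {
  if (f < 0) stop("F statistic must be non-negative", call. = FALSE)
  if (cv_lower >= cv_upper) stop("lower bound must be below upper bound", call. = FALSE)
  if (f > cv_upper) "cointegrated"
  else if (f < cv_lower) "no level relationship"
  else "inconclusive"
}

#' @export
print.bounds_test <- function(x, ...) {
  cat(sprintf("Bounds cointegration test: %s = f(%s)\n", x$dependent,
              paste(x$regressors, collapse = ", ")))
  cat(sprintf("  F = %.3f on %d level terms (k = %d); bounds at %g%%: I(0) %.2f, I(1) %.2f\n",
              x$statistic, x$n_restrictions, x$k, 100 * x$level,
              x$cv[["I0"]], x$cv[["I1"]]))
  cat("  decision:", x$decision, "\n")
  invisible(x)
}

#' Bounds-test grid for a model rotation
#'
#' @param fits Named list of `ecm_fit`s, as from [rotate_models()].
#' @param level Significance level.
#' @return Data frame: dependent variable, F, bounds, decision.
#' @export
bounds_table <- function(fits, level = 0.05) {
  rows <- lapply(names(fits), function(v) {
    bt <- bounds_f_test(fits[[v]], level)
    data.frame(dependent = v, F = bt$statistic, k = bt$k,
               I0 = bt$cv[["I0"]], I1 = bt$cv[["I1"]],
               decision = bt$decision)
  })
  do.call(rbind, rows)
}
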