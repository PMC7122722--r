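#' Augmented Dickey-Fuller unit-root test
#'
#' Fits the auxiliary regression
#' `dx_t = a0 (+ a1 t) + lambda x_{t-1} + sum_{i=1..m} phi_i dx_{t-i} + u_t`
#' by least squares for every lag augmentation `m` in `0..max_lag`, selects
#' `m` by the Schwarz information criterion on a common estimation sample,
#' refits at the chosen `m` on the longest available sample, and reports the
#' t-ratio of `lambda` against embedded finite-sample Dickey-Fuller critical
#' values. The null hypothesis is a unit root (`lambda = 0`); the series is
#' called stationary when the statistic falls below the left-tail critical
#' value at `level`.
#'
#' @param x Numeric series.
#' @param type Deterministic terms: `"trend"` (constant + trend, the usual
#'   choice in levels), `"drift"` (constant only, the usual choice for
#'   differences), or `"none"`.
#' @param max_lag Largest lag augmentation tried; default
#'   `floor(12 * (n/100)^0.25)`.
#' @param lags Optional fixed lag order, bypassing the SIC search.
#' @param level Decision significance level: 0.01, 0.05 or 0.10.
#' @return A `unit_root_test` object: statistic, selected lags, auxiliary
#'   regression coefficients, critical values, and the stationarity decision.
#' @seealso [pp_test()], [integration_order()]
#' @export
adf_test <- function(x, type = c("trend", "drift", "none"),
                     max_lag = NULL, lags = NULL, level = 0.05) {
  type <- match.arg(type)
  x <- as.numeric(x)
  n <- length(x)
  if (stats::sd(x) == 0) stop("constant series: unit-root test undefined", call. = FALSE)
  if (is.null(max_lag)) max_lag <- floor(12 * (n / 100)^0.25)
  if (!is.null(lags)) max_lag <- lags
  if (n <= max_lag + 10) stop("series too short for requested lag order", call. = FALSE)

  if (is.null(lags)) {
    # SIC over a common sample so criteria are comparable across m
    sic <- vapply(0:max_lag, function(m) {
      f <- df_regression(x, type, m, start = max_lag + 2L)
      ne <- length(f$residuals)
      ne * log(sum(f$residuals^2) / ne) + ncol(f$X) * log(ne)
    }, numeric(1))
    m_sel <- (0:max_lag)[which.min(sic)]
  } else {
    m_sel <- lags
  }
  fit <- df_regression(x, type, m_sel, start = m_sel + 2L)
  stat <- fit$t_lambda
  n_eff <- length(fit$residuals)
  cv <- df_critical_values(type, n_eff)
  decision <- unit_root_decision(stat, cv, level)
  structure(list(test = "ADF", type = type, statistic = stat,
                 lags = m_sel, coefficients = fit$coefficients,
                 se = fit$se, n_effective = n_eff,
                 critical_values = cv, level = level, decision = decision),
            class = "unit_root_test")
}

# Dickey-Fuller auxiliary regression with m lagged differences.
# start: first usable t index (1-based) for dx; allows a common sample.
df_regression <- function(x, type, m, start) {
  n <- length(x)
  dx <- diff(x)
  t_idx <- start:n                       # time indices of the dependent dx_t
  y <- dx[t_idx - 1L]
  X <- cbind(lag_level = x[t_idx - 1L])
  if (m > 0) {
    for (i in seq_len(m)) {
      X <- cbind(X, dx[t_idx - 1L - i])
      colnames(X)[ncol(X)] <- paste0("lag_diff", i)
    }
  }
  if (type %in% c("drift", "trend")) X <- cbind(`(Intercept)` = 1, X)
  if (type == "trend") X <- cbind(X, trend = t_idx)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("singular Dickey-Fuller regression", call. = FALSE)
  b <- qr.coef(qr_x, y)
  res <- y - drop(X %*% b)
  s2 <- sum(res^2) / (length(y) - ncol(X))
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(s2 * diag(XtX_inv))
  names(se) <- colnames(X)
  list(coefficients = b, se = se, residuals = res, X = X, y = y,
       t_lambda = b[["lag_level"]] / se[["lag_level"]],
       se_lambda = se[["lag_level"]])
}

unit_root_decision <- function(stat, cv, level) {
  key <- c("0.01" = "1%", "0.05" = "5%", "0.1" = "10%")[as.character(level)]
  if (is.na(key)) stop("'level' must be 0.01, 0.05 or 0.10", call. = FALSE)
  if (stat < cv[[key]]) "stationary" else "nonstationary"
}

#' Phillips-Perron unit-root test
#'
#' Runs the Dickey-Fuller regression without lagged-difference augmentation
#' and corrects the t-ratio nonparametrically for residual serial correlation
#' using a Bartlett-kernel long-run variance with bandwidth
#' `floor(4 * (n/100)^(2/9))`. Shares the Dickey-Fuller critical values.
#'
#' @inheritParams adf_test
#' @param bandwidth Optional kernel truncation lag override.
#' @return A `unit_root_test` object (field `lags` holds the bandwidth).
#' @export
pp_test <- function(x, type = c("trend", "drift", "none"),
                    bandwidth = NULL, level = 0.05) {
  type <- match.arg(type)
  x <- as.numeric(x)
  n <- length(x)
  if (stats::sd(x) == 0) stop("constant series: unit-root test undefined", call. = FALSE)
  if (n <= 12) stop("series too short", call. = FALSE)
  fit <- df_regression(x, type, m = 0L, start = 2L)
  u <- fit$residuals
  Tn <- length(u)
  if (is.null(bandwidth)) bandwidth <- floor(4 * (Tn / 100)^(2 / 9))
  gamma <- vapply(0:bandwidth, function(j) {
    sum(u[(j + 1):Tn] * u[1:(Tn - j)]) / Tn
  }, numeric(1))
  lam2 <- gamma[1]
  if (bandwidth > 0) {
    w <- 1 - (1:bandwidth) / (bandwidth + 1)
    lam2 <- lam2 + 2 * sum(w * gamma[-1])
  }
  s <- sqrt(sum(u^2) / (Tn - length(fit$coefficients)))
  t_raw <- fit$t_lambda
  # Z_t correction (Bartlett long-run variance lam2, short-run variance gamma0)
  stat <- sqrt(gamma[1] / lam2) * t_raw -
    (lam2 - gamma[1]) * Tn * fit$se_lambda / (2 * sqrt(lam2) * s)
  cv <- df_critical_values(type, Tn)
  decision <- unit_root_decision(stat, cv, level)
  structure(list(test = "PP", type = type, statistic = stat,
                 lags = bandwidth, coefficients = fit$coefficients,
                 se = fit$se, n_effective = Tn,
                 critical_values = cv, level = level, decision = decision),
            class = "unit_root_test")
}

#' @export
print.unit_root_test <- function(x, ...) {
  cat(sprintf("%s unit-root test (%s): statistic %.3f, %s at %g%% (lags/bw %d)\n",
              x$test, x$type, x$statistic, x$decision, 100 * x$level, x$lags))
  cat("  critical values:",
      paste(sprintf("%s %.3f", names(x$critical_values), x$critical_values),
            collapse = ", "), "\n")
  invisible(x)
}

#' Integration order from level and difference test results
#'
#' Combines unit-root results on the level, first difference and second
#' difference of one variable into an integration order `d`: the smallest
#' order of differencing at which the series is judged stationary. `d = 2`
#' raises a flag because bounds cointegration testing requires variables to
#' be I(0) or I(1) but not I(2).
#'
#' @param level_result,diff1_result,diff2_result `unit_root_test` objects for
#'   the same variable and test at differencing orders 0, 1, 2.
#' @return List with `order` (0, 1 or 2) and `i2_flag`.
#' @export
classify_integration_order <- function(level_result, diff1_result, diff2_result) {
  res <- list(level_result, diff1_result, diff2_result)
  stopifnot(all(vapply(res, inherits, logical(1), "unit_root_test")))
  tests <- unique(vapply(res, `[[`, character(1), "test"))
  if (length(tests) != 1) {
    stop("all three results must come from the same test", call. = FALSE)
  }
  d <- which(vapply(res, `[[`, character(1), "decision") == "stationary")[1] - 1L
  if (is.na(d)) stop("series not stationary after two differences: order > 2",
                     call. = FALSE)
  list(order = d, i2_flag = d == 2L)
}

#' Classify a series' integration order directly
#'
#' Convenience wrapper running [adf_test()] or [pp_test()] on the level
#' (constant + trend) and on first and second differences (constant only),
#' then applying [classify_integration_order()].
#'
#' @param x Numeric series.
#' @param test `"adf"` or `"pp"`.
#' @param level Decision significance level.
#' @param ... Passed to the underlying test.
#' @return List with `order`, `i2_flag` and the three `unit_root_test`s.
#' @export
integration_order <- function(x, test = c("adf", "pp"), level = 0.05, ...) {
  test <- match.arg(test)
  f <- if (test == "adf") adf_test else pp_test
  r0 <- f(x, type = "trend", level = level, ...)
  r1 <- f(difference(x, 1), type = "drift", level = level, ...)
  r2 <- f(difference(x, 2), type = "drift", level = level, ...)
  out <- classify_integration_order(r0, r1, r2)
  c(out, list(level = r0, diff1 = r1, diff2 = r2))
}

#' Unit-root summary grid for a dataset
#'
#' Runs ADF and PP tests on the level and first difference of every variable,
#' producing the standard variables-by-test summary grid.
#'
#' @param ds A `fire_ts`.
#' @param level Decision significance level.
#' @return Data frame with one row per variable: level and first-difference
#'   statistics for both tests, and the implied integration order per test.
#' @export
unit_root_table <- function(ds, level = 0.05) {
  stopifnot(inherits(ds, "fire_ts"))
  vars <- setdiff(names(ds), "date")
  rows <- lapply(vars, function(v) {
    x <- ds[[v]]
    res <- lapply(c("adf", "pp"), function(tst) integration_order(x, tst, level))
    data.frame(variable = v,
               adf_level = res[[1]]$level$statistic,
               adf_diff1 = res[[1]]$diff1$statistic,
               pp_level = res[[2]]$level$statistic,
               pp_diff1 = res[[2]]$diff1$statistic,
               adf_order = res[[1]]$order, pp_order = res[[2]]$order,
               i2_flag = res[[1]]$i2_flag || res[[2]]$i2_flag)
  })
  do.call(rbind, rows)
}
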