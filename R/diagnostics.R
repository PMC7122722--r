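#' Durbin-Watson statistic
#'
#' `sum((e_t - e_{t-1})^2) / sum(e_t^2)`; values near 2 indicate no first-order
#' residual autocorrelation.
#'
#' @param residuals Numeric residual vector (length >= 2, not all zero).
#' @return The statistic, in `[0, 4]`.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("need at least 2 residuals", call. = FALSE)
  if (all(residuals == 0)) stop("all-zero residuals", call. = FALSE)
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' ARCH LM test for conditional heteroskedasticity
#'
#' Regresses squared residuals on their own lags; the statistic is the
#' auxiliary sample size times R-squared, asymptotically chi-square with
#' `lags` degrees of freedom under the homoskedastic null.
#'
#' @param residuals Residual vector.
#' @param lags Number of lags of the squared residual (default 1).
#' @return List: `statistic`, `p.value`, `lags`.
#' @export
arch_lm <- function(residuals, lags = 1) {
  if (lags < 1) stop("'lags' must be at least 1", call. = FALSE)
  n <- length(residuals)
  if (n <= lags + 2) stop("too few residuals for requested lags", call. = FALSE)
  e2 <- residuals^2
  y <- e2[(lags + 1):n]
  X <- cbind(1, sapply(seq_len(lags), function(j) e2[(lags + 1 - j):(n - j)]))
  r2 <- aux_r_squared(y, X)
  stat <- length(y) * r2
  list(statistic = stat, p.value = stats::pchisq(stat, lags, lower.tail = FALSE),
       lags = lags)
}

# R-squared of an auxiliary least-squares regression (with intercept column)
aux_r_squared <- function(y, X) {
  qr_x <- qr(X)
  res <- y - drop(X %*% qr.coef(qr_x, y))
  res[is.na(res)] <- 0
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("degenerate auxiliary regression (constant response)", call. = FALSE)
  1 - sum(res^2) / tss
}

#' Breusch-Godfrey test for residual autocorrelation
#'
#' Auxiliary regression of the fit's residuals on the original design plus
#' `lags` lagged residuals (zero-padded at the start). The statistic is
#' `(T - lags) * R^2`, asymptotically chi-square with `lags` degrees of
#' freedom under the no-autocorrelation null.
#'
#' @param fit An `ecm_fit` (anything with `$residuals` and `$X`).
#' @param lags Number of residual lags (>= 1).
#' @return List: `statistic`, `p.value`, `lags`.
#' @export
breusch_godfrey <- function(fit, lags = 1) {
  if (lags < 1) stop("'lags' must be at least 1", call. = FALSE)
  e <- fit$residuals
  n <- length(e)
  E <- sapply(seq_len(lags), function(j) c(rep(0, j), e[seq_len(n - j)]))
  r2 <- aux_r_squared(e, cbind(fit$X, E))
  stat <- (n - lags) * r2
  list(statistic = stat, p.value = stats::pchisq(stat, lags, lower.tail = FALSE),
       lags = lags)
}

#' Ramsey RESET test for functional form
#'
#' F-test of adding powers of the fitted values to the original regression; a
#' significant statistic indicates neglected nonlinearity.
#'
#' @param fit An `ecm_fit`.
#' @param powers Powers of the fitted values added (default 2 and 3).
#' @return List: `statistic` (F), `p.value`, `df1`, `df2`.
#' @export
ramsey_reset <- function(fit, powers = 2:3) {
  f <- fit$fitted
  if (stats::sd(f) == 0) stop("constant fitted values", call. = FALSE)
  # scale to unit sd so high powers stay numerically tame
  fs <- f / stats::sd(f)
  Z <- sapply(powers, function(p) fs^p)
  X_u <- cbind(fit$X, Z)
  y <- fit$y
  ssr_r <- fit$ssr
  qr_u <- qr(X_u)
  res_u <- y - drop(X_u %*% qr.coef(qr_u, y))
  res_u[is.na(res_u)] <- 0
  ssr_u <- sum(res_u^2)
  m <- length(powers)
  df2 <- length(y) - qr_u$rank
  stat <- ((ssr_r - ssr_u) / m) / (ssr_u / df2)
  list(statistic = stat,
       p.value = stats::pf(stat, m, df2, lower.tail = FALSE),
       df1 = m, df2 = df2)
}

#' Jarque-Bera normality test
#'
#' `(n/6) (S^2 + (K - 3)^2 / 4)` from sample skewness `S` and kurtosis `K`,
#' compared with chi-square on 2 degrees of freedom.
#'
#' @param x Numeric vector (length >= 8, non-degenerate).
#' @return List: `statistic`, `p.value`, `skewness`, `kurtosis`.
#' @export
jarque_bera <- function(x) {
  n <- length(x)
  if (n < 8) stop("need at least 8 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance", call. = FALSE)
  m <- x - mean(x)
  m2 <- mean(m^2); m3 <- mean(m^3); m4 <- mean(m^4)
  S <- m3 / m2^1.5
  K <- m4 / m2^2
  stat <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = stat, p.value = stats::pchisq(stat, 2, lower.tail = FALSE),
       skewness = S, kurtosis = K)
}

#' Seasonal correlations between burned area and its drivers
#'
#' Pools the months of each season group (default FMA = Feb/Mar/Apr,
#' MJJ = May/Jun/Jul, ASO = Aug/Sep/Oct, bracketing the spring and autumn fire
#' seasons) across all years and reports the Pearson correlation of the
#' response with every other variable, with two-sided t-based p-values from
#' [stats::cor.test()].
#'
#' @param ds A `fire_ts`.
#' @param groups Named list of month-number triplets.
#' @param response Response variable (default `"area_burned"`).
#' @param scale `"raw"` back-transforms logged series before correlating;
#'   `"as_is"` uses the stored values.
#' @return Data frame: group, variable, `r`, `p`, `n`. Zero-variance
#'   variables yield `NA` correlations.
#' @export
seasonal_correlations <- function(ds,
                                  groups = list(FMA = 2:4, MJJ = 5:7, ASO = 8:10),
                                  response = "area_burned",
                                  scale = c("raw", "as_is")) {
  stopifnot(inherits(ds, "fire_ts"))
  scale <- match.arg(scale)
  if (scale == "raw") ds <- unlog_transform(ds)
  vars <- setdiff(names(ds), c("date", response))
  mo <- as.integer(format(ds$date, "%m"))
  rows <- list()
  for (g in names(groups)) {
    sel <- mo %in% groups[[g]]
    if (sum(sel) < 3) stop("fewer than 3 observations in group ", g, call. = FALSE)
    yv <- ds[[response]][sel]
    for (v in vars) {
      xv <- ds[[v]][sel]
      if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
        rows[[length(rows) + 1]] <- data.frame(group = g, variable = v,
                                               r = NA_real_, p = NA_real_,
                                               n = sum(sel))
      } else {
        ct <- stats::cor.test(yv, xv)
        rows[[length(rows) + 1]] <- data.frame(group = g, variable = v,
                                               r = unname(ct$estimate),
                                               p = ct$p.value, n = sum(sel))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full diagnostics report for an error-correction fit
#'
#' Bundles the residual tests (Durbin-Watson, ARCH LM, Breusch-Godfrey,
#' Ramsey RESET, Jarque-Bera) and the CUSUM / CUSUMSQ stability paths.
#'
#' @param fit An `ecm_fit`.
#' @param lags Lag count for the ARCH and Breusch-Godfrey tests (default 1).
#' @param powers Fitted-value powers for the RESET test.
#' @return A `diagnostics_report` list.
#' @export
diagnostics_report <- function(fit, lags = 1, powers = 2:3) {
  e <- fit$residuals
  structure(list(
    dw = durbin_watson(e),
    arch = arch_lm(e, lags),
    bg = breusch_godfrey(fit, lags),
    reset = ramsey_reset(fit, powers),
    jb = jarque_bera(e),
    cusum = cusum_test(fit)
  ), class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Residual diagnostics:\n")
  cat(sprintf("  Durbin-Watson          %.3f\n", x$dw))
  cat(sprintf("  ARCH LM (%d lag)        stat %.3f  p %.3f\n",
              x$arch$lags, x$arch$statistic, x$arch$p.value))
  cat(sprintf("  Breusch-Godfrey (%d)    stat %.3f  p %.3f\n",
              x$bg$lags, x$bg$statistic, x$bg$p.value))
  cat(sprintf("  Ramsey RESET           F %.3f  p %.3f\n",
              x$reset$statistic, x$reset$p.value))
  cat(sprintf("  Jarque-Bera            stat %.3f  p %.3f\n",
              x$jb$statistic, x$jb$p.value))
  cat(sprintf("  CUSUM within 5%% bounds: %s; CUSUMSQ: %s\n",
              x$cusum$cusum_within, x$cusum$cusumsq_within))
  invisible(x)
}
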