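#' Specify an ARDL model in error-correction form
#'
#' The estimated regression is
#' \deqn{\Delta y_t = \alpha_0 + \theta_0 y_{t-1} + \sum_k \theta_k x_{k,t-1}
#'   + \sum_{i=1}^{p} \alpha_i \Delta y_{t-i}
#'   + \sum_k \sum_{j=0}^{q_k} \beta_{k,j} \Delta x_{k,t-j} + \varepsilon_t}
#' so the lagged levels carry the long-run (cointegrating) relation and the
#' differences carry the short-run dynamics. `p` counts lagged differences of
#' the dependent variable; `q_k` counts lagged differences of regressor `k`
#' beyond the contemporaneous one (`q_k = 0` keeps only `dx_{k,t}`).
#'
#' The default order pattern mirrors the ARDL(1,1,1,1,1,0,1) structure chosen
#' by Schwarz criterion for the burned-area model: one lag everywhere except
#' sunlight at zero.
#'
#' @param dependent Name of the dependent variable.
#' @param regressors Character vector of regressor names (order preserved).
#' @param p Number of lagged `dy` terms (>= 1... the lagged level `y_{t-1}` is
#'   always present; `p` controls only the `dy_{t-i}` terms, and `p = 0` drops
#'   them).
#' @param q Scalar or named vector of per-regressor difference lag orders in
#'   `{0, 1, 2, ...}`; unnamed scalar is recycled.
#' @param constant Include an intercept (default `TRUE`).
#' @return An `ecm_spec` object.
#' @export
ecm_spec <- function(dependent = "area_burned",
                     regressors = c("cem", "rel_humidity", "t_min", "t_max",
                                    "precip", "sunlight", "wind"),
                     p = 1,
                     q = c(cem = 1, rel_humidity = 1, t_min = 1, t_max = 1,
                           precip = 1, sunlight = 0, wind = 1),
                     constant = TRUE) {
  if (p < 0) stop("'p' must be non-negative", call. = FALSE)
  if (dependent %in% regressors) {
    stop("dependent variable also listed as regressor", call. = FALSE)
  }
  if (anyDuplicated(regressors)) stop("duplicated regressor names", call. = FALSE)
  if (is.null(names(q))) {
    q <- stats::setNames(rep_len(q, length(regressors)), regressors)
  } else {
    qq <- stats::setNames(rep(1L, length(regressors)), regressors)
    hit <- intersect(names(q), regressors)
    qq[hit] <- q[hit]
    q <- qq
  }
  if (any(q < 0)) stop("'q' orders must be non-negative", call. = FALSE)
  structure(list(dependent = dependent, regressors = regressors,
                 p = as.integer(p),
                 q = stats::setNames(as.integer(q), names(q)),
                 constant = constant),
            class = "ecm_spec")
}

#' Build the error-correction design matrix
#'
#' Constructs the response `dy_t` and the regressor matrix with columns
#' ordered: intercept, lagged level of the dependent (`L.y`), lagged levels of
#' each regressor (`L.x`), lagged differences of the dependent (`LD.y`, ...),
#' then per regressor the contemporaneous difference (`D.x`) and its lags
#' (`LD.x`, `L2D.x`, ...). Rows whose lags are undefined are dropped.
#'
#' @param ds A `fire_ts` whose series are on the analysis (log) scale.
#' @param spec An [ecm_spec()].
#' @return List with `y`, `X`, `level_cols` (indices of the lagged-level
#'   columns, dependent first), `rows` (time indices used), and `n_lost`.
#' @export
build_ecm_design <- function(ds, spec) {
  stopifnot(inherits(ds, "fire_ts"), inherits(spec, "ecm_spec"))
  vars <- c(spec$dependent, spec$regressors)
  missing_v <- setdiff(vars, names(ds))
  if (length(missing_v)) {
    stop("variable(s) not in dataset: ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(ds)
  y <- ds[[spec$dependent]]
  maxdepth <- max(1L + spec$p, if (length(spec$q)) 1L + max(spec$q) else 1L)
  t_idx <- (maxdepth + 1L):n
  if (length(t_idx) < length(vars) * 2L + 5L) {
    stop("too few observations for the requested lag structure", call. = FALSE)
  }
  dy <- diff(y)
  resp <- dy[t_idx - 1L]

  cols <- list()
  if (spec$constant) cols[["(Intercept)"]] <- rep(1, length(t_idx))
  cols[[paste0("L.", spec$dependent)]] <- y[t_idx - 1L]
  for (v in spec$regressors) cols[[paste0("L.", v)]] <- ds[[v]][t_idx - 1L]
  if (spec$p > 0) {
    for (i in seq_len(spec$p)) {
      nm <- if (i == 1) paste0("LD.", spec$dependent)
            else paste0("L", i, "D.", spec$dependent)
      cols[[nm]] <- dy[t_idx - 1L - i]
    }
  }
  for (v in spec$regressors) {
    dx <- diff(ds[[v]])
    for (j in 0:spec$q[[v]]) {
      nm <- if (j == 0) paste0("D.", v)
            else if (j == 1) paste0("LD.", v)
            else paste0("L", j, "D.", v)
      cols[[nm]] <- dx[t_idx - 1L - j]
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  level_cols <- match(paste0("L.", vars), colnames(X))
  list(y = resp, X = X, level_cols = level_cols, rows = t_idx,
       n_lost = maxdepth, dates = ds$date[t_idx])
}

#' Fit the ARDL error-correction regression
#'
#' Least-squares estimation of the design from [build_ecm_design()], with
#' coefficient covariance `s^2 (X'X)^{-1}` where `s^2` uses the
#' degrees-of-freedom denominator `n - n_par`.
#'
#' @inheritParams build_ecm_design
#' @return An `ecm_fit`: coefficients, covariance, residuals, fitted values,
#'   `r.squared`, `adj.r.squared`, `ssr`, Durbin-Watson statistic, the design,
#'   and bookkeeping needed by the bounds test and simulator.
#' @export
fit_ecm <- function(ds, spec) {
  d <- build_ecm_design(ds, spec)
  qr_x <- qr(d$X)
  if (qr_x$rank < ncol(d$X)) {
    drop_cols <- colnames(d$X)[qr_x$pivot[(qr_x$rank + 1):ncol(d$X)]]
    stop("rank-deficient design; dependent column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  b <- qr.coef(qr_x, d$y)
  fitted <- drop(d$X %*% b)
  res <- d$y - fitted
  n <- length(d$y)
  n_par <- ncol(d$X)
  ssr <- sum(res^2)
  s2 <- ssr / (n - n_par)
  R_inv <- chol2inv(qr.R(qr_x))
  # undo the QR pivot so the covariance matches coefficient order
  piv <- qr_x$pivot
  V <- matrix(0, n_par, n_par, dimnames = list(colnames(d$X), colnames(d$X)))
  V[piv, piv] <- s2 * R_inv
  tss <- sum((d$y - mean(d$y))^2)
  r2 <- 1 - ssr / tss
  structure(list(spec = spec, coefficients = b, vcov = V,
                 residuals = res, fitted = fitted, y = d$y, X = d$X,
                 level_cols = d$level_cols, dates = d$dates,
                 n = n, n_par = n_par, df_residual = n - n_par,
                 sigma2 = s2, ssr = ssr, r.squared = r2,
                 adj.r.squared = 1 - (1 - r2) * (n - 1) / (n - n_par),
                 dw = durbin_watson(res)),
            class = "ecm_fit")
}

#' @export
print.ecm_fit <- function(x, ...) {
  cat(sprintf("ARDL error-correction fit: d(%s) on %d terms, n = %d\n",
              x$spec$dependent, x$n_par, x$n))
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$coefficients, se = se,
                    t = x$coefficients / se)
  tab$p <- 2 * stats::pt(-abs(tab$t), df = x$df_residual)
  print(round(tab, 4))
  cat(sprintf("R2 %.3f  adj-R2 %.3f  SSR %.4g  DW %.3f\n",
              x$r.squared, x$adj.r.squared, x$ssr, x$dw))
  invisible(x)
}

#' @export
vcov.ecm_fit <- function(object, ...) object$vcov

#' @export
coef.ecm_fit <- function(object, ...) object$coefficients

#' @export
residuals.ecm_fit <- function(object, ...) object$residuals

#' @export
fitted.ecm_fit <- function(object, ...) object$fitted

#' Long-run elasticities from an error-correction fit
#'
#' Each long-run elasticity is `-theta_k / theta_0`, the ratio of a lagged
#' regressor level coefficient to the lagged dependent level coefficient.
#' Standard errors come from the delta method on the corresponding 2x2 block
#' of the coefficient covariance; p-values are two-sided normal. `theta_0 >=
#' 0` means no error correction: results are flagged and still reported.
#'
#' @param fit An `ecm_fit`.
#' @return A `longrun_result` data frame: one row per regressor with
#'   `elasticity`, `se`, `z`, `p`, plus fit statistics and the
#'   `no_error_correction` flag as attributes.
#' @export
long_run_coefficients <- function(fit) {
  stopifnot(inherits(fit, "ecm_fit"))
  b <- fit$coefficients
  theta0_name <- paste0("L.", fit$spec$dependent)
  theta0 <- b[[theta0_name]]
  flag <- theta0 >= 0
  if (flag) warning("theta0 >= 0: no error correction; elasticities unreliable",
                    call. = FALSE)
  rows <- lapply(fit$spec$regressors, function(v) {
    nm <- paste0("L.", v)
    thk <- b[[nm]]
    el <- if (thk == 0) 0 else -thk / theta0
    g <- c(thk / theta0^2, -1 / theta0)        # d(-thk/th0)/d(th0, thk)
    Vb <- fit$vcov[c(theta0_name, nm), c(theta0_name, nm)]
    se <- sqrt(drop(t(g) %*% Vb %*% g))
    z <- el / se
    data.frame(regressor = v, elasticity = el, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("longrun_result", "data.frame"),
            theta0 = theta0, no_error_correction = flag,
            r.squared = fit$r.squared, adj.r.squared = fit$adj.r.squared,
            ssr = fit$ssr, dw = fit$dw)
}

#' @export
print.longrun_result <- function(x, ...) {
  cat("Long-run elasticities (-theta_k / theta_0):\n")
  print.data.frame(cbind(x[1], round(x[-1], 4)), row.names = FALSE)
  cat(sprintf("theta0 = %.4f%s | R2 %.3f adj-R2 %.3f SSR %.4g DW %.3f\n",
              attr(x, "theta0"),
              if (attr(x, "no_error_correction")) " [no error correction!]" else "",
              attr(x, "r.squared"), attr(x, "adj.r.squared"),
              attr(x, "ssr"), attr(x, "dw")))
  invisible(x)
}

#' Short-run coefficients and the error-correction term
#'
#' Reports every first-difference coefficient of the fit together with the
#' error-correction term ECM(-1): the coefficient on the lagged level of the
#' dependent variable, which after reparameterization is the loading on the
#' lagged equilibrium deviation. A converging model has ECM(-1) in `(-2, 0)`
#' (monotone convergence in `(-1, 0)`); values outside flag instability.
#'
#' @param fit An `ecm_fit`.
#' @return A `shortrun_result` data frame (term, estimate, se, t, p) with the
#'   stability flag as attribute `"stable"`.
#' @export
short_run_coefficients <- function(fit) {
  stopifnot(inherits(fit, "ecm_fit"))
  b <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  keep <- grepl("^(L?[0-9]*D)\\.", names(b))
  terms <- names(b)[keep]
  ect_name <- paste0("L.", fit$spec$dependent)
  tab <- data.frame(term = c(terms, "ECM(-1)"),
                    estimate = c(b[terms], b[[ect_name]]),
                    se = c(se[terms], se[[ect_name]]))
  tab$t <- tab$estimate / tab$se
  tab$p <- 2 * stats::pt(-abs(tab$t), df = fit$df_residual)
  rownames(tab) <- NULL
  ect <- b[[ect_name]]
  structure(tab, class = c("shortrun_result", "data.frame"),
            ect = ect, stable = ect > -2 && ect < 0,
            r.squared = fit$r.squared, adj.r.squared = fit$adj.r.squared,
            ssr = fit$ssr, dw = fit$dw)
}

#' @export
print.shortrun_result <- function(x, ...) {
  cat("Short-run (error-correction representation):\n")
  print.data.frame(cbind(x[1], round(x[-1], 4)), row.names = FALSE)
  if (!attr(x, "stable")) cat("warning: ECM(-1) outside (-2, 0) - unstable\n")
  invisible(x)
}

#' Fit the model rotation: each variable as dependent
#'
#' Re-estimates the error-correction regression once per variable, with the
#' remaining variables as regressors, producing the eight conceptual models
#' whose bounds F statistics populate the cointegration summary.
#'
#' @param ds A `fire_ts`.
#' @param variables Variables to rotate over (default all series).
#' @param p,q,constant Passed to [ecm_spec()]; `q` entries are matched by
#'   regressor name, missing names default to 1.
#' @return Named list of `ecm_fit` objects, one per dependent variable.
#' @export
rotate_models <- function(ds, variables = NULL, p = 1, q = 1, constant = TRUE) {
  stopifnot(inherits(ds, "fire_ts"))
  vars <- if (is.null(variables)) setdiff(names(ds), "date") else variables
  fits <- lapply(vars, function(dep) {
    fit_ecm(ds, ecm_spec(dependent = dep, regressors = setdiff(vars, dep),
                         p = p, q = q, constant = constant))
  })
  stats::setNames(fits, vars)
}
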