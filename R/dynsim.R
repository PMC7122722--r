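#' Define a counterfactual shock scenario
#'
#' Describes the experiment run by [simulate_response()]: hold every regressor
#' at its sample mean, let the system settle over a burn-in, then apply a
#' permanent step increase to one regressor and trace the distribution of the
#' dependent variable's response.
#'
#' @param variable Regressor to shock.
#' @param size Shock magnitude (default +1).
#' @param size_unit `"sd"` (multiples of the regressor's sample standard
#'   deviation, the usual "one standard deviation increment") or `"log"`
#'   (absolute log units).
#' @param shock_time Period (after burn-in) at which the shock starts; must
#'   not exceed `horizon`.
#' @param horizon Number of post-burn-in periods simulated.
#' @param burn_in Settling-in periods before the shock clock starts.
#' @param n_sims Number of parameter draws (>= 100).
#' @param mode `"expected"` (no residual noise injected; the long-run
#'   convergence algebra is exact) or `"predicted"` (adds regression noise
#'   each period).
#' @param seed Integer seed; fully determines the simulation.
#' @return A `shock_scenario` list.
#' @export
shock_scenario <- function(variable, size = 1, size_unit = c("sd", "log"),
                           shock_time = 10, horizon = 20, burn_in = 20,
                           n_sims = 5000, mode = c("expected", "predicted"),
                           seed = 1) {
  size_unit <- match.arg(size_unit)
  mode <- match.arg(mode)
  if (n_sims < 100) stop("'n_sims' must be at least 100", call. = FALSE)
  if (shock_time < 1 || shock_time > horizon) {
    stop("'shock_time' must lie in 1..horizon", call. = FALSE)
  }
  structure(list(variable = variable, size = size, size_unit = size_unit,
                 shock_time = shock_time, horizon = horizon,
                 burn_in = burn_in, n_sims = n_sims, mode = mode,
                 seed = seed),
            class = "shock_scenario")
}

#' Stochastic response simulation of a fitted error-correction model
#'
#' Draws `n_sims` coefficient vectors from `MVN(b, V)` using the fitted
#' coefficients and covariance, and for each draw iterates the
#' error-correction recursion with all regressors pinned at their sample
#' means: the system starts at that draw's equilibrium, runs through the
#' burn-in, receives a permanent step shift of the scenario size on the
#' shocked regressor, and continues to the horizon. Draws whose lagged-level
#' coefficient on the dependent variable is non-negative cannot converge;
#' they are excluded from the bands and the exclusion rate is reported.
#'
#' @param fit An `ecm_fit`.
#' @param ds The `fire_ts` the model was fitted on (supplies regressor means
#'   and standard deviations on the analysis scale).
#' @param scenario A [shock_scenario()].
#' @return An `ardl_sim`: `paths` (kept draws x periods matrix of dependent
#'   levels), `bands` (per-period mean and 75/90/95% intervals),
#'   `exclusion_rate`, `shock_period`, and the scenario.
#' @export
simulate_response <- function(fit, ds, scenario) {
  stopifnot(inherits(fit, "ecm_fit"), inherits(scenario, "shock_scenario"))
  spec <- fit$spec
  if (!scenario$variable %in% spec$regressors) {
    stop("shocked variable is not a regressor of the fit", call. = FALSE)
  }
  V <- fit$vcov
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  psd_repaired <- FALSE
  if (min(ev) < -1e-8 * max(abs(ev))) {
    e <- eigen(V, symmetric = TRUE)
    V <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
    dimnames(V) <- dimnames(fit$vcov)
    psd_repaired <- TRUE
  }
  set.seed(scenario$seed)
  B <- MASS::mvrnorm(scenario$n_sims, fit$coefficients, V)
  colnames(B) <- names(fit$coefficients)

  th0 <- B[, paste0("L.", spec$dependent)]
  keep <- th0 < 0
  excl_rate <- mean(!keep)
  if (!any(keep)) stop("all draws divergent (theta0 >= 0)", call. = FALSE)
  B <- B[keep, , drop = FALSE]
  th0 <- th0[keep]
  ns <- nrow(B)

  # regressor paths: pinned at sample means, permanent step on the shocked one
  P <- scenario$burn_in + scenario$horizon
  shock_period <- scenario$burn_in + scenario$shock_time
  xbar <- vapply(spec$regressors, function(v) mean(ds[[v]]), numeric(1))
  size_log <- if (scenario$size_unit == "sd") {
    scenario$size * stats::sd(ds[[scenario$variable]])
  } else scenario$size
  Xlev <- matrix(rep(xbar, each = P), P, length(xbar),
                 dimnames = list(NULL, spec$regressors))
  Xlev[shock_period:P, scenario$variable] <-
    Xlev[shock_period:P, scenario$variable] + size_log
  Xlag <- rbind(Xlev[1, ], Xlev[-P, , drop = FALSE])        # x_{t-1}, x_0 = x_1
  dX <- Xlev - Xlag

  a0 <- if (spec$constant) B[, "(Intercept)"] else rep(0, ns)
  TH <- B[, paste0("L.", spec$regressors), drop = FALSE]
  lev_contrib <- TH %*% t(Xlag)                             # ns x P

  diff_contrib <- matrix(0, ns, P)
  for (v in spec$regressors) {
    for (j in 0:spec$q[[v]]) {
      nm <- if (j == 0) paste0("D.", v)
            else if (j == 1) paste0("LD.", v)
            else paste0("L", j, "D.", v)
      dxj <- c(rep(0, j), dX[seq_len(P - j), v])            # dx_{v, t-j}
      diff_contrib <- diff_contrib + outer(B[, nm], dxj)
    }
  }

  AL <- if (spec$p > 0) {
    nms <- vapply(seq_len(spec$p), function(i) {
      if (i == 1) paste0("LD.", spec$dependent)
      else paste0("L", i, "D.", spec$dependent)
    }, character(1))
    B[, nms, drop = FALSE]
  } else NULL

  eps <- if (scenario$mode == "predicted") {
    matrix(stats::rnorm(ns * P, sd = sqrt(fit$sigma2)), ns, P)
  } else matrix(0, ns, P)

  # start each draw at its own equilibrium given the pre-shock regressor level
  y_prev <- -(a0 + drop(TH %*% Xlag[1, ])) / th0
  dy_hist <- matrix(0, ns, max(spec$p, 1L))
  paths <- matrix(NA_real_, ns, P)
  for (t in seq_len(P)) {
    dy <- a0 + th0 * y_prev + lev_contrib[, t] + diff_contrib[, t] + eps[, t]
    if (!is.null(AL)) {
      for (i in seq_len(spec$p)) dy <- dy + AL[, i] * dy_hist[, i]
    }
    y_prev <- y_prev + dy
    paths[, t] <- y_prev
    if (spec$p > 0) {
      if (spec$p > 1) dy_hist[, 2:spec$p] <- dy_hist[, 1:(spec$p - 1), drop = FALSE]
      dy_hist[, 1] <- dy
    }
  }

  bands <- summarize_bands(paths)
  structure(list(paths = paths, bands = bands,
                 shock_period = shock_period, burn_in = scenario$burn_in,
                 exclusion_rate = excl_rate, n_kept = ns,
                 psd_repaired = psd_repaired, scenario = scenario,
                 size_log = size_log),
            class = "ardl_sim")
}

#' Percentile bands of simulated response paths
#'
#' @param paths Draws-by-periods matrix of simulated dependent levels.
#' @param levels Central interval coverages in (0, 1).
#' @return Data frame: `period`, `mean`, and `lo`/`hi` columns per coverage
#'   level (empirical quantiles at `(1 - level)/2` and `(1 + level)/2`).
#'   Intervals are nested by construction when levels are increasing.
#' @export
summarize_bands <- function(paths, levels = c(0.75, 0.90, 0.95)) {
  if (!is.matrix(paths) || nrow(paths) == 0 || ncol(paths) == 0) {
    stop("'paths' must be a non-empty matrix", call. = FALSE)
  }
  if (any(levels <= 0 | levels >= 1)) stop("'levels' must lie in (0,1)", call. = FALSE)
  out <- data.frame(period = seq_len(ncol(paths)), mean = colMeans(paths))
  for (l in levels) {
    qs <- apply(paths, 2, stats::quantile,
                probs = c((1 - l) / 2, (1 + l) / 2), names = FALSE)
    tag <- formatC(round(100 * l), width = 2, flag = "0")
    out[[paste0("lo", tag)]] <- qs[1, ]
    out[[paste0("hi", tag)]] <- qs[2, ]
  }
  out
}

#' @export
print.ardl_sim <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf(
    "Dynamic ARDL simulation: +%g %s shock to %s at period %d (horizon %d, %d draws kept)\n",
    sc$size, sc$size_unit, sc$variable, sc$shock_time, sc$horizon, x$n_kept))
  if (x$exclusion_rate > 0) {
    cat(sprintf("  excluded %.1f%% divergent draws (theta0 >= 0)\n",
                100 * x$exclusion_rate))
  }
  pre <- x$bands$mean[x$shock_period - 1]
  post <- x$bands$mean[nrow(x$bands)]
  cat(sprintf("  mean level: pre-shock %.3f -> terminal %.3f (shift %.3f log units)\n",
              pre, post, post - pre))
  invisible(x)
}
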