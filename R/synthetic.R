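#' Random walk with drift
#'
#' Generates `x_t = x_{t-1} + drift + e_t`, `e_t ~ N(0, sigma^2)`, the
#' canonical I(1) process used to emulate nonstationary climate drivers.
#' The first element equals `x0`.
#'
#' @param n Series length (at least 2).
#' @param drift Per-period drift.
#' @param sigma Innovation standard deviation (>= 0).
#' @param seed Optional integer seed; the seed fully determines the output.
#' @param x0 Starting value.
#' @return Numeric vector of length `n`.
#' @export
generate_random_walk <- function(n, drift = 0, sigma = 1, seed = NULL, x0 = 0) {
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x0 + cumsum(c(0, drift + stats::rnorm(n - 1, sd = sigma)))
}

#' Stationary mean-zero AR(1) series
#'
#' Simulates `x_t = phi * x_{t-1} + e_t` and discards a burn-in so that the
#' returned draw is (approximately) from the stationary distribution with
#' variance `sigma^2 / (1 - phi^2)`.
#'
#' @param n Series length.
#' @param phi Autoregressive coefficient, `|phi| < 1`.
#' @param sigma Innovation standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @param burn_in Number of initial draws discarded (>= 100 by default).
#' @return Numeric vector of length `n`.
#' @export
generate_stationary_ar <- function(n, phi, sigma = 1, seed = NULL, burn_in = 100) {
  if (abs(phi) >= 1) stop("'phi' must satisfy |phi| < 1", call. = FALSE)
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  e <- stats::rnorm(n + burn_in, sd = sigma)
  x <- as.numeric(stats::filter(e, phi, method = "recursive"))
  x[(burn_in + 1):(burn_in + n)]
}

#' Specify the synthetic error-correction data-generating process
#'
#' The generator emulates the statistical structure the ARDL workflow assumes:
#' I(1) (or stationary AR) regressors on the log scale, a single cointegrating
#' relation `y = c + kappa' x` with known long-run elasticities, and an
#' error-correction adjustment `dy_t = rho (y_{t-1} - c - kappa' x_{t-1}) +
#' sum_k beta_k dx_{k,t} + eps_t` whose speed `rho` mirrors the adjustment
#' observed for monthly burned-area data (about -0.6 per month).
#'
#' Defaults reproduce the study conditions: 216 months, long-run elasticities
#' matching the magnitudes estimated for the Xilingol fire-climate system
#' (wind 20.81, maximum temperature 8.651, ...), `rho = -0.611`, and
#' contemporaneous short-run coefficients at one tenth of the long-run ones.
#'
#' @param n_obs Number of months.
#' @param kappa Named vector of long-run elasticities, one per regressor.
#' @param rho Adjustment speed, in `(-1, 0]` (0 switches cointegration off).
#' @param intercept Long-run intercept `c`.
#' @param regressor_process `"rw"` (random walk) or `"ar1"` per regressor
#'   (recycled).
#' @param phi AR(1) coefficient for `"ar1"` regressors.
#' @param drift Per-regressor random-walk drift (recycled).
#' @param regressor_sd Innovation SD of each regressor (log scale, recycled).
#' @param regressor_mean Baseline log level of each regressor (recycled);
#'   processes start at (for `"rw"`) or fluctuate around (for `"ar1"`) this
#'   level.
#' @param eps_sd Innovation SD of the error-correction equation.
#' @param short_run Named vector of contemporaneous `dx` coefficients;
#'   default `0.1 * kappa`.
#' @param break_time Optional period after which the long-run elasticity of
#'   `break_variable` is multiplied by `break_multiplier`, creating a
#'   midsample parameter break for stability-test power studies. `NULL`
#'   (default) keeps parameters constant.
#' @param break_variable Regressor whose elasticity breaks.
#' @param break_multiplier Multiplier applied from `break_time + 1` onward.
#' @param seasonal Logical; add a month-of-year multiplicative fire-season
#'   factor (April/May/September peaks, no winter fires) to the burned-area
#'   series. Off by default so estimation tests see the pure ECM structure.
#' @param seed Integer seed; fully determines the draw.
#' @return A `dgp_spec` list, validated.
#' @export
dgp_spec <- function(n_obs = 216,
                     kappa = c(cem = 2.616, rel_humidity = 1.102,
                               t_min = 1.026, t_max = 8.651, precip = 1.421,
                               sunlight = 4.481, wind = 20.81),
                     rho = -0.611, intercept = 0,
                     regressor_process = "rw", phi = 0.5,
                     drift = 0, regressor_sd = 0.02, regressor_mean = 0,
                     eps_sd = 0.3, short_run = NULL, seasonal = FALSE,
                     break_time = NULL, break_variable = NULL,
                     break_multiplier = 2, seed = 1) {
  if (is.null(names(kappa)) || any(!nzchar(names(kappa)))) {
    stop("'kappa' must be a named vector", call. = FALSE)
  }
  if (rho > 0 || rho <= -1) stop("'rho' must lie in (-1, 0]", call. = FALSE)
  k <- length(kappa)
  spec <- list(
    n_obs = n_obs, kappa = kappa, rho = rho, intercept = intercept,
    regressor_process = rep_len(regressor_process, k),
    phi = rep_len(phi, k), drift = rep_len(drift, k),
    regressor_sd = rep_len(regressor_sd, k),
    regressor_mean = rep_len(regressor_mean, k), eps_sd = eps_sd,
    short_run = if (is.null(short_run)) 0.1 * kappa else short_run,
    seasonal = seasonal, break_time = break_time,
    break_variable = break_variable, break_multiplier = break_multiplier,
    seed = seed
  )
  if (!is.null(break_time) && is.null(break_variable)) {
    stop("'break_variable' required when 'break_time' is set", call. = FALSE)
  }
  if (!is.null(break_variable) && !break_variable %in% names(kappa)) {
    stop("'break_variable' must name a regressor in 'kappa'", call. = FALSE)
  }
  if (any(spec$regressor_sd < 0) || eps_sd < 0) {
    stop("innovation SDs must be non-negative", call. = FALSE)
  }
  if (any(abs(spec$phi[spec$regressor_process == "ar1"]) >= 1)) {
    stop("AR(1) regressors need |phi| < 1", call. = FALSE)
  }
  class(spec) <- "dgp_spec"
  spec
}

#' Generate a synthetic cointegrated fire-climate system
#'
#' Draws the regressors and response described by [dgp_spec()] and returns a
#' log-scale [fire_ts()] together with the ground truth (`kappa`, `rho`,
#' intercept, short-run coefficients) so downstream estimators can be checked
#' for parameter recovery. The response is started at its equilibrium value
#' `c + kappa' x_1`. The time index starts at 2001-01.
#'
#' @param spec A [dgp_spec()].
#' @param response Name of the response column (default `"area_burned"`).
#' @return List with `data` (a `fire_ts` whose series are already on the log
#'   scale) and `truth` (list of the DGP parameters).
#' @export
generate_ecm_system <- function(spec, response = "area_burned") {
  stopifnot(inherits(spec, "dgp_spec"))
  set.seed(spec$seed)
  n <- spec$n_obs
  k <- length(spec$kappa)
  vars <- names(spec$kappa)
  X <- matrix(0, n, k, dimnames = list(NULL, vars))
  for (j in seq_len(k)) {
    if (spec$regressor_process[j] == "rw") {
      X[, j] <- spec$regressor_mean[j] +
        cumsum(c(0, spec$drift[j] +
                   stats::rnorm(n - 1, sd = spec$regressor_sd[j])))
    } else {
      e <- stats::rnorm(n + 100, sd = spec$regressor_sd[j])
      x <- as.numeric(stats::filter(e, spec$phi[j], method = "recursive"))
      X[, j] <- spec$regressor_mean[j] + x[101:(100 + n)]
    }
  }
  eps <- stats::rnorm(n, sd = spec$eps_sd)
  beta <- spec$short_run[vars]
  y <- numeric(n)
  y[1] <- spec$intercept + drop(X[1, ] %*% spec$kappa)
  for (t in 2:n) {
    kt <- spec$kappa
    if (!is.null(spec$break_time) && t > spec$break_time) {
      kt[spec$break_variable] <- spec$break_multiplier * kt[spec$break_variable]
    }
    ect <- y[t - 1] - spec$intercept - drop(X[t - 1, ] %*% kt)
    dy <- spec$rho * ect + drop((X[t, ] - X[t - 1, ]) %*% beta) + eps[t]
    y[t] <- y[t - 1] + dy
  }
  dates <- seq(as.Date("2001-01-01"), by = "month", length.out = n)
  df <- data.frame(date = dates, y, X, check.names = FALSE)
  names(df)[2] <- response
  if (spec$seasonal) {
    # multiplicative fire-season profile on the burned-area level scale:
    # exp-scale factors peaking Apr/May/Sep, structural zeros in winter
    mo <- as.integer(format(dates, "%m"))
    fac <- c(0, 0.4, 0.8, 1.6, 1.5, 0.6, 0.5, 0.7, 1.4, 0.6, 0, 0)[mo]
    raw <- (exp(df[[response]]) - 1) * fac
    df[[response]] <- log(pmax(raw, 0) + 1)
  }
  tr <- stats::setNames(rep(list(list(type = "log", offset = 0)),
                            ncol(df) - 1L), names(df)[-1])
  tr[[response]] <- list(type = "log", offset = 1)
  ds <- fire_ts(df, transform = tr)
  list(data = ds,
       truth = list(kappa = spec$kappa, rho = spec$rho,
                    intercept = spec$intercept, short_run = beta,
                    response = response))
}
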