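# Embedded critical-value tables used by the unit-root, bounds and stability
# tests. Everything is stored in source so the package works offline.

# MacKinnon (2010) response-surface coefficients for finite-sample
# Dickey-Fuller critical values: cv(T) = b_inf + b1/T + b2/T^2 + b3/T^3.
# Rows: deterministic spec x significance level.
.df_surface <- local({
  m <- rbind(
    # type  level  b_inf      b1        b2       b3
    c(-2.56574, -2.2358,  -3.627,    0.000),   # none  1%
    c(-1.94100, -0.2686,  -3.365,   31.223),   # none  5%
    c(-1.61682,  0.2656,  -2.714,   25.364),   # none 10%
    c(-3.43035, -6.5393, -16.786,  -79.433),   # drift 1%
    c(-2.86154, -2.8903,  -4.234,  -40.040),   # drift 5%
    c(-2.56677, -1.5384,  -2.809,    0.000),   # drift 10%
    c(-3.95877, -9.0531, -28.428, -134.155),   # trend 1%
    c(-3.41049, -4.3904,  -9.036,  -45.374),   # trend 5%
    c(-3.12705, -2.5856,  -3.925,  -22.380)    # trend 10%
  )
  dimnames(m) <- list(
    paste(rep(c("none", "drift", "trend"), each = 3),
          rep(c("1%", "5%", "10%"), 3), sep = "."),
    c("b_inf", "b1", "b2", "b3"))
  m
})

#' Finite-sample Dickey-Fuller critical values
#'
#' Left-tail critical values for the t-ratio on the lagged level in the
#' Dickey-Fuller regression, from the standard response-surface approximation
#' in sample size `n`.
#'
#' @param type Deterministic specification: `"none"`, `"drift"` (constant), or
#'   `"trend"` (constant + linear trend).
#' @param n Effective sample size of the test regression.
#' @return Named vector `c("1%", "5%", "10%")`, strictly increasing.
#' @export
df_critical_values <- function(type = c("trend", "drift", "none"), n) {
  type <- match.arg(type)
  if (n < 10) stop("sample too short for tabulated critical values", call. = FALSE)
  rows <- paste(type, c("1%", "5%", "10%"), sep = ".")
  cv <- vapply(rows, function(r) {
    b <- .df_surface[r, ]
    unname(b[1] + b[2] / n + b[3] / n^2 + b[4] / n^3)
  }, numeric(1))
  names(cv) <- c("1%", "5%", "10%")
  cv
}

# Pesaran, Shin & Smith (2001) asymptotic bounds for the joint F statistic,
# case III (unrestricted intercept, no trend), k = 1..10 level regressors.
# Columns: I0 and I1 bounds at 10%, 5%, 2.5%, 1%.
.pss_ciii <- local({
  m <- rbind(
    c(4.04, 4.78, 4.94, 5.73, 5.77, 6.68, 6.84, 7.84),
    c(3.17, 4.14, 3.79, 4.85, 4.41, 5.52, 5.15, 6.36),
    c(2.72, 3.77, 3.23, 4.35, 3.69, 4.89, 4.29, 5.61),
    c(2.45, 3.52, 2.86, 4.01, 3.25, 4.49, 3.74, 5.06),
    c(2.26, 3.35, 2.62, 3.79, 2.96, 4.18, 3.41, 4.68),
    c(2.12, 3.23, 2.45, 3.61, 2.75, 3.99, 3.15, 4.43),
    c(2.03, 3.13, 2.32, 3.50, 2.60, 3.84, 2.96, 4.26),
    c(1.95, 3.06, 2.22, 3.39, 2.48, 3.70, 2.79, 4.10),
    c(1.88, 2.99, 2.14, 3.30, 2.37, 3.60, 2.65, 3.97),
    c(1.83, 2.94, 2.06, 3.24, 2.28, 3.50, 2.54, 3.86)
  )
  dimnames(m) <- list(1:10,
                      c("I0.10", "I1.10", "I0.05", "I1.05",
                        "I0.025", "I1.025", "I0.01", "I1.01"))
  m
})

#' Bounds-test critical values
#'
#' Published asymptotic lower (all regressors I(0)) and upper (all I(1))
#' critical bounds for the joint levels F statistic, unrestricted-intercept /
#' no-trend case, for `k` level regressors (excluding the lagged dependent
#' variable).
#'
#' @param k Number of level regressors, 1..10.
#' @param level Significance level: 0.10, 0.05, 0.025 or 0.01.
#' @param case Deterministic case; only `"iii"` (unrestricted intercept, no
#'   trend) is tabulated.
#' @return Named vector `c(I0 = lower, I1 = upper)`.
#' @export
bounds_critical_values <- function(k, level = 0.05, case = "iii") {
  if (!identical(case, "iii")) {
    stop("only case 'iii' (unrestricted intercept, no trend) is tabulated",
         call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 10 || k != round(k)) {
    stop("'k' must be an integer in 1..10", call. = FALSE)
  }
  lev <- c("0.1" = "10", "0.05" = "05", "0.025" = "025", "0.01" = "01")
  key <- lev[as.character(level)]
  if (is.na(key)) stop("unsupported significance level: ", level, call. = FALSE)
  c(I0 = .pss_ciii[k, paste0("I0.", key)],
    I1 = .pss_ciii[k, paste0("I1.", key)])
}

# 5% critical offsets c0 for the CUSUMSQ maximum deviation
# max_r |S_r - (r-k)/(T-k)|, indexed by m = T - k (number of recursive
# residuals). Derived by Monte Carlo under the iid-normal null (200,000
# replicates per m, seed 20260101); interpolated linearly in m between grid
# points and held flat outside the grid.
.cusumsq_c0 <- data.frame(
  m  = c(10, 15, 20, 30, 40, 60, 80, 100, 150, 200, 300),
  c0 = c(0.47381, 0.40971, 0.36654, 0.30950, 0.27348, 0.22862,
         0.20054, 0.18037, 0.14917, 0.13020, 0.10739)
)

cusumsq_critical_offset <- function(m) {
  tab <- .cusumsq_c0
  if (m <= tab$m[1]) return(tab$c0[1])
  if (m >= tab$m[nrow(tab)]) return(tab$c0[nrow(tab)])
  stats::approx(tab$m, tab$c0, xout = m)$y
}
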