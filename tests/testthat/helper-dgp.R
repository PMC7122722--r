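# Shared fixtures: small synthetic systems and independent regression oracles.

study_kappa <- c(cem = 2.616, rel_humidity = 1.102, t_min = 1.026,
                 t_max = 8.651, precip = 1.421, sunlight = 4.481, wind = 20.81)

# correctly-specified estimation design for parameter-recovery experiments:
# the generator has no lagged dy and only contemporaneous dx terms
recovery_spec <- function() ecm_spec(p = 0, q = 0)

# noiseless cointegrated system: exact-fit checks
noiseless_system <- function(n = 120, rho = -0.6, seed = 11) {
  generate_ecm_system(dgp_spec(n_obs = n, rho = rho, eps_sd = 0,
                               regressor_sd = 0.05, seed = seed))
}

# DGP for the CUSUM power study: the wind elasticity doubles at midsample.
# The broken elasticity multiplies a stationary regressor with a nonzero mean
# level, so the break shifts the mean of one-step forecast errors (the
# alternative CUSUM has power against); a zero-mean random-walk regressor
# would leave the break nearly orthogonal to the mean regressor.
break_dgp <- function(seed, n = 216, broken = TRUE) {
  dgp_spec(n_obs = n,
           regressor_process = c(rep("rw", 6), "ar1"), phi = 0.8,
           regressor_mean = c(rep(0, 6), 0.1), eps_sd = 0.2,
           break_time = if (broken) n %/% 2 else NULL,
           break_variable = if (broken) "wind" else NULL,
           break_multiplier = 2, seed = seed)
}

# independent least-squares oracle: normal-equations solve, nothing shared
# with the package's QR path
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - drop(X %*% b)
  s2 <- sum(res^2) / (length(y) - ncol(X))
  V <- s2 * solve(XtX)
  list(coef = drop(b), vcov = V, residuals = res, ssr = sum(res^2),
       se = sqrt(diag(V)))
}

# restricted-vs-unrestricted SSR form of the joint F test
f_oracle <- function(y, X, drop_cols) {
  full <- ols_oracle(y, X)
  Xr <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
  br <- solve(crossprod(Xr), crossprod(Xr, y))
  ssr_r <- sum((y - drop(Xr %*% br))^2)
  q <- length(drop_cols)
  ((ssr_r - full$ssr) / q) / (full$ssr / (length(y) - ncol(X)))
}

# write a fire_ts to CSV and return the path (temp, cleaned by testthat)
write_fixture_csv <- function(ds, file = tempfile(fileext = ".csv")) {
  write_fire_csv(ds, file)
  file
}
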