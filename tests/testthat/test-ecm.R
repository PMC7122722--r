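test_that("design matrix has the documented shape and lag arithmetic", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 216, seed = 71))
  spec <- ecm_spec()                      # p = 1, q = (1,1,1,1,1,0,1)
  d <- build_ecm_design(sys$data, spec)
  expect_equal(length(d$y), 214)          # one row to the difference, one to the lag
  expect_equal(nrow(d$X), 214)
  cn <- colnames(d$X)
  expect_equal(cn[1:3], c("(Intercept)", "L.area_burned", "L.cem"))
  expect_true("LD.area_burned" %in% cn)
  expect_true("D.sunlight" %in% cn)
  expect_false("LD.sunlight" %in% cn)     # q = 0: contemporaneous only
  expect_true(all(c("D.wind", "LD.wind") %in% cn))
  expect_equal(cn[d$level_cols],
               paste0("L.", c("area_burned", spec$regressors)))
})

test_that("fit matches an independent normal-equations oracle", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 200, seed = 72))
  fit <- fit_ecm(sys$data, ecm_spec())
  o <- ols_oracle(fit$y, fit$X)
  expect_lt(max(abs(fit$coefficients - o$coef)), 1e-8)
  expect_lt(max(abs(fit$vcov - o$vcov)), 1e-8)
  # residual orthogonality and basic fit-statistic invariants
  expect_lt(max(abs(crossprod(fit$X, fit$residuals))),
            1e-6 * max(abs(crossprod(fit$X, fit$y))))
  expect_true(fit$r.squared >= 0 && fit$r.squared <= 1)
  expect_true(fit$dw >= 0 && fit$dw <= 4)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10 * max(ev)))
})

test_that("noiseless data are fitted exactly and recover the DGP", {
  sys <- noiseless_system()
  fit <- fit_ecm(sys$data, recovery_spec())
  expect_lt(fit$ssr, 1e-12)
  expect_equal(fit$r.squared, 1, tolerance = 1e-9)
  sr <- short_run_coefficients(fit)
  expect_lt(abs(attr(sr, "ect") - (-0.6)), 1e-8)
  lr <- long_run_coefficients(fit)
  expect_equal(lr$elasticity, unname(sys$truth$kappa[lr$regressor]),
               tolerance = 1e-7)
})

test_that("long-run elasticities follow -theta_k/theta_0 with delta-method SEs", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 216, seed = 73))
  fit <- fit_ecm(sys$data, ecm_spec())
  lr <- long_run_coefficients(fit)
  b <- coef(fit); th0 <- b[["L.area_burned"]]
  for (v in fit$spec$regressors) {
    thk <- b[[paste0("L.", v)]]
    expect_equal(lr$elasticity[lr$regressor == v], -thk / th0,
                 tolerance = 1e-12)
    g <- c(thk / th0^2, -1 / th0)
    Vb <- fit$vcov[paste0("L.", c("area_burned", v)),
                   paste0("L.", c("area_burned", v))]
    expect_equal(lr$se[lr$regressor == v], sqrt(drop(t(g) %*% Vb %*% g)),
                 tolerance = 1e-12)
  }
  # arithmetic spot check of the ratio itself
  expect_equal(-(4.325) / (-0.5), 8.65)
  sr <- short_run_coefficients(fit)
  expect_true(attr(sr, "ect") > -1 && attr(sr, "ect") < 0)
})

test_that("elasticities are invariant to relocating a regressor", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 180, seed = 74))
  ds2 <- sys$data
  ds2$wind <- ds2$wind + 5
  f1 <- fit_ecm(sys$data, ecm_spec())
  f2 <- fit_ecm(ds2, ecm_spec())
  l1 <- long_run_coefficients(f1)
  l2 <- long_run_coefficients(f2)
  expect_equal(l1$elasticity, l2$elasticity, tolerance = 1e-8)
  expect_gt(abs(coef(f2)[["(Intercept)"]] - coef(f1)[["(Intercept)"]]), 1e-6)
})

test_that("theta0 >= 0 is flagged but still reported", {
  set.seed(75)
  # an explosive-ish dependent: no error correction
  df <- data.frame(date = seq(as.Date("2001-01-01"), by = "month", length.out = 150),
                   area_burned = cumsum(rnorm(150, 0.2)),
                   wind = generate_stationary_ar(150, 0.5, seed = 76))
  fit <- fit_ecm(fire_ts(df),
                 ecm_spec(regressors = "wind", p = 0, q = c(wind = 0)))
  if (coef(fit)[["L.area_burned"]] >= 0) {
    expect_warning(lr <- long_run_coefficients(fit), "no error correction")
    expect_true(attr(lr, "no_error_correction"))
  } else {
    succeed("draw produced a negative theta0; flag path covered elsewhere")
  }
})

test_that("model rotation returns one deterministic fit per dependent", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 150, seed = 77))
  fits <- rotate_models(sys$data)
  expect_length(fits, 8)
  expect_setequal(names(fits), setdiff(names(sys$data), "date"))
  direct <- fit_ecm(sys$data,
                    ecm_spec(dependent = "wind",
                             regressors = setdiff(names(fits), "wind"), q = 1))
  expect_identical(coef(fits[["wind"]]), coef(direct))
})

test_that("degenerate designs are rejected with named columns", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 120, seed = 78))
  ds <- sys$data
  ds$dup <- ds$wind
  spec <- ecm_spec(regressors = c("wind", "dup"), q = 0)
  expect_error(fit_ecm(ds, spec), "rank-deficient")
  expect_error(ecm_spec(dependent = "wind", regressors = c("wind", "cem")),
               "also listed")
})
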