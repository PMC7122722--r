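test_that("a zero-size shock leaves the mean path at equilibrium", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 216, seed = 91))
  fit <- fit_ecm(sys$data, ecm_spec())
  sim <- simulate_response(fit, sys$data,
                           shock_scenario("wind", size = 0, n_sims = 200,
                                          seed = 1))
  dev <- abs(sim$bands$mean - sim$bands$mean[1])
  expect_lt(max(dev) / abs(sim$bands$mean[1]), 1e-6)
})

test_that("the simulated long-run response converges to -theta_k/theta_0", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 216, seed = 92))
  fit <- fit_ecm(sys$data, ecm_spec())
  lr <- long_run_coefficients(fit)
  el <- lr$elasticity[lr$regressor == "wind"]
  sc <- shock_scenario("wind", size = 1, size_unit = "log", shock_time = 5,
                       horizon = 40, n_sims = 2000, seed = 2)
  sim <- simulate_response(fit, sys$data, sc)
  shift <- sim$paths[, ncol(sim$paths)] - sim$paths[, sim$shock_period - 1]
  mc_se <- stats::sd(shift) / sqrt(length(shift))
  expect_lt(abs(mean(shift) - el), 2 * mc_se + 1e-3 * abs(el))
})

test_that("identical seeds reproduce bands bitwise", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 150, seed = 93))
  fit <- fit_ecm(sys$data, ecm_spec())
  sc <- shock_scenario("t_max", n_sims = 300, seed = 9)
  s1 <- simulate_response(fit, sys$data, sc)
  s2 <- simulate_response(fit, sys$data, sc)
  expect_identical(s1$bands, s2$bands)
  expect_identical(s1$paths, s2$paths)
})

test_that("percentile bands are nested, bracket the mean, and match a sort oracle", {
  set.seed(94)
  paths <- matrix(rnorm(500 * 30), 500, 30)
  b <- summarize_bands(paths)
  expect_true(all(b$lo95 <= b$lo90 & b$lo90 <= b$lo75))
  expect_true(all(b$hi75 <= b$hi90 & b$hi90 <= b$hi95))
  expect_true(all(b$mean >= b$lo75 & b$mean <= b$hi75))
  # independent sort-based quantile (type-7 interpolation done by hand)
  q_oracle <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  for (j in c(1, 15, 30)) {
    expect_lt(abs(b$lo90[j] - q_oracle(paths[, j], 0.05)), 1e-12)
    expect_lt(abs(b$hi75[j] - q_oracle(paths[, j], 0.875)), 1e-12)
  }
  cst <- matrix(2.5, 40, 10)
  bc <- summarize_bands(cst)
  expect_true(all(bc$lo95 == 2.5 & bc$hi95 == 2.5 & bc$mean == 2.5))
  expect_error(summarize_bands(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(summarize_bands(paths, levels = c(0.5, 1.2)), "0,1")
})

test_that("post-shock convergence is geometric at rate 1 + theta0", {
  sys <- noiseless_system(n = 200)
  fit <- fit_ecm(sys$data, recovery_spec())
  sc <- shock_scenario("wind", size = 1, size_unit = "log", shock_time = 1,
                       horizon = 30, burn_in = 5, n_sims = 100, seed = 4)
  sim <- simulate_response(fit, sys$data, sc)
  y <- sim$bands$mean
  y_inf <- y[length(y)]
  gap <- abs(y[sim$shock_period:(sim$shock_period + 8)] - y_inf)
  slope <- stats::coef(stats::lm(log(gap) ~ seq_along(gap)))[2]
  th0 <- coef(fit)[["L.area_burned"]]
  expect_lt(abs(slope - log(1 + th0)) / abs(log(1 + th0)), 0.1)
})

test_that("divergent draws are excluded and reported, never silent", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 150, seed = 95))
  fit <- fit_ecm(sys$data, recovery_spec())
  # push theta0 toward zero with wide uncertainty so some draws are >= 0
  nm <- "L.area_burned"
  fit$coefficients[[nm]] <- -0.05
  fit$vcov[nm, nm] <- 0.05^2
  sim <- simulate_response(fit, sys$data,
                           shock_scenario("wind", n_sims = 400, seed = 5))
  expect_gt(sim$exclusion_rate, 0)
  expect_equal(sim$n_kept, round((1 - sim$exclusion_rate) * 400))
  expect_false(anyNA(sim$paths))
})

test_that("scenario validation catches impossible configurations", {
  expect_error(shock_scenario("wind", n_sims = 10), "at least 100")
  expect_error(shock_scenario("wind", shock_time = 30, horizon = 20),
               "shock_time")
  sys <- generate_ecm_system(dgp_spec(n_obs = 120, seed = 96))
  fit <- fit_ecm(sys$data, ecm_spec())
  expect_error(simulate_response(fit, sys$data,
                                 shock_scenario("not_there", n_sims = 100)),
               "not a regressor")
})
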