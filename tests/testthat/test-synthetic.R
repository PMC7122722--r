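test_that("random walk generator honors drift, sigma and the seed contract", {
  expect_equal(generate_random_walk(5, drift = 1, sigma = 0), c(0, 1, 2, 3, 4))
  expect_identical(generate_random_walk(100, seed = 7),
                   generate_random_walk(100, seed = 7))
  expect_error(generate_random_walk(1), "at least 2")
  expect_error(generate_random_walk(10, sigma = -1), "non-negative")
})

test_that("stationary AR(1) draws match their closed-form moments", {
  x <- generate_stationary_ar(2000, phi = 0, sigma = 1, seed = 21)
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 2 / sqrt(length(x)))

  expect_equal(generate_stationary_ar(50, phi = 0.5, sigma = 0, seed = 1),
               rep(0, 50))

  x <- generate_stationary_ar(500, phi = 0.5, sigma = 1, seed = 22)
  v_true <- 1 / (1 - 0.25)
  se_var <- v_true * sqrt(2 / length(x))   # approx SE of a sample variance
  expect_lt(abs(stats::var(x) - v_true), 3 * se_var)

  expect_error(generate_stationary_ar(100, phi = 1.0), "phi")
})

test_that("noiseless static-regressor system sits at its equilibrium", {
  spec <- dgp_spec(n_obs = 50, rho = -0.6, eps_sd = 0, regressor_sd = 0,
                   regressor_mean = 0.3, intercept = 2, seed = 1)
  sys <- generate_ecm_system(spec)
  eq <- 2 + sum(spec$kappa * 0.3)
  expect_equal(unname(sys$data$area_burned), rep(eq, 50), tolerance = 1e-12)
})

test_that("rho = 0 leaves the equilibrium error uncorrected (a random walk)", {
  spec <- dgp_spec(n_obs = 300, rho = 0, seed = 31)
  sys <- generate_ecm_system(spec)
  z <- sys$data$area_burned -
    as.matrix(as.data.frame(sys$data)[names(spec$kappa)]) %*% spec$kappa
  res <- adf_test(drop(z), type = "drift")
  expect_equal(res$decision, "nonstationary")
})

test_that("the seed fully determines the generated system", {
  a <- generate_ecm_system(dgp_spec(seed = 77))
  b <- generate_ecm_system(dgp_spec(seed = 77))
  expect_identical(as.data.frame(a$data), as.data.frame(b$data))
  expect_identical(a$truth, b$truth)
})

test_that("seasonal mode zeroes winter burned area and keeps fire-season peaks", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 48, seasonal = TRUE, seed = 3))
  raw <- exp(sys$data$area_burned) - 1
  mo <- as.integer(format(sys$data$date, "%m"))
  expect_true(all(raw[mo %in% c(1, 11, 12)] == 0))
  expect_true(all(raw[mo %in% c(4, 5)] >= 0))
})

test_that("invalid DGP specifications are rejected", {
  expect_error(dgp_spec(rho = 0.2), "rho")
  expect_error(dgp_spec(kappa = c(1, 2)), "named")
  expect_error(dgp_spec(eps_sd = -1), "non-negative")
  expect_error(dgp_spec(break_time = 10), "break_variable")
  expect_error(dgp_spec(break_time = 10, break_variable = "nope"),
               "must name a regressor")
})
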