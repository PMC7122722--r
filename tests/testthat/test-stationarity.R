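test_that("ADF t-ratio equals an independent normal-equations oracle", {
  set.seed(41)
  x <- cumsum(rnorm(200))
  for (type in c("trend", "drift")) {
    res <- adf_test(x, type, lags = 2)
    # rebuild the auxiliary regression by hand and solve independently
    n <- length(x); m <- 2L
    dx <- diff(x)
    t_idx <- (m + 2L):n
    X <- cbind(x[t_idx - 1], 1, sapply(1:m, function(i) dx[t_idx - 1 - i]))
    colnames(X) <- c("lag_level", "const", paste0("ld", 1:m))
    if (type == "trend") X <- cbind(X, trend = t_idx)
    o <- ols_oracle(dx[t_idx - 1], X)
    expect_lt(abs(res$statistic - o$coef[["lag_level"]] / o$se[["lag_level"]]),
              1e-8)
  }
})

test_that("differencing a random walk restores stationarity at 5%", {
  rw <- generate_random_walk(300, seed = 42)
  expect_equal(adf_test(rw, "drift")$decision, "nonstationary")
  expect_equal(adf_test(difference(rw, 1), "drift")$decision, "stationary")
})

test_that("PP equals ADF(0) at bandwidth zero and separates I(0) from I(1)", {
  set.seed(43)
  wn <- rnorm(300)
  expect_lt(abs(pp_test(wn, "drift", bandwidth = 0)$statistic -
                adf_test(wn, "drift", lags = 0)$statistic), 1e-10)
  # default bandwidth: correction small for iid residuals
  expect_lt(abs(pp_test(wn, "drift")$statistic -
                adf_test(wn, "drift", lags = 0)$statistic), 0.3)
  expect_equal(pp_test(generate_stationary_ar(500, 0.5, seed = 44),
                       "drift")$decision, "stationary")
  expect_equal(pp_test(generate_random_walk(500, seed = 45),
                       "drift")$decision, "nonstationary")
})

test_that("critical values are ordered and the decision matches the rule", {
  for (type in c("none", "drift", "trend")) {
    cv <- df_critical_values(type, 150)
    expect_true(cv[["1%"]] < cv[["5%"]], label = type)
    expect_true(cv[["5%"]] < cv[["10%"]], label = type)
  }
  res <- adf_test(generate_random_walk(200, seed = 46), "drift")
  expect_identical(res$decision,
                   if (res$statistic < res$critical_values[["5%"]])
                     "stationary" else "nonstationary")
})

test_that("integration orders classify I(0), I(1) and I(2) constructions", {
  i0 <- generate_stationary_ar(300, 0.3, seed = 47)
  expect_equal(integration_order(i0, "adf")$order, 0)

  i1 <- generate_random_walk(300, seed = 48)
  o1 <- integration_order(i1, "adf")
  expect_equal(o1$order, 1)
  expect_false(o1$i2_flag)

  set.seed(49)
  i2 <- cumsum(cumsum(rnorm(300)))
  o2 <- integration_order(i2, "adf")
  expect_equal(o2$order, 2)
  expect_true(o2$i2_flag)

  set.seed(50)
  i3 <- cumsum(cumsum(cumsum(rnorm(300))))
  expect_error(integration_order(i3, "adf"), "order > 2")
})

test_that("classification demands comparable results and guards degenerate input", {
  a <- adf_test(generate_random_walk(100, seed = 51), "trend")
  p <- pp_test(generate_random_walk(100, seed = 51), "drift")
  expect_error(classify_integration_order(a, p, a), "same test")
  expect_error(adf_test(rep(1, 100)), "constant series")
})

test_that("stationary-at-level series stay stationary after differencing", {
  # monotonicity of the classification in the differencing order
  hits <- vapply(1:40, function(i) {
    x <- generate_stationary_ar(250, 0.4, seed = 600 + i)
    lev <- adf_test(x, "trend")
    d1 <- adf_test(difference(x, 1), "drift")
    !(lev$decision == "stationary") || d1$decision == "stationary"
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
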