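test_that("Durbin-Watson matches its closed forms and guards", {
  n <- 1000
  alt <- rep(c(1, -1), n / 2)
  expect_equal(durbin_watson(alt), 4 * (n - 1) / n, tolerance = 1e-12)
  expect_error(durbin_watson(rep(0, 10)), "all-zero")
  expect_error(durbin_watson(1), "at least 2")
  set.seed(101)
  expect_true(durbin_watson(rnorm(200)) > 0 && durbin_watson(rnorm(200)) < 4)
})

test_that("ARCH LM matches its auxiliary-regression oracle and has power", {
  set.seed(112)
  e <- rnorm(400)
  got <- arch_lm(e, lags = 2)
  e2 <- e^2; n <- length(e2)
  y <- e2[3:n]
  X <- cbind(1, e2[2:(n - 1)], e2[1:(n - 2)])
  o <- ols_oracle(y, X)
  r2 <- 1 - o$ssr / sum((y - mean(y))^2)
  expect_lt(abs(got$statistic - length(y) * r2), 1e-8)
  expect_gt(got$p.value, 0.05)                 # iid null

  # ARCH(1) alternative, alpha = 0.8
  set.seed(103)
  h <- numeric(600); a <- numeric(600); h[1] <- 1; a[1] <- rnorm(1)
  for (t in 2:600) { h[t] <- 0.2 + 0.8 * a[t - 1]^2; a[t] <- sqrt(h[t]) * rnorm(1) }
  expect_lt(arch_lm(a, 1)$p.value, 0.01)
})

test_that("Breusch-Godfrey matches lmtest and detects AR(1) errors", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 200, seed = 104))
  fit <- fit_ecm(sys$data, ecm_spec())
  got <- bg <- breusch_godfrey(fit, lags = 2)
  # oracle: aux regression by independent solve
  e <- fit$residuals; n <- length(e)
  E <- sapply(1:2, function(j) c(rep(0, j), e[1:(n - j)]))
  o <- ols_oracle(e, cbind(fit$X, E))
  r2 <- 1 - o$ssr / sum((e - mean(e))^2)
  expect_lt(abs(got$statistic - (n - 2) * r2), 1e-8)
  expect_gt(got$p.value, 0.05)

  # cross-check order of magnitude against lmtest on a plain lm
  set.seed(105)
  x <- rnorm(300)
  u <- as.numeric(stats::filter(rnorm(300), 0.6, method = "recursive"))
  y <- 1 + x + u
  lmfit <- stats::lm(y ~ x)
  pseudo <- list(residuals = stats::residuals(lmfit),
                 X = stats::model.matrix(lmfit))
  ours <- breusch_godfrey(pseudo, lags = 1)
  expect_lt(ours$p.value, 0.01)
  if (requireNamespace("lmtest", quietly = TRUE)) {
    ref <- lmtest::bgtest(lmfit, order = 1, fill = 0)
    expect_lt(abs(ours$statistic - unname(ref$statistic)) /
                unname(ref$statistic), 0.02)
  }
  expect_error(breusch_godfrey(fit, lags = 0), "at least 1")
})

test_that("RESET matches its SSR oracle, is quiet under linearity, loud under curvature", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 200, seed = 106))
  fit <- fit_ecm(sys$data, ecm_spec())
  got <- ramsey_reset(fit)
  fs <- fit$fitted / stats::sd(fit$fitted)
  o_f <- f_oracle(fit$y, cbind(fit$X, f2 = fs^2, f3 = fs^3), c("f2", "f3"))
  expect_lt(abs(got$statistic - o_f) / max(o_f, 1e-6), 1e-8)
  expect_gt(got$p.value, 0.05)

  # quadratic DGP fitted linearly
  set.seed(107)
  x <- rnorm(300)
  yq <- 1 + x + 0.5 * x^2 + rnorm(300, sd = 0.5)
  lmfit <- stats::lm(yq ~ x)
  pseudo <- list(fitted = stats::fitted(lmfit), X = stats::model.matrix(lmfit),
                 y = yq, ssr = sum(stats::residuals(lmfit)^2))
  expect_lt(ramsey_reset(pseudo)$p.value, 0.01)
})

test_that("Jarque-Bera is exact on a zero-skew kurtosis-3 sample and calibrated", {
  x <- c(rep(0, 8), -1, -1, 1, 1)      # S = 0, K = 3 exactly
  jb <- jarque_bera(x)
  expect_equal(jb$statistic, 0, tolerance = 1e-12)
  expect_equal(jb$skewness, 0)
  expect_equal(jb$kurtosis, 3)

  set.seed(108)
  expect_lt(jarque_bera(rexp(500))$p.value, 0.01)
  expect_gt(jarque_bera(rnorm(1000))$p.value, 0.05)
  expect_error(jarque_bera(rep(1, 20)), "zero variance")
  expect_error(jarque_bera(rnorm(5)), "at least 8")
})

test_that("diagnostic tests hold their nominal size under the null", {
  set.seed(109)
  rates <- rowMeans(replicate(400, {
    n <- 300
    x1 <- rnorm(n); x2 <- rnorm(n)
    X <- cbind(`(Intercept)` = 1, x1, x2)
    y <- drop(X %*% c(1, 0.5, -0.5)) + rnorm(n)
    o <- ols_oracle(y, X)
    fit <- list(residuals = o$residuals, X = X, y = y, ssr = o$ssr,
                fitted = y - o$residuals)
    c(arch = arch_lm(o$residuals, 1)$p.value < 0.05,
      bg = breusch_godfrey(fit, 1)$p.value < 0.05,
      reset = ramsey_reset(fit)$p.value < 0.05,
      jb = jarque_bera(o$residuals)$p.value < 0.05)
  }))
  for (nm in names(rates)) {
    expect_gte(rates[[nm]], 0.02)
    expect_lte(rates[[nm]], 0.08)
  }
})

test_that("seasonal correlations pool the right months and match cor()", {
  sys <- generate_ecm_system(dgp_spec(n_obs = 216, seed = 110))
  sc <- seasonal_correlations(sys$data, scale = "as_is")
  expect_setequal(unique(sc$group), c("FMA", "MJJ", "ASO"))
  mo <- as.integer(format(sys$data$date, "%m"))
  sel <- mo %in% 2:4
  r_ref <- stats::cor(sys$data$area_burned[sel], sys$data$t_max[sel])
  expect_lt(abs(sc$r[sc$group == "FMA" & sc$variable == "t_max"] - r_ref),
            1e-12)
  p_ref <- stats::cor.test(sys$data$area_burned[sel],
                           sys$data$t_max[sel])$p.value
  expect_equal(sc$p[sc$group == "FMA" & sc$variable == "t_max"], p_ref)
  expect_true(all(abs(sc$r) <= 1, na.rm = TRUE))

  flat <- as.data.frame(sys$data)
  flat$wind <- 1                                # zero variance
  sc2 <- seasonal_correlations(fire_ts(flat), scale = "as_is")
  expect_true(all(is.na(sc2$r[sc2$variable == "wind"])))
})
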