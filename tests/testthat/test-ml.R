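test_that("ML stationary point at the origin when sum(x_i y_i) = 0", {
  d <- make_data(c(1, 1), matrix(c(1, -1), 2, 1))  # x'y = 0, no intercept
  f <- fit_ml(d)
  expect_equal(unname(f$beta_hat), 0, tolerance = 1e-10)
})

test_that("monotone likelihood is capped at the boundary with a flag", {
  d <- make_data(1, matrix(1, 1, 1))
  expect_warning(f <- fit_ml(d, boundary_margin = 0.01), "boundary")
  expect_equal(unname(f$beta_hat), 0.99)
  expect_true(f$boundary_active)
  expect_true(all(is.na(f$cov_hat)))
})

test_that("one-parameter ML matches a fine grid search", {
  set.seed(3)
  n <- 50
  x <- runif(n, -1, 1)
  delta <- 0.5 * x
  y <- ifelse(runif(n) < (1 + delta) / 2, 1, -1)
  d <- make_data(y, matrix(x, ncol = 1), kinds = c(x1 = "continuous"))
  # feasible range for beta is |beta| < 1 / max|x|
  bmax <- 1 / max(abs(x))
  grid <- seq(-bmax + 1e-6, bmax - 1e-6, by = 1e-5)
  ll <- vapply(grid, function(b) {
    a <- 1 + y * x * b
    if (any(a <= 0)) -Inf else sum(log(a))
  }, numeric(1))
  f <- fit_ml(d)
  expect_false(f$boundary_active)
  expect_equal(unname(f$beta_hat), grid[which.max(ll)], tolerance = 1e-4)
})

test_that("interior ML satisfies the score equation and strict feasibility", {
  d <- random_lpm(200, c(0.05, 0.2, -0.15), seed = 61)
  f <- fit_ml(d)
  expect_false(f$boundary_active)
  expect_lt(f$score_norm, 1e-6)
  expect_true(all(abs(f$delta_hat) < 1))
  expect_true(all(eigen(f$cov_hat, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("ML agrees with OLS to first order in the small-signal limit", {
  for (seed in 1:3) {
    d <- random_lpm(500, c(0.01, 0.02, 0.02), seed = 70 + seed)
    f_ols <- fit_ols(d)
    f_ml <- fit_ml(d)
    gap <- sqrt(sum((f_ml$beta_hat - f_ols$beta_hat)^2))
    expect_lt(gap, 10 * max(abs(f_ols$delta_hat))^2 *
                     sqrt(sum(f_ols$beta_hat^2)))
  }
})

test_that("one aberrant row destroys the likelihood but barely moves OLS", {
  # minimal fragility world: intercept + one +/-1 covariate; the single
  # contaminated row (covariate at +/-1.5) has modest leverage
  spec <- simulation_spec(2000,
                          list(covariate_spec("b1", "binary_pm1", prob = 0.5)),
                          c(0.1, 0.65),
                          feasibility = "reject", seed = 81,
                          contamination = 1L)
  sim <- simulate_lpm(spec)
  expect_identical(lpm_loglik(sim$data, sim$truth$beta), -Inf)
  clean <- lpmbin:::lpm_subset(sim$data, seq_len(2000))
  expect_true(is.finite(lpm_loglik(clean, sim$truth$beta)))
  shift <- sqrt(sum((fit_ols(sim$data)$beta_hat -
                       fit_ols(clean)$beta_hat)^2))
  expect_lt(shift, 5 / 2000)
})

test_that("efficiency gap vanishes at beta = 0 and matches direct assembly", {
  d <- random_lpm(40, c(0.1, 0.3, -0.2), seed = 91)
  eff0 <- efficiency_gap(d, c(0, 0, 0))
  expect_equal(max(abs(eff0$inflation)), 0, tolerance = 1e-14)
  expect_equal(eff0$bound_scalar, 0)

  beta <- c(0.1, 0.3, -0.2)
  eff <- efficiency_gap(d, beta)
  # oracle: explicit (I - Delta)^{-1} matrix assembly
  delta <- drop(d$X %*% beta)
  W <- diag(1 / (1 - delta^2))
  oracle_ml <- solve(t(d$X) %*% W %*% d$X)
  expect_equal(eff$var_ml_approx, oracle_ml, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(all(diag(eff$inflation) > -1e-14))
  expect_error(efficiency_gap(d, c(2, 0, 0)), "infeasible")
})

test_that("Upsilon - Delta diagonal follows the geometric series", {
  # oracle: partial geometric sums sum_{k>=1} delta^{2k} minus delta^2
  for (delta in c(0.3, -0.6)) {
    series <- sum(delta^(2 * (1:200))) - delta^2
    expect_equal(delta^4 / (1 - delta^2), series, tolerance = 1e-12)
  }
  d <- make_data(c(1, -1), rbind(c(1, 0.3 / 0.4), c(1, -0.6 / 0.4)))
  # delta = (0.3, -0.6) under beta = (0, 0.4); inflation bounded by the
  # sandwich of Upsilon - Delta = diag(0.3^4/0.91, 0.6^4/0.64)
  beta <- c(0, 0.4)
  eff <- efficiency_gap(d, beta)
  ud <- c(0.3^4 / (1 - 0.09), 0.6^4 / (1 - 0.36))
  expect_equal(eff$bound_scalar, max(ud) / 2)
  XtX_inv <- solve(crossprod(d$X))
  bound <- XtX_inv %*% crossprod(d$X * ud, d$X) %*% XtX_inv
  expect_true(all(diag(bound) - diag(eff$inflation) > -1e-12))
})
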