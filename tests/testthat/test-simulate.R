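test_that("null model gives fair coin flips", {
  spec <- simulation_spec(4000, list(covariate_spec("u", "continuous")),
                          c(0, 0), seed = 401)
  sim <- simulate_lpm(spec)
  expect_lt(abs(mean(sim$data$y)), 3 / sqrt(4000))
})

test_that("spec invariants are validated", {
  expect_error(simulation_spec(100, list(), numeric(0)))   # beta too short
  expect_error(covariate_spec("a", "continuous", lower = 2, upper = 1))
  expect_error(covariate_spec("a", "binary_pm1", missing_rate = 1))
})

test_that("positive-outcome fraction tracks (1 + delta)/2", {
  spec <- simulation_spec(10000, list(covariate_spec("u", "continuous",
                                                     lower = 0, upper = 0.01)),
                          c(0.5, 0), seed = 403)
  sim <- simulate_lpm(spec)
  p_hat <- mean(sim$data$y == 1)
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
})

test_that("identical seeds reproduce the dataset exactly", {
  spec <- nlsy_like_spec(500, seed = 404)
  s1 <- simulate_lpm(spec)
  s2 <- simulate_lpm(spec)
  expect_identical(s1, s2)
})

test_that("rescale mode makes the worst support corner feasible", {
  spec <- simulation_spec(200, list(covariate_spec("u", "continuous")),
                          c(0.5, 5), feasibility = "rescale", seed = 405)
  sim <- simulate_lpm(spec)
  expect_lt(max(abs(sim$data$X %*% sim$truth$beta)), 1)
  expect_lt(sim$truth$rescale_factor, 1)
  # the emitted beta is feasible at both support corners
  b <- sim$truth$beta
  expect_lte(max(abs(b[1] + b[2] * c(-1, 1))), 1 - 0.02 + 1e-12)
})

test_that("reject mode truncates the linear predictor, error when hopeless", {
  spec <- simulation_spec(500, list(covariate_spec("u", "continuous")),
                          c(0, 1.2), feasibility = "reject", seed = 406)
  sim <- simulate_lpm(spec)
  expect_lte(max(abs(sim$data$X %*% sim$truth$beta)), 1 - 0.02)
  spec_bad <- simulation_spec(50, list(covariate_spec("u", "continuous",
                                                      lower = 2, upper = 3)),
                              c(0, 1), feasibility = "reject", seed = 407)
  expect_error(simulate_lpm(spec_bad), "feasib")
})

test_that("MCAR missingness hits the requested rates", {
  spec <- simulation_spec(20000, list(
    covariate_spec("a", "continuous", missing_rate = 0.3),
    covariate_spec("b", "binary_pm1", missing_rate = 0)),
    c(0.1, 0.2, 0.1), seed = 408)
  sim <- simulate_lpm(spec)
  rate <- mean(sim$data$missing_mask[, "a"])
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / 20000))
  expect_equal(sum(sim$data$missing_mask[, "b"]), 0L)
})

test_that("contamination contract holds exactly", {
  spec <- simulation_spec(300, list(covariate_spec("u", "continuous")),
                          c(0.1, 0.85), feasibility = "reject",
                          contamination = 3L, seed = 409)
  sim <- simulate_lpm(spec)
  expect_equal(sim$truth$contaminated_rows, 301:303)
  delta <- drop(sim$data$X %*% sim$truth$beta)
  expect_equal(sum(abs(delta) > 1), 3L)
  expect_true(all(abs(delta[301:303]) > 1))
  expect_identical(lpm_loglik(sim$data, sim$truth$beta), -Inf)
  expect_true(all(is.finite(fit_ols(sim$data)$beta_hat)))
})

test_that("binned conditional frequencies match (1 + delta)/2", {
  spec <- simulation_spec(1e5, list(covariate_spec("u", "continuous")),
                          c(0, 0.9), seed = 410)
  sim <- simulate_lpm(spec)
  delta <- drop(sim$data$X %*% sim$truth$beta)
  bins <- cut(delta, breaks = seq(-0.9, 0.9, by = 0.2))
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (length(idx) < 500) next
    p_emp <- mean(sim$data$y[idx] == 1)
    p_mod <- mean((1 + delta[idx]) / 2)
    expect_lt(abs(p_emp - p_mod),
              4 * sqrt(p_mod * (1 - p_mod) / length(idx)))
  }
})

test_that("estimation recovers the generator's coefficients", {
  spec <- simulation_spec(1e5, acceptance_covariates(), acceptance_beta,
                          feasibility = "reject", seed = 411)
  sim <- simulate_lpm(spec)
  f <- fit_ols(sim$data)
  se <- sqrt(diag(f$cov_hat))
  expect_true(all(abs(f$beta_hat - sim$truth$beta) < 4 * se))
})

test_that("the study-like spec has the advertised structure", {
  spec <- nlsy_like_spec(9043, seed = 412)
  expect_equal(length(spec$covariates), 5L)
  rates <- vapply(spec$covariates, `[[`, numeric(1), "missing_rate")
  expect_equal(sum(rates > 0), 3L)
  kinds <- vapply(spec$covariates, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "binary_pm1"), 3L)
  sim <- simulate_lpm(spec)
  expect_equal(nrow(sim$data$X), 9043L)
  expect_equal(ncol(sim$data$X), 6L)
  # emitted beta satisfies the simulation-spec feasibility invariant
  # (evaluate on fully observed rows; missing cells are NA by design)
  cd <- lpm_complete(sim$data)
  expect_lt(max(abs(cd$X %*% sim$truth$beta)), 1)
})
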