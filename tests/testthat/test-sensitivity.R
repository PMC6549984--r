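# A small dataset with controllable missingness for design/refit tests.
sens_fixture <- function(n = 400, seed = 301, miss = c(b1 = 0.1, u1 = 0.15)) {
  set.seed(seed)
  X <- cbind("(Intercept)" = 1,
             b1 = 2 * rbinom(n, 1, 0.5) - 1,
             u1 = runif(n, -1, 1),
             u2 = runif(n, -1, 1))
  beta <- c(0.1, 0.1, 0.1, -0.1)
  y <- ifelse(runif(n) < (1 + drop(X %*% beta)) / 2, 1, -1)
  d <- make_data(y, X)
  for (v in names(miss)) {
    d$X[runif(n) < miss[[v]], v] <- NA
  }
  d$missing_mask <- is.na(d$X)
  d
}

test_that("no missingness yields the single empty pattern", {
  d <- sens_fixture(miss = c())
  des <- build_design(d)
  expect_equal(length(des$variables), 0L)
  expect_equal(nrow(des$patterns), 1L)
  rep <- run_sensitivity(d, des)
  base <- fit_ols(d)
  expect_equal(unname(rep$coefficients[1, ]), unname(base$beta_hat))
  expect_equal(unname(rep$max_abs_difference), rep(0, 4))
})

test_that("k partially missing covariates give the 2^k factorial", {
  d <- sens_fixture(miss = c(b1 = 0.1, u1 = 0.1, u2 = 0.1))
  des <- build_design(d)
  expect_equal(des$design_kind, "full_factorial")
  expect_equal(nrow(des$patterns), 8L)
  expect_setequal(rownames(des$patterns),
                  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  expect_equal(des$levels$b1, c(-1, 1))
})

test_that("quartile levels use the interpolation definition", {
  d <- make_data(rep(c(1, -1), 50), cbind(1, v = 1:100))
  d$X[1:4, "v"] <- NA
  d$missing_mask <- is.na(d$X)
  des <- build_design(d)
  obs <- 5:100
  expect_equal(des$levels$v,
               unname(quantile(obs, c(0.25, 0.75), type = 7)))
  # the full 1..100 sequence oracle
  expect_equal(unname(quantile(1:100, c(0.25, 0.75), type = 7)),
               c(25.75, 75.25))
})

test_that("user levels override and bad inputs error", {
  d <- sens_fixture()
  des <- build_design(d, user_levels = list(u1 = c(-0.9, 0.9)))
  expect_equal(des$levels$u1, c(-0.9, 0.9))
  expect_error(build_design(d, user_levels = list(u1 = c(1, -1))))
  d$X[, "u2"] <- NA
  d$missing_mask <- is.na(d$X)
  expect_error(build_design(d), "entirely missing")
})

test_that("large k falls back to a balanced half fraction", {
  d <- sens_fixture(miss = c(b1 = 0.1, u1 = 0.1, u2 = 0.1))
  des <- build_design(d, max_full_factorial = 2L)
  expect_equal(des$design_kind, "half_fraction")
  expect_equal(nrow(des$patterns), 4L)
  expect_match(des$defining_contrast, "b1:u1:u2")
  code <- ifelse(des$patterns == "H", 1, -1)
  expect_true(all(colSums(code) == 0))                 # balance
  expect_true(all(apply(code, 1, prod) == 1))          # defining relation
})

test_that("filling restores the base fit when nothing is actually missing", {
  d <- sens_fixture()
  des <- build_design(d)
  d_clean <- d
  d_clean$X[is.na(d_clean$X)] <- 0.5
  d_clean$missing_mask[] <- FALSE
  base <- fit_ols(d_clean)
  rep <- run_sensitivity(d_clean, des)
  for (r in seq_len(nrow(rep$coefficients))) {
    expect_equal(unname(rep$coefficients[r, ]), unname(base$beta_hat))
  }
})

test_that("sensitivity reports are deterministic and annotated on failure", {
  d <- sens_fixture()
  des <- build_design(d)
  r1 <- run_sensitivity(d, des)
  r2 <- run_sensitivity(d, des)
  expect_identical(r1$coefficients, r2$coefficients)
  # pattern labels cover the design uniquely
  expect_false(anyDuplicated(r1$per_pattern$pattern) > 0)
  expect_equal(sort(r1$per_pattern$pattern), sort(rownames(des$patterns)))
})

test_that("main effects recover constructed contrasts", {
  d <- sens_fixture(miss = c(b1 = 0.1, u1 = 0.1))
  des <- build_design(d)
  rep <- run_sensitivity(d, des)

  # identical estimates across patterns: all effects zero
  rep0 <- rep
  rep0$coefficients[] <- rep(rep$coefficients[1, ], each = 4)
  expect_equal(max(abs(missingness_main_effects(rep0, des))), 0)

  # estimates +c when b1 assigned H, -c when L, other variable inert
  repc <- rep
  code <- ifelse(des$patterns == "H", 1, -1)
  repc$coefficients[] <- 0
  repc$coefficients[, 2] <- 0.3 * code[, "b1"]
  eff <- missingness_main_effects(repc, des)
  expect_equal(eff["b1", 2], 0.3)
  expect_equal(eff["u1", 2], 0)

  # random table vs brute-force least-squares on the +/-1 codes
  set.seed(311)
  repr <- rep
  repr$coefficients[] <- rnorm(length(repr$coefficients))
  eff_r <- missingness_main_effects(repr, des)
  for (j in seq_len(ncol(repr$coefficients))) {
    oracle <- solve(crossprod(cbind(1, code)),
                    crossprod(cbind(1, code), repr$coefficients[, j]))[-1]
    expect_equal(unname(eff_r[, j]), unname(oracle), tolerance = 1e-12)
  }
})

test_that("non-orthogonal pattern subsets are rejected", {
  d <- sens_fixture(miss = c(b1 = 0.1, u1 = 0.1))
  des <- build_design(d)
  rep <- run_sensitivity(d, des)
  des_bad <- des
  des_bad$patterns <- des$patterns[c(1, 2, 3), ]
  rep_bad <- rep
  rep_bad$coefficients <- rep$coefficients[c(1, 2, 3), ]
  expect_error(missingness_main_effects(rep_bad, des_bad), "orthogonal")
})

test_that("orthogonality: effects are stable under dropping other contrasts", {
  d <- sens_fixture(miss = c(b1 = 0.1, u1 = 0.1))
  des <- build_design(d)
  rep <- run_sensitivity(d, des)
  code <- ifelse(des$patterns == "H", 1, -1)
  eff <- missingness_main_effects(rep, des)
  for (j in seq_len(ncol(rep$coefficients))) {
    solo <- solve(crossprod(cbind(1, code[, 1])),
                  crossprod(cbind(1, code[, 1]), rep$coefficients[, j]))[-1]
    expect_equal(unname(eff["b1", j]), unname(solo), tolerance = 1e-12)
  }
})
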