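# Synthetic data obeying the linear-in-probability model
#   pr(Y = y | x) = (1 + y b'x) / 2,  y in {-1, +1},
# with mixed +/-1-coded binary and bounded continuous covariates, optional
# MCAR missingness, and optional contaminated rows violating |b'x| <= 1 (the
# failure mode that destroys the likelihood while barely moving OLS).

#' Declare a covariate for the simulator
#'
#' @param name Column name.
#' @param kind `"binary_pm1"` (values -1/+1), `"continuous"` (uniform on a
#'   bounded support), or `"clamped_normal"` (normal clamped to the support
#'   bounds — emulates the floor/ceiling clumping of bounded instruments such
#'   as percentile test scores, which piles probability mass exactly at the
#'   support edges).
#' @param prob Success probability pr(x = +1) for binary covariates.
#' @param lower,upper Support bounds for continuous covariates.
#' @param mu,sigma Location and scale of the pre-clamping normal draw
#'   (`"clamped_normal"` only); defaults are the support midpoint and a
#'   quarter of the support width.
#' @param missing_rate Probability that each cell of this covariate is
#'   missing completely at random, in `[0, 1)`.
#' @return A list describing the covariate.
#' @export
covariate_spec <- function(name,
                           kind = c("binary_pm1", "continuous",
                                    "clamped_normal"),
                           prob = 0.5, lower = -1, upper = 1,
                           mu = NULL, sigma = NULL, missing_rate = 0) {
  kind <- match.arg(kind)
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (kind == "binary_pm1") stopifnot(prob > 0, prob < 1)
  if (kind != "binary_pm1") stopifnot(lower < upper)
  if (kind == "clamped_normal") {
    if (is.null(mu)) mu <- (lower + upper) / 2
    if (is.null(sigma)) sigma <- (upper - lower) / 4
    stopifnot(sigma > 0)
  }
  list(name = name, kind = kind, prob = prob, lower = lower, upper = upper,
       mu = mu, sigma = sigma, missing_rate = missing_rate)
}

#' Specify a linear-in-probability simulation
#'
#' @param n Sample size.
#' @param covariates List of [covariate_spec()] entries (the intercept is
#'   implicit and always first).
#' @param beta Coefficient vector of length `length(covariates) + 1`
#'   (intercept first).
#' @param feasibility `"reject"` (redraw rows with `|b'x| > 1 - margin`) or
#'   `"rescale"` (shrink `beta` once so the worst corner of the covariate
#'   support is feasible).
#' @param margin Feasibility margin (default 0.02): sampled rows satisfy
#'   `|b'x| <= 1 - margin`, so estimation noise rarely produces out-of-range
#'   fitted values except to the extent the model itself predicts.
#' @param contamination Number of extra rows generated outside the stated
#'   support with `|b'x| > 1` (default 0).
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `lpm_sim_spec`.
#' @export
simulation_spec <- function(n, covariates, beta,
                            feasibility = c("reject", "rescale"),
                            margin = 0.02, contamination = 0L, seed = 1L) {
  feasibility <- match.arg(feasibility)
  stopifnot(n >= 1, length(beta) == length(covariates) + 1L,
            margin > 0, margin < 1, contamination >= 0)
  nm <- vapply(covariates, `[[`, character(1), "name")
  stopifnot(!anyDuplicated(nm))
  structure(list(n = as.integer(n), covariates = covariates,
                 beta = as.numeric(beta), feasibility = feasibility,
                 margin = margin, contamination = as.integer(contamination),
                 seed = as.integer(seed)),
            class = "lpm_sim_spec")
}

# Worst-case |b'x| over the box support (binary in {-1,+1}, continuous in
# [lower, upper]): maximize/minimize each coordinate contribution.
worst_corner <- function(spec, beta = spec$beta) {
  hi <- beta[1]
  lo <- beta[1]
  for (k in seq_along(spec$covariates)) {
    cv <- spec$covariates[[k]]
    b <- beta[k + 1L]
    rng <- if (cv$kind == "binary_pm1") c(-1, 1) else c(cv$lower, cv$upper)
    hi <- hi + max(b * rng)
    lo <- lo + min(b * rng)
  }
  max(abs(hi), abs(lo))
}

draw_covariates <- function(spec, n) {
  cols <- lapply(spec$covariates, function(cv) {
    switch(cv$kind,
           binary_pm1 = 2 * rbinom(n, 1L, cv$prob) - 1,
           continuous = runif(n, cv$lower, cv$upper),
           clamped_normal = pmin(pmax(stats::rnorm(n, cv$mu, cv$sigma),
                                      cv$lower), cv$upper))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- vapply(spec$covariates, `[[`, character(1), "name")
  cbind("(Intercept)" = 1, X)
}

#' Draw a dataset from the linear-in-probability model
#'
#' Covariates are drawn per the spec; feasibility of the linear predictor is
#' enforced either by redrawing offending rows (`"reject"`, capped at 1000
#' sweeps) or by shrinking `beta` once up front so the worst support corner
#' satisfies `|b'x| <= 1 - margin` (`"rescale"`).  Outcomes are then drawn
#' with `pr(Y = +1 | x) = (1 + b'x)/2`, missingness is applied completely at
#' random cell-by-cell, and any contaminated rows (covariates scaled 1.5x
#' beyond the support until `|b'x| > 1`, outcome set to the value the
#' postulated model deems impossible there, making the true-parameter log
#' likelihood `-Inf`) are appended last and flagged.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `data` (an [lpm_data()]-classed object), and `truth`
#'   (list: `beta` actually used after any rescaling, `rescale_factor`,
#'   `seed`, `contaminated_rows` — indices of appended out-of-range rows).
#' @examples
#' spec <- nlsy_like_spec(n = 300, seed = 42)
#' sim <- simulate_lpm(spec)
#' sim$data
#' @export
simulate_lpm <- function(spec) {
  stopifnot(inherits(spec, "lpm_sim_spec"))
  set.seed(spec$seed)
  beta <- spec$beta
  rescale <- 1
  cap <- 1 - spec$margin
  if (spec$feasibility == "rescale") {
    wc <- worst_corner(spec)
    if (wc > cap) {
      rescale <- cap / wc
      beta <- beta * rescale
    }
  }
  X <- draw_covariates(spec, spec$n)
  delta <- drop(X %*% beta)
  if (spec$feasibility == "reject") {
    for (sweep in seq_len(1000L)) {
      bad <- which(abs(delta) > cap)
      if (length(bad) == 0L) break
      if (sweep == 1000L) {
        stop("simulate_lpm: feasibility rejection cap reached; ",
             length(bad), " row(s) still violate |b'x| <= 1 - margin. ",
             "Use feasibility = 'rescale' or a smaller beta.")
      }
      Xb <- draw_covariates(spec, length(bad))
      X[bad, ] <- Xb
      delta[bad] <- drop(Xb %*% beta)
    }
  }
  y <- ifelse(runif(spec$n) < (1 + delta) / 2, 1, -1)

  # MCAR missingness on covariate cells (never the intercept or outcome)
  for (k in seq_along(spec$covariates)) {
    rate <- spec$covariates[[k]]$missing_rate
    if (rate > 0) {
      miss <- runif(spec$n) < rate
      X[miss, k + 1L] <- NA_real_
    }
  }

  contaminated <- integer()
  if (spec$contamination > 0L) {
    rows <- matrix(NA_real_, spec$contamination, ncol(X))
    yc <- numeric(spec$contamination)
    for (r in seq_len(spec$contamination)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 10000L) {
          stop("simulate_lpm: cannot generate a contaminated row with ",
               "|b'x| > 1; 1.5x the support corner stays in range for this beta")
        }
        xr <- draw_covariates(spec, 1L)
        xr[, -1L] <- xr[, -1L] * 1.5          # outside the stated support
        dr <- drop(xr %*% beta)
        if (abs(dr) > 1) break
      }
      rows[r, ] <- xr
      # the aberrant observation takes the outcome the postulated model deems
      # impossible at this x, so l(beta_true) = -Inf on the contaminated data
      yc[r] <- -sign(dr)
    }
    colnames(rows) <- colnames(X)
    contaminated <- spec$n + seq_len(spec$contamination)
    X <- rbind(X, rows)
    y <- c(y, yc)
  }

  kind <- c("(Intercept)" = "constant",
            vapply(spec$covariates, function(cv) cv$kind, character(1)))
  names(kind) <- colnames(X)
  data <- structure(list(
    y = y, X = X, missing_mask = is.na(X),
    column_meta = kind, n_dropped_outcome = 0L), class = "lpm_data")

  list(data = data,
       truth = list(beta = beta, rescale_factor = rescale, seed = spec$seed,
                    contaminated_rows = contaminated))
}

#' Illustrative study-like simulation spec
#'
#' A fixture emulating the structure of a large youth-cohort educational
#' attainment study: five covariates — a \eqn{\pm 1} gender indicator, a
#' percentile ability score (continuous, 0–100), log family income
#' (continuous, 3–11.23), a \eqn{\pm 1} race indicator, and a \eqn{\pm 1}
#' lives-with-parent indicator — with missingness on the ability score
#' (4.3%), log income (51.2%) and the lives-with-parent indicator (5.1%).
#' Coefficient magnitudes are of the same order as such a study reports; the
#' spec uses `feasibility = "rescale"`, so the emitted coefficients are a
#' feasible shrinkage of these illustrative values.  All numbers are package
#' fixtures, not estimates from any real data.
#'
#' @param n Sample size (at least 100).
#' @param seed Integer seed.
#' @return An `lpm_sim_spec` with five covariates plus intercept, three of
#'   them partially missing.
#' @export
nlsy_like_spec <- function(n, seed = 1L) {
  stopifnot(n >= 100)
  covs <- list(
    covariate_spec("gender", "binary_pm1", prob = 0.5),
    covariate_spec("afqt", "continuous", lower = 0, upper = 100,
                   missing_rate = 0.043),
    covariate_spec("log_income", "continuous", lower = 3, upper = 11.23,
                   missing_rate = 0.512),
    covariate_spec("race", "binary_pm1", prob = 0.25),
    covariate_spec("with_parent", "binary_pm1", prob = 0.9,
                   missing_rate = 0.051)
  )
  beta <- c(-1.45, -0.06, 0.020, 0.06, 0.22, -0.03)
  simulation_spec(n, covs, beta, feasibility = "rescale", seed = seed)
}
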