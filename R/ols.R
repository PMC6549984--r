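# Least-squares estimation for the linear-in-probability model.
#
# With outcomes Y in {-1, +1} and E(Y | x) = b'x, the OLS projection
# (X'X)^{-1} X'Y is unbiased but heteroskedastic: var(Y_i) = 1 - (b'x_i)^2.
# The corrected covariance is
#   Sigma_b = (X'X)^{-1} - (X'X)^{-1} X' D X (X'X)^{-1},  D = diag((b'x_i)^2),
# estimated by plugging in the OLS coefficients.

# QR-based full-rank check; names the aliased columns on failure.
check_full_rank <- function(X, caller) {
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    dep <- colnames(X)[qd$pivot[seq(qd$rank + 1L, ncol(X))]]
    stop(caller, ": design matrix is rank deficient; linearly dependent ",
         "column(s): ", paste(dep, collapse = ", "))
  }
  invisible(qd)
}

new_lpm_fit <- function(beta, cov, delta, method, n, extra = list()) {
  out <- c(list(
    beta_hat = beta,
    cov_hat = cov,
    delta_hat = as.numeric(delta),
    method = method,
    n = n,
    n_out_of_range = sum(abs(delta) > 1)
  ), extra)
  class(out) <- "lpm_fit"
  out
}

#' Ordinary least squares for the linear-in-probability model
#'
#' Projects the \eqn{\pm 1} outcome vector orthogonally onto the column space
#' of the design matrix and attaches the heteroskedasticity-corrected
#' covariance estimate (see [lpm_covariance()]).
#'
#' @param data An [lpm_data()] object with no missing covariate cells.
#' @return An object of class `lpm_fit` with elements `beta_hat`, `cov_hat`,
#'   `delta_hat` (fitted linear predictors \eqn{x_i'\hat\beta}), `method`
#'   (`"ols"`), `n_out_of_range` (count of fitted values outside \eqn{[-1,1]})
#'   and `n_clipped` (rows whose squared fitted value was clipped at 1 inside
#'   the covariance plug-in).
#' @examples
#' spec <- nlsy_like_spec(n = 500, seed = 1)
#' sim <- simulate_lpm(spec)
#' fit_ols(lpm_complete(sim$data))
#' @export
fit_ols <- function(data) {
  stopifnot(inherits(data, "lpm_data"))
  require_complete(data, "fit_ols")
  X <- data$X
  check_full_rank(X, "fit_ols")
  XtX <- crossprod(X)
  beta <- drop(solve(XtX, crossprod(X, data$y)))
  delta <- drop(X %*% beta)
  cv <- lpm_covariance(data, beta)
  new_lpm_fit(beta, cv$sigma, delta, "ols", nrow(X),
              extra = list(n_clipped = cv$n_clipped))
}

#' Corrected covariance of the OLS coefficients
#'
#' Evaluates \deqn{\Sigma_\beta = (X'X)^{-1} - (X'X)^{-1} X' \Delta X
#' (X'X)^{-1}, \quad \Delta = \mathrm{diag}\{(x_i'\beta)^2\},} the covariance
#' of the least-squares estimator under the linear-in-probability model, at a
#' supplied coefficient vector (usually the OLS plug-in).  Rows whose squared
#' linear predictor exceeds 1 would imply a negative outcome variance; such
#' entries are clipped at 1 and counted.
#'
#' @param data An [lpm_data()] object with no missing covariate cells.
#' @param beta Coefficient vector of length `ncol(data$X)`.
#' @return A list with `sigma` (p x p symmetric matrix) and `n_clipped`
#'   (number of rows clipped inside \eqn{\hat\Delta}).
#' @export
lpm_covariance <- function(data, beta) {
  stopifnot(inherits(data, "lpm_data"))
  require_complete(data, "lpm_covariance")
  X <- data$X
  stopifnot(length(beta) == ncol(X), all(is.finite(beta)))
  check_full_rank(X, "lpm_covariance")
  delta2 <- drop(X %*% beta)^2
  n_clipped <- sum(delta2 > 1)
  delta2 <- pmin(delta2, 1)
  XtX_inv <- solve(crossprod(X))
  middle <- crossprod(X * delta2, X)       # X' Delta X
  sigma <- XtX_inv - XtX_inv %*% middle %*% XtX_inv
  sigma <- (sigma + t(sigma)) / 2
  dimnames(sigma) <- list(colnames(X), colnames(X))
  list(sigma = sigma, n_clipped = n_clipped)
}

#' One-step weighted least squares
#'
#' Re-weights the observations by the reciprocal of the estimated outcome
#' variance \eqn{1 - (x_i'\hat\beta_{OLS})^2} and solves the weighted normal
#' equations once.  Because that variance is not bounded away from zero,
#' weights are floored at `1 / variance_floor`; any floored weight sets a
#' caution flag, and weighted least squares should then not be trusted as a
#' general-purpose estimator.
#'
#' @param data An [lpm_data()] object with no missing covariate cells.
#' @param variance_floor Smallest admissible estimated outcome variance
#'   (default 0.05).
#' @return An `lpm_fit` with `method = "wls"`, plus `caution` (`TRUE` when
#'   any weight was floored) and `n_floored`.
#' @export
fit_wls <- function(data, variance_floor = 0.05) {
  stopifnot(variance_floor > 0)
  base <- fit_ols(data)
  v <- 1 - base$delta_hat^2
  n_floored <- sum(v < variance_floor)
  w <- 1 / pmax(v, variance_floor)
  X <- data$X
  XtWX <- crossprod(X * w, X)
  beta <- drop(solve(XtWX, crossprod(X * w, data$y)))
  delta <- drop(X %*% beta)
  cv <- lpm_covariance(data, beta)
  new_lpm_fit(beta, cv$sigma, delta, "wls", nrow(X),
              extra = list(n_clipped = cv$n_clipped,
                           caution = n_floored > 0L,
                           n_floored = n_floored))
}

#' @export
print.lpm_fit <- function(x, ...) {
  cat(sprintf("Linear-in-probability model fit (%s), n = %d\n",
              toupper(x$method), x$n))
  print(coef_table(x), digits = 4)
  cat(sprintf("Fitted values outside [-1, 1]: %d\n", x$n_out_of_range))
  if (!is.null(x$n_clipped) && x$n_clipped > 0L) {
    cat(sprintf("Note: %d squared fitted value(s) clipped at 1 in the covariance plug-in\n",
                x$n_clipped))
  }
  if (isTRUE(x$caution)) {
    cat(sprintf("Caution: %d WLS weight(s) floored; estimated variances near zero\n",
                x$n_floored))
  }
  if (isTRUE(x$boundary_active)) {
    cat("Warning: ML solution on the feasibility boundary; no covariance reported\n")
  }
  invisible(x)
}

# Coefficients, SEs, z-values, and normal-approximation CIs as a data frame.
coef_table <- function(fit, level = 0.95) {
  se <- if (all(is.na(fit$cov_hat))) rep(NA_real_, length(fit$beta_hat)) else
    sqrt(pmax(diag(fit$cov_hat), 0))
  z <- fit$beta_hat / se
  q <- qnorm(1 - (1 - level) / 2)
  data.frame(
    estimate = fit$beta_hat,
    se = se,
    z = z,
    lower = fit$beta_hat - q * se,
    upper = fit$beta_hat + q * se,
    row.names = names(fit$beta_hat)
  )
}
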